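Package: olivenir
Title: NIR Chemometric Prediction of Antioxidant Capacity in Olive Leaf Powder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for calibrating near-infrared (NIR) spectra of dried
    olive (Olea europaea L.) leaf powder against antioxidant-capacity
    reference assays (DPPH, ABTS, ORAC).  Provides spectral pretreatments
    (Savitzky-Golay smoothing and derivatives, multiplicative scatter
    correction, standard normal variate) composable through a compact
    pipeline code, Kennard-Stone calibration/prediction set selection,
    single-response NIPALS partial least squares regression with
    cross-validated latent-variable selection, RMSE/RPD model evaluation
    and pretreatment ranking, Trolox standard-curve assay quantification
    including full and simplified kinetic area-under-curve statistics, and
    phenolic-compound/assay Pearson correlation tables.  A synthetic-data
    generator emulating phenolic profiles, assay reference values, Gaussian
    absorption-band spectra with baseline and scatter effects, and kinetic
    plate readings makes the whole pipeline testable without instrument
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
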