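#' Default NIR absorption-band library for olive-leaf phenolics
#'
#' Seven Gaussian absorption bands at the overtone/combination wavenumbers
#' characteristic of powdered olive leaf: first C-H stretching overtones at
#' 5785 and 5677 cm^-1, the second C=O overtone at 5222 cm^-1, O-H
#' stretching/deformation at 4861 cm^-1, N-H/O-H combination bands at
#' 4404 cm^-1, C-H stretching combination modes at 4337 cm^-1 and CH2
#' bending at 4262 cm^-1.  Each band carries a loading vector giving its
#' absorbance contribution (AU per mg/g dry leaf) for each of the five
#' phenolic compounds tracked by the generator; the loadings encode the
#' expected chemistry (e.g. the carbonyl overtone is dominated by the
#' secoiridoid oleuropein, the hydroxyl bands by hydroxytyrosol and
#' verbascoside).
#'
#' @param centers band centers in cm^-1.
#' @param widths Gaussian standard deviations in cm^-1 (all > 0).
#' @param loadings numeric matrix, `length(centers)` rows x 5 compound
#'   columns, in AU per (mg/g).
#' @return A list of class `band_library` with fields `centers`, `widths`
#'   and `loadings`.
#' @export
band_library <- function(centers = c(5785, 5677, 5222, 4861, 4404, 4337, 4262),
                         widths = c(45, 45, 50, 55, 50, 40, 40),
                         loadings = NULL) {
  if (is.null(loadings)) {
    loadings <- matrix(c(
      # oleuropein  hydroxytyr  ht_hexoside verbascoside apigenin7g
      0.010, 0.006, 0.003, 0.002, 0.004,   # 5785 C-H 1st overtone
      0.008, 0.004, 0.002, 0.001, 0.005,   # 5677 C-H 1st overtone
      0.016, 0.001, 0.002, 0.001, 0.001,   # 5222 C=O 2nd overtone
      0.003, 0.012, 0.006, 0.008, 0.004,   # 4861 O-H str + def
      0.002, 0.003, 0.007, 0.012, 0.002,   # 4404 N-H/O-H combination
      0.006, 0.002, 0.001, 0.002, 0.009,   # 4337 C-H combination
      0.007, 0.001, 0.002, 0.001, 0.006    # 4262 CH2 bending
    ), ncol = 5, byrow = TRUE,
    dimnames = list(NULL, .olivenir_compounds))
  }
  loadings <- as.matrix(loadings)
  if (length(centers) != length(widths) ||
      nrow(loadings) != length(centers)) {
    stop_olivenir("centers, widths and loading rows must align")
  }
  if (any(widths <= 0)) stop_olivenir("band widths must be > 0")
  structure(list(centers = as.numeric(centers), widths = as.numeric(widths),
                 loadings = loadings),
            class = "band_library")
}

default_assay_params <- function() {
  # weights in mM Trolox per (mg/g); sign patterns follow the observed
  # compound/assay correlation structure: oleuropein and hydroxytyrosol
  # drive DPPH and ORAC (hydrogen-atom transfer), verbascoside and the
  # hexoside drive ABTS (electron transfer), apigenin-7-glucoside loads
  # weakly negative on ABTS.  Intercepts place the population means at
  # 0.69 (DPPH), 0.74 (ABTS) and 2.72 (ORAC) mM Trolox; clip ranges
  # enforce the assay ranges 0.42-0.96, 0.60-0.99 and 0.94-4.10.
  list(
    DPPH = list(
      weights = c(oleuropein = 0.004, hydroxytyrosol = 0.020,
                  hydroxytyrosol_hexoside = 0.010, verbascoside = 0,
                  apigenin_7_glucoside = 0),
      intercept = 0.4275, clip = c(0.42, 0.96)),
    ABTS = list(
      weights = c(oleuropein = 0, hydroxytyrosol = 0,
                  hydroxytyrosol_hexoside = 0.012, verbascoside = 0.015,
                  apigenin_7_glucoside = -0.020),
      intercept = 0.6655, clip = c(0.60, 0.99)),
    ORAC = list(
      weights = c(oleuropein = 0.020, hydroxytyrosol = 0.100,
                  hydroxytyrosol_hexoside = 0, verbascoside = 0,
                  apigenin_7_glucoside = 0),
      intercept = 1.543, clip = c(0.94, 4.10), noise_scale = 8)
  )
}

# broad matrix absorption of the leaf powder itself (water, cellulose,
# protein): the large, compositionally stable background every NIR
# spectrum of plant material rides on.  Constant across samples; only the
# phenolic bands vary.  Amplitudes in AU.
matrix_background <- function(wn, scale = 1) {
  centers <- c(6900, 5600, 5190, 4750, 4300)
  widths <- c(400, 350, 70, 90, 55)
  amps <- c(0.40, 0.35, 1.60, 0.90, 1.20) * scale
  bg <- numeric(length(wn))
  for (b in seq_along(centers)) {
    bg <- bg + amps[b] * exp(-((wn - centers[b])^2) / (2 * widths[b]^2))
  }
  bg
}

#' Configuration for the synthetic olive-leaf data generator
#'
#' Collects every tunable of the generator in one validated object.  The
#' defaults emulate the study conditions the package is designed around:
#' 120 leaf-powder samples, log-normal phenolic concentrations with
#' oleuropein predominant, assay values that are affine in the phenolic
#' profile with the assay-specific sign pattern described in
#' [band_library()], and FT-NIR spectra on a 13,333-4000 cm^-1 grid with
#' additive baseline, multiplicative scatter and measurement noise.
#'
#' @param n_samples number of leaf samples (>= 2).
#' @param seed integer seed; every generator draws through it, so a fixed
#'   config reproduces bit-identical data.
#' @param profile_meanlog,profile_sdlog named per-compound log-normal
#'   parameters of the concentration distributions (mg/g dry leaf).
#' @param assay_params per-assay list with `weights` (mM Trolox per mg/g),
#'   `intercept` (mM), `clip` (mM range applied after noise) and optional
#'   `noise_scale` (per-assay multiplier of `noise_sd_reference`; the
#'   fluorescence-based ORAC assay defaults to 8x the noise of the
#'   absorbance assays).
#' @param noise_sd_reference measurement noise sd of the reference assays
#'   (mM Trolox).
#' @param wavenumber_start,wavenumber_end,wavenumber_step spectral grid in
#'   cm^-1 (descending from start to end; step > 0).
#' @param baseline_slope_range,baseline_offset_range uniform ranges of the
#'   per-sample linear baseline (AU over the full grid, AU).
#' @param multiplicative_scatter_sd sd of the per-sample multiplicative
#'   scatter factor around 1.
#' @param additive_scatter_sd sd of the per-sample additive offset (AU).
#' @param spectral_noise_sd per-point absorbance noise sd (AU).
#' @param matrix_background_scale amplitude multiplier of the constant
#'   leaf-matrix absorption background (water/cellulose bands) included in
#'   every clean spectrum; 0 removes the matrix entirely.
#' @param bands a [band_library()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_samples = 120,
                             seed = 1L,
                             profile_meanlog = log(c(
                               oleuropein = 35, hydroxytyrosol = 4,
                               hydroxytyrosol_hexoside = 2.5,
                               verbascoside = 4, apigenin_7_glucoside = 1.2)),
                             profile_sdlog = c(
                               oleuropein = 0.35, hydroxytyrosol = 0.40,
                               hydroxytyrosol_hexoside = 0.40,
                               verbascoside = 0.50,
                               apigenin_7_glucoside = 0.40),
                             assay_params = default_assay_params(),
                             noise_sd_reference = 0.05,
                             wavenumber_start = 13333,
                             wavenumber_end = 4000,
                             wavenumber_step = 4,
                             baseline_slope_range = c(-0.05, 0.05),
                             baseline_offset_range = c(0, 0.10),
                             multiplicative_scatter_sd = 0.05,
                             additive_scatter_sd = 0.02,
                             spectral_noise_sd = 5e-4,
                             matrix_background_scale = 1,
                             bands = band_library()) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2) {
    stop_olivenir("n_samples must be an integer >= 2")
  }
  if (wavenumber_step <= 0) stop_olivenir("wavenumber_step must be > 0")
  if (wavenumber_start <= wavenumber_end) {
    stop_olivenir("wavenumber_start must exceed wavenumber_end")
  }
  for (nm in c("noise_sd_reference", "multiplicative_scatter_sd",
               "additive_scatter_sd", "spectral_noise_sd")) {
    if (get(nm) < 0) stop_olivenir(nm, " must be >= 0")
  }
  if (!all(.olivenir_compounds %in% names(profile_meanlog)) ||
      !all(.olivenir_compounds %in% names(profile_sdlog))) {
    stop_olivenir("profile_meanlog/profile_sdlog must name all five compounds")
  }
  if (any(profile_sdlog < 0)) stop_olivenir("profile_sdlog must be >= 0")
  structure(
    list(n_samples = n_samples, seed = as.integer(seed),
         profile_meanlog = profile_meanlog[.olivenir_compounds],
         profile_sdlog = profile_sdlog[.olivenir_compounds],
         assay_params = assay_params,
         noise_sd_reference = noise_sd_reference,
         wavenumber_start = wavenumber_start,
         wavenumber_end = wavenumber_end,
         wavenumber_step = wavenumber_step,
         baseline_slope_range = baseline_slope_range,
         baseline_offset_range = baseline_offset_range,
         multiplicative_scatter_sd = multiplicative_scatter_sd,
         additive_scatter_sd = additive_scatter_sd,
         spectral_noise_sd = spectral_noise_sd,
         matrix_background_scale = matrix_background_scale,
         bands = bands),
    class = "generator_config")
}

config_wavenumbers <- function(config) {
  seq(config$wavenumber_start, config$wavenumber_end,
      by = -config$wavenumber_step)
}

#' Generate synthetic phenolic profiles
#'
#' Draws per-sample concentrations (mg/g dry leaf) of the five principal
#' olive-leaf phenolics from independent log-normal distributions.  Under
#' the defaults oleuropein is by far the most concentrated compound, as in
#' real leaf material.
#'
#' @param config a [generator_config()].
#' @return A data frame of class `phenolic_profile`: `sample_id` plus one
#'   nonnegative concentration column per compound.
#' @examples
#' profiles <- generate_profiles(generator_config(n_samples = 5, seed = 42))
#' profiles
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_samples
  conc <- withr::with_seed(config$seed, {
    vapply(.olivenir_compounds, function(cmp) {
      rlnorm(n, meanlog = config$profile_meanlog[[cmp]],
             sdlog = config$profile_sdlog[[cmp]])
    }, numeric(n))
  })
  out <- data.frame(sample_id = sprintf("sample_%03d", seq_len(n)),
                    conc, stringsAsFactors = FALSE)
  class(out) <- c("phenolic_profile", "data.frame")
  out
}

profile_matrix <- function(profiles) {
  m <- as.matrix(profiles[, .olivenir_compounds, drop = FALSE])
  rownames(m) <- profiles$sample_id
  m
}

#' Generate synthetic assay reference values
#'
#' Reference antioxidant capacity (mM Trolox) for one assay is an affine
#' function of the phenolic profile plus Gaussian measurement noise,
#' clipped to the configured assay range.  The noise is drawn as a
#' standard-normal vector scaled by `noise_sd_reference`, so holding the
#' seed fixed and increasing the noise sd rescales the same disturbances
#' rather than redrawing them.
#'
#' @param profiles a [generate_profiles()] table.
#' @param assay `"DPPH"`, `"ABTS"` or `"ORAC"`.
#' @param config a [generator_config()].
#' @return A [reference_values()] object aligned to `profiles$sample_id`.
#' @export
generate_reference_values <- function(profiles, assay, config) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(profiles) == 0) stop_olivenir("profiles is empty")
  if (!assay %in% names(config$assay_params)) {
    stop_olivenir("unknown assay '", assay, "'; configured assays: ",
                  paste(names(config$assay_params), collapse = ", "))
  }
  par <- config$assay_params[[assay]]
  w <- par$weights[.olivenir_compounds]
  w[is.na(w)] <- 0
  mu <- par$intercept + drop(profile_matrix(profiles) %*% w)
  z <- withr::with_seed(
    config$seed + 1000L + match(assay, .olivenir_assays),
    rnorm(nrow(profiles)))
  noise_sd <- config$noise_sd_reference * (par$noise_scale %||% 1)
  val <- mu + noise_sd * z
  if (!is.null(par$clip)) val <- pmin(pmax(val, par$clip[1]), par$clip[2])
  reference_values(profiles$sample_id, val, assay)
}

#' Generate synthetic NIR spectra
#'
#' Builds each clean spectrum by Beer-Lambert-style linear mixing: every
#' band in the library contributes a Gaussian profile whose amplitude is
#' the inner product of its loading vector with the sample's phenolic
#' concentrations.  The observed spectrum then receives the classical
#' scatter model `m_i * clean + a_i`, a random linear baseline and white
#' measurement noise.
#'
#' @param profiles a [generate_profiles()] table.
#' @param bands a [band_library()]; defaults to `config$bands`.
#' @param config a [generator_config()].
#' @return A [spectra_set()] on the configured wavenumber grid (descending).
#' @export
generate_spectra <- function(profiles, config, bands = config$bands) {
  stopifnot(inherits(config, "generator_config"))
  wn <- config_wavenumbers(config)
  outside <- bands$centers > max(wn) | bands$centers < min(wn)
  if (any(outside)) {
    stop_olivenir("band center ", bands$centers[which(outside)[1]],
                  " cm-1 lies outside the wavenumber grid [",
                  min(wn), ", ", max(wn), "]")
  }
  # G: n_wn x n_bands Gaussian profiles; S: n_wn x n_compounds
  G <- vapply(seq_along(bands$centers), function(b) {
    exp(-((wn - bands$centers[b])^2) / (2 * bands$widths[b]^2))
  }, numeric(length(wn)))
  S <- G %*% bands$loadings
  C <- profile_matrix(profiles)
  bg <- matrix_background(wn, config$matrix_background_scale %||% 1)
  clean <- C %*% t(S)                      # n_samples x n_wn
  clean <- sweep(clean, 2, bg, "+")        # shared leaf-matrix absorption
  n <- nrow(clean)
  obs <- withr::with_seed(config$seed + 2000L, {
    m_i <- rnorm(n, mean = 1, sd = config$multiplicative_scatter_sd)
    a_i <- rnorm(n, mean = 0, sd = config$additive_scatter_sd)
    slope <- runif(n, config$baseline_slope_range[1],
                   config$baseline_slope_range[2])
    offset <- runif(n, config$baseline_offset_range[1],
                    config$baseline_offset_range[2])
    frac <- (wn - min(wn)) / (max(wn) - min(wn))  # 0 at red end, 1 at blue
    baseline <- outer(slope, frac) + offset
    noise <- matrix(rnorm(length(clean), sd = config$spectral_noise_sd),
                    nrow = n)
    m_i * clean + a_i + baseline + noise
  })
  spectra_set(obs, wn, sample_ids = profiles$sample_id)
}

# noise-free mixed spectra (no scatter/baseline); used by tests and docs
clean_spectra <- function(profiles, config, bands = config$bands) {
  cfg <- config
  cfg$multiplicative_scatter_sd <- 0
  cfg$additive_scatter_sd <- 0
  cfg$baseline_slope_range <- c(0, 0)
  cfg$baseline_offset_range <- c(0, 0)
  cfg$spectral_noise_sd <- 0
  generate_spectra(profiles, cfg, bands)
}

#' Generate a synthetic kinetic plate-reader curve
#'
#' Emulates the signal decay recorded during an antioxidant assay: the
#' fluorescence of fluorescein under peroxyl-radical attack (ORAC) or the
#' absorbance of a colored radical being quenched (DPPH/ABTS).  The decay
#' is exponential with rate `k0 / (1 + trolox_equiv / c_half)`, so a more
#' antioxidant-rich well decays more slowly and retains a higher final
#' reading at a fixed horizon.
#'
#' @param trolox_equiv antioxidant content of the well, mM Trolox (>= 0).
#' @param mode `"fluorescence_decay"` or `"absorbance_decay"` (sets the
#'   default initial signal: 1000 RFU or 1.0 AU).
#' @param params list with `f0` (initial signal), `k0` (uninhibited decay
#'   rate, 1/s), `c_half` (mM giving half-rate), `t_end` and `dt`
#'   (seconds), `noise_sd` (signal units).
#' @param seed integer seed for the measurement noise.
#' @return A list of class `kinetic_curve` with strictly increasing `times`
#'   (s), nonnegative `signal` and the `mode`.  The first reading is the
#'   configured `f0` exactly; noise perturbs later readings only.
#' @export
generate_kinetic_curve <- function(trolox_equiv,
                                   mode = c("fluorescence_decay",
                                            "absorbance_decay"),
                                   params = list(), seed = 1L) {
  mode <- match.arg(mode)
  if (trolox_equiv < 0) {
    stop_olivenir("trolox_equiv must be >= 0, got ", trolox_equiv)
  }
  def <- list(f0 = if (mode == "fluorescence_decay") 1000 else 1.0,
              k0 = 1e-3, c_half = 0.5, t_end = 3600, dt = 300,
              noise_sd = 0)
  p <- modifyList(def, params)
  times <- seq(0, p$t_end, by = p$dt)
  if (length(times) < 2) stop_olivenir("curve needs at least 2 readings")
  rate <- p$k0 / (1 + trolox_equiv / p$c_half)
  signal <- p$f0 * exp(-rate * times)
  if (p$noise_sd > 0) {
    noise <- withr::with_seed(seed, rnorm(length(times) - 1, sd = p$noise_sd))
    signal[-1] <- pmax(signal[-1] + noise, 0)
  }
  structure(list(times = times, signal = signal, mode = mode),
            class = "kinetic_curve")
}
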