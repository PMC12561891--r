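test_that("profile generation is sized, seeded and distribution-faithful", {
  cfg <- generator_config(n_samples = 120, seed = 1)
  p <- generate_profiles(cfg)
  expect_equal(nrow(p), 120)
  expect_setequal(names(p), c("sample_id", "oleuropein", "hydroxytyrosol",
                              "hydroxytyrosol_hexoside", "verbascoside",
                              "apigenin_7_glucoside"))
  expect_true(all(as.matrix(p[, -1]) >= 0))
  # oleuropein dominates under defaults
  means <- colMeans(p[, -1])
  expect_equal(names(which.max(means)), "oleuropein")
  # fixed seed: bit-identical
  expect_identical(p, generate_profiles(cfg))
  # degenerate distributions collapse to the point mass
  cfg0 <- generator_config(n_samples = 5, seed = 3,
                           profile_sdlog = setNames(rep(0, 5),
                             names(cfg$profile_sdlog)))
  p0 <- generate_profiles(cfg0)
  for (cmp in names(cfg$profile_meanlog)) {
    expect_equal(p0[[cmp]], rep(exp(cfg$profile_meanlog[[cmp]]), 5))
  }
  expect_error(generator_config(n_samples = 1), "n_samples")
})

test_that("reference values are affine in profiles, clipped, and seeded", {
  cfg <- small_config(seed = 2, n_samples = 30)
  p <- generate_profiles(cfg)
  # identity weighting with zero noise returns the oleuropein column
  cfg_id <- cfg
  cfg_id$noise_sd_reference <- 0
  cfg_id$assay_params$DPPH <- list(
    weights = c(oleuropein = 1), intercept = 0, clip = NULL)
  y <- generate_reference_values(p, "DPPH", cfg_id)
  expect_equal(y$value, p$oleuropein)
  expect_identical(y$value,
                   generate_reference_values(p, "DPPH", cfg_id)$value)
  # with zero noise the affine map is exactly recoverable by least squares
  cfg0 <- cfg
  cfg0$noise_sd_reference <- 0
  cfg0$assay_params$ABTS$clip <- NULL
  y0 <- generate_reference_values(p, "ABTS", cfg0)
  fit <- lm(y0$value ~ p$hydroxytyrosol_hexoside + p$verbascoside +
              p$apigenin_7_glucoside)
  expect_equal(unname(coef(fit)),
               c(cfg0$assay_params$ABTS$intercept,
                 unname(cfg0$assay_params$ABTS$weights[
                   c("hydroxytyrosol_hexoside", "verbascoside",
                     "apigenin_7_glucoside")])),
               tolerance = 1e-8)
  expect_error(generate_reference_values(p, "FRAP", cfg), "unknown assay")
})

test_that("default DPPH values for the full design stay in the assay range", {
  cfg <- generator_config(n_samples = 120, seed = 1, wavenumber_step = 64)
  p <- generate_profiles(cfg)
  y <- generate_reference_values(p, "DPPH", cfg)
  expect_true(all(y$value >= 0.42 & y$value <= 0.96))
})

test_that("spectra follow the linear band-mixing + scatter model", {
  cfg <- small_config(seed = 4, n_samples = 6,
                      multiplicative_scatter_sd = 0,
                      additive_scatter_sd = 0,
                      baseline_slope_range = c(0, 0),
                      baseline_offset_range = c(0, 0),
                      spectral_noise_sd = 0,
                      matrix_background_scale = 0)
  p <- generate_profiles(cfg)
  # zero concentrations + zero background/noise -> all-zero spectra
  p0 <- p
  for (cmp in setdiff(names(p), "sample_id")) p0[[cmp]] <- 0
  s0 <- generate_spectra(p0, cfg)
  expect_equal(max(abs(s0$absorbance)), 0)
  # axis descending and finite always
  sp <- generate_spectra(p, cfg)
  expect_true(all(diff(sp$wavenumbers) < 0))
  expect_true(all(is.finite(sp$absorbance)))
  # fixed seed reproducibility
  expect_identical(sp$absorbance, generate_spectra(p, cfg)$absorbance)
  # band centers outside the grid are refused by name
  cfg_bad <- cfg
  cfg_bad$wavenumber_end <- 6000
  expect_error(generate_spectra(p, cfg_bad), "5785")
})

test_that("mean phenolic-only spectrum peaks at a library band center", {
  cfg <- generator_config(n_samples = 30, seed = 5, wavenumber_step = 4,
                          matrix_background_scale = 0,
                          multiplicative_scatter_sd = 0,
                          additive_scatter_sd = 0,
                          baseline_slope_range = c(0, 0),
                          baseline_offset_range = c(0, 0),
                          spectral_noise_sd = 0)
  p <- generate_profiles(cfg)
  sp <- generate_spectra(p, cfg)
  peak_wn <- sp$wavenumbers[which.max(colMeans(sp$absorbance))]
  centers <- band_library()$centers
  expect_lte(min(abs(peak_wn - centers)), cfg$wavenumber_step)
})

test_that("known multiplicative/additive scatter is inverted by MSC", {
  cfg <- small_config(seed = 6, n_samples = 5, spectral_noise_sd = 0,
                      multiplicative_scatter_sd = 0, additive_scatter_sd = 0,
                      baseline_slope_range = c(0, 0),
                      baseline_offset_range = c(0, 0))
  p <- generate_profiles(cfg)
  clean <- generate_spectra(p, cfg)
  distorted <- spectra_set(2 * clean$absorbance + 1, clean$wavenumbers,
                           clean$sample_ids)
  ref <- colMeans(clean$absorbance)
  recovered <- msc(distorted, reference = ref)
  # the imposed (a = 1, b = 2) distortion cancels exactly: correcting the
  # distorted set equals correcting the clean set itself
  expect_lt(max(abs(recovered$absorbance -
                    msc(clean, reference = ref)$absorbance)), 1e-8)
})

test_that("kinetic curves decay, honor F0, and slow down with antioxidant", {
  k0 <- generate_kinetic_curve(0, params = list(noise_sd = 0))
  expect_lt(tail(k0$signal, 1), k0$signal[1])          # uninhibited decay
  expect_identical(k0$signal[1], 1000)                 # F0 exact
  expect_true(all(diff(k0$signal) <= 0))
  expect_true(all(diff(k0$times) > 0))
  f_low <- tail(generate_kinetic_curve(0.1, params = list(noise_sd = 0))$signal, 1)
  f_high <- tail(generate_kinetic_curve(1.0, params = list(noise_sd = 0))$signal, 1)
  # oracle: evaluate the decay law F0 * exp(-k0 t / (1 + c/c_half)) directly
  law <- function(c) 1000 * exp(-1e-3 * 3600 / (1 + c / 0.5))
  expect_equal(f_low, law(0.1))
  expect_equal(f_high, law(1.0))
  expect_gt(f_high, f_low)
  expect_error(generate_kinetic_curve(-0.5), "trolox_equiv")
  # noisy curves are seeded and nonnegative
  n1 <- generate_kinetic_curve(0.2, params = list(noise_sd = 50), seed = 9)
  n2 <- generate_kinetic_curve(0.2, params = list(noise_sd = 50), seed = 9)
  expect_identical(n1$signal, n2$signal)
  expect_true(all(n1$signal >= 0))
})
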