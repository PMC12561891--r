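test_that("rmse follows its definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2))
  set.seed(51)
  f <- rnorm(10); y <- rnorm(10)
  perm <- sample(10)
  expect_equal(rmse(f, y), rmse(f[perm], y[perm]))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(1:3, 1:2), "lengths")
})

test_that("rpd is the sd-to-rmse ratio with an infinite guard", {
  expect_equal(rpd(0.5, 0.25), 2)
  expect_equal(rpd(0.3, 0.3), 1)
  expect_equal(rpd(1.0, 0.25), 2 * rpd(0.5, 0.25))
  expect_warning(v <- rpd(0.5, 0), "Inf")
  expect_identical(v, Inf)
  # monotone: inflating residuals can only lower the RPD
  set.seed(52)
  obs <- rnorm(30)
  res <- rnorm(30, sd = 0.2)
  rpds <- vapply(c(0.5, 1, 2, 4), function(k)
    rpd(sd(obs), rmse(obs + k * res, obs)), numeric(1))
  expect_true(all(diff(rpds) < 0))
})

test_that("RPD bands match the quality-control interpretation", {
  expect_equal(interpret_rpd(3.01), "quality control")
  expect_equal(interpret_rpd(3.0), "quality control")
  expect_equal(interpret_rpd(2.69), "screening")
  expect_equal(interpret_rpd(2.0), "screening")
  expect_equal(interpret_rpd(1.5), "not recommended")
  expect_error(interpret_rpd(0), "positive")
  expect_error(interpret_rpd(-1), "positive")
})

test_that("observed-predicted diagnostics match the least-squares oracle", {
  obs <- c(1, 2, 3, 4, 5)
  f <- observed_predicted_fit(obs, obs)
  expect_equal(c(f$slope, f$intercept, f$r_squared), c(1, 0, 1))
  f2 <- observed_predicted_fit(obs, 2 * obs)
  expect_equal(c(f2$slope, f2$intercept), c(2, 0))
  set.seed(53)
  o <- rnorm(40); pr <- 0.8 * o + rnorm(40, sd = 0.3)
  f3 <- observed_predicted_fit(o, pr)
  ref <- lm(pr ~ o)
  expect_equal(f3$slope, unname(coef(ref)[2]))
  expect_equal(f3$intercept, unname(coef(ref)[1]))
  expect_equal(f3$r_squared, summary(ref)$r.squared)
  expect_error(observed_predicted_fit(rep(1, 5), rnorm(5)), "variance")
  expect_error(observed_predicted_fit(1:2, 1:2), "3")
})

test_that("evaluate_model reports all sets and guards against leakage", {
  cfg <- generator_config(n_samples = 40, seed = 54, wavenumber_step = 32,
                          noise_sd_reference = 0.001)
  p <- generate_profiles(cfg)
  sp <- generate_spectra(p, cfg)
  y <- generate_reference_values(p, "DPPH", cfg)
  rep <- evaluate_model(sp, y, "SNV-2.19.5", cv_scheme = cv_kfold(5, 1),
                        max_lv = 8)
  expect_named(rep$sets, c("calibration", "cv", "prediction"))
  # near-noise-free synthetic data is predicted almost perfectly
  expect_gt(rep$sets$prediction$r_squared, 0.95)
  # audit: the training ids exclude every prediction sample
  expect_length(intersect(rep$training_ids, rep$split$prediction_ids), 0)
  # paper mode trains on everything instead
  rep_l <- evaluate_model(sp, y, "SNV-2.19.5", split = rep$split,
                          cv_scheme = cv_kfold(5, 1), max_lv = 8,
                          paper_mode = TRUE)
  expect_setequal(rep_l$training_ids,
                  c(rep$split$cv_ids, rep$split$prediction_ids))
  # full-complexity calibration interpolates: R2 = 1, RMSEC ~ 0
  rep_f <- evaluate_model(sp, y, "SNV-2.19.5", split = rep$split,
                          n_latent = length(rep$split$cv) - 1)
  expect_equal(rep_f$sets$calibration$r_squared, 1, tolerance = 1e-8)
  expect_lt(rep_f$sets$calibration$rmse, 1e-8)
})

test_that("evaluation reports serialize losslessly", {
  cfg <- generator_config(n_samples = 16, seed = 55, wavenumber_step = 64)
  p <- generate_profiles(cfg)
  sp <- generate_spectra(p, cfg)
  y <- generate_reference_values(p, "ABTS", cfg)
  rep <- evaluate_model(sp, y, "MSC-1.19.5", cv_scheme = cv_kfold(4, 2),
                        max_lv = 5, fraction = 0.7)
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  back <- read_report_json(path)
  expect_equal(back$code, rep$code)
  expect_equal(back$selected_lv, rep$selected_lv)
  for (s in names(rep$sets)) {
    expect_equal(back$sets[[s]]$rmse, rep$sets[[s]]$rmse, tolerance = 0)
    expect_equal(back$sets[[s]]$rpd, rep$sets[[s]]$rpd, tolerance = 0)
  }
  expect_identical(back$training_ids, rep$training_ids)
})

test_that("grid search covers the default codes and ranks deterministically", {
  expect_setequal(default_pretreatment_codes(),
                  c("MSC-1.19.5", "SNV-2.13.9", "MSC-2.19.5", "SNV-2.19.5",
                    "SNV-2.5.19", "MSC-2.5.19"))
  expect_length(default_pretreatment_codes(), 6)
  cfg <- generator_config(n_samples = 30, seed = 56, wavenumber_step = 32,
                          noise_sd_reference = 0.002)
  p <- generate_profiles(cfg)
  sp <- generate_spectra(p, cfg)
  y <- generate_reference_values(p, "DPPH", cfg)
  # single code: a rank list of one
  g1 <- grid_search(sp, y, codes = "SNV-2.19.5",
                    cv_scheme = cv_kfold(4, 1), max_lv = 6)
  expect_equal(nrow(g1$ranking), 1)
  # a genuinely better code ranks first: compare a real pretreatment with
  # a derivative wide enough to flatten the analyte bands away
  g2 <- grid_search(sp, y, codes = c("SNV-2.121.121", "SNV-2.19.5"),
                    cv_scheme = cv_kfold(4, 1), max_lv = 6)
  expect_equal(g2$ranking$code[1], "SNV-2.19.5")
  expect_true(all(diff(g2$ranking$rpd_p) <= 0))
  # deterministic reruns
  g3 <- grid_search(sp, y, codes = c("SNV-2.121.121", "SNV-2.19.5"),
                    cv_scheme = cv_kfold(4, 1), max_lv = 6)
  expect_identical(g2$ranking, g3$ranking)
})
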