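test_that("spectra_set enforces its invariants", {
  wn <- seq(8000, 7910, by = -10)
  x <- matrix(1:20, nrow = 2)
  expect_s3_class(spectra_set(x, wn), "spectra_set")
  expect_error(spectra_set(x, rev(wn)), "descending")
  expect_error(spectra_set(x, wn[-1]), "columns")
  xna <- x; xna[2, 3] <- NA
  expect_error(spectra_set(xna, wn), "row 2, column 3")
  expect_error(spectra_set(x, wn, sample_ids = c("a", "a")), "duplicate")
})

test_that("Savitzky-Golay reproduces polynomials and their derivatives", {
  # rows sample 1 + 2v + 3v^2 and 5 - v + 0.5v^2 on the wavenumber axis
  sp <- poly_spectra(list(c(1, 2, 3), c(5, -1, 0.5)))
  wn <- sp$wavenumbers
  interior <- 3:(length(wn) - 2)  # window-5 edges excluded
  # smoothing (deriv 0) preserves degree-2 polynomials everywhere
  sm <- savitzky_golay(sp, window = 5, polyorder = 2, deriv_order = 0)
  expect_equal(sm$absorbance, sp$absorbance, tolerance = 1e-8)
  # analytic first derivatives: 2 + 6v and -1 + v
  d1 <- savitzky_golay(sp, window = 5, polyorder = 2, deriv_order = 1)
  expect_equal(unname(d1$absorbance[1, interior]),
               unname(2 + 6 * wn[interior]),
               tolerance = 1e-6)
  expect_equal(unname(d1$absorbance[2, interior]),
               unname(-1 + wn[interior]),
               tolerance = 1e-6)
  # analytic second derivatives: constants 6 and 1
  d2 <- savitzky_golay(sp, window = 5, polyorder = 2, deriv_order = 2)
  expect_equal(unname(d2$absorbance[1, interior]), rep(6, length(interior)),
               tolerance = 1e-6)
  expect_equal(unname(d2$absorbance[2, interior]), rep(1, length(interior)),
               tolerance = 1e-6)
  expect_error(savitzky_golay(sp, window = 4), "odd")
  expect_error(savitzky_golay(sp, window = 5, polyorder = 2,
                              deriv_order = 3), "deriv_order")
  # non-uniform grids are refused
  wn_bad <- c(5000, 4996, 4991, 4980)
  sp_bad <- spectra_set(matrix(rnorm(8), 2), wn_bad)
  expect_error(savitzky_golay(sp_bad, 3), "uniform")
})

test_that("SNV centers and scales rows, idempotently", {
  sp <- spectra_set(rbind(c(1, 2, 3), c(10, 30, 50)), c(100, 90, 80))
  out <- snv(sp)
  expect_equal(out$absorbance[1, ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(unname(rowMeans(out$absorbance)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(out$absorbance, 1, sd)), c(1, 1),
               tolerance = 1e-12)
  expect_equal(snv(out)$absorbance, out$absorbance, tolerance = 1e-12)
  # invariant to positive affine transforms of each row
  sp2 <- spectra_set(3.7 * sp$absorbance + 11, sp$wavenumbers,
                     sp$sample_ids)
  expect_equal(snv(sp2)$absorbance, out$absorbance, tolerance = 1e-12)
  sp_const <- spectra_set(rbind(c(1, 2, 3), c(4, 4, 4)), c(100, 90, 80),
                          sample_ids = c("ok", "flat"))
  expect_error(snv(sp_const), "flat")
})

test_that("MSC inverts affine scatter against the reference", {
  set.seed(21)
  wn <- seq(6000, by = -10, length.out = 20)
  ref <- exp(-((wn - 5900)^2) / (2 * 100^2)) + 0.3
  a <- runif(5, -0.5, 0.5); b <- runif(5, 0.5, 2)
  sp <- spectra_set(outer(a, rep(1, 20)) + b %o% ref, wn)
  out <- msc(sp, reference = ref)
  expect_equal(out$absorbance, matrix(ref, 5, 20, byrow = TRUE),
               ignore_attr = TRUE, tolerance = 1e-10)
  # the reference itself maps to itself (a = 0, b = 1)
  self <- msc(spectra_set(rbind(ref, ref + 0.1), wn), reference = ref)
  expect_equal(self$absorbance[1, ], ref, ignore_attr = TRUE,
               tolerance = 1e-10)
  # refit oracle: corrected rows regressed on the reference give a=0, b=1
  rough <- spectra_set(sp$absorbance + matrix(rnorm(100, sd = 0.01), 5), wn)
  corr <- msc(rough, reference = ref)
  for (r in seq_len(5)) {
    fit <- lm(corr$absorbance[r, ] ~ ref)
    expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-10)
  }
})

test_that("pretreatment codes parse, validate, and round-trip", {
  spec <- parse_pretreatment_code("MSC-1.19.5")
  expect_equal(spec$scatter, "MSC")
  expect_equal(spec$deriv_order, 1L)
  expect_equal(spec$deriv_window, 19L)
  expect_equal(spec$smooth_window, 5L)
  spec2 <- parse_pretreatment_code("SNV-2.5.19")
  expect_equal(spec2$scatter, "SNV")
  expect_equal(spec2$deriv_window, 5L)
  expect_equal(spec2$smooth_window, 19L)
  for (code in default_pretreatment_codes()) {
    expect_identical(format(parse_pretreatment_code(code)), code)
  }
  expect_error(parse_pretreatment_code("ABC-9.9"), "malformed")
  expect_error(parse_pretreatment_code("SNV-3.5.5"), "derivative order")
  expect_error(parse_pretreatment_code("SNV-1.4.5"), "odd")
  expect_error(parse_pretreatment_code("SNV-1.5.6"), "odd")
})

test_that("pretreatment pipelines compose derivative, smoothing, scatter", {
  sp <- toy_spectra(n = 5, n_wn = 60)
  # identity spec changes nothing
  raw <- apply_pretreatment(sp, pretreatment_spec())
  expect_equal(raw$absorbance, sp$absorbance)
  # pipeline equals the manual stage-by-stage composition
  out <- apply_pretreatment(sp, "SNV-2.19.5")
  manual <- snv(savitzky_golay(savitzky_golay(sp, 19, 2, 2), 5, 2, 0))
  expect_equal(out$absorbance, manual$absorbance)
  # scatter last: every output row is standardized
  expect_equal(unname(rowMeans(out$absorbance)), rep(0, 5),
               tolerance = 1e-12)
  expect_equal(unname(apply(out$absorbance, 1, sd)), rep(1, 5),
               tolerance = 1e-12)
  # sample order, ids and axis survive every pretreatment
  for (code in c("MSC-1.19.5", "SNV-2.5.19")) {
    pt <- apply_pretreatment(sp, code)
    expect_identical(pt$sample_ids, sp$sample_ids)
    expect_identical(pt$wavenumbers, sp$wavenumbers)
  }
  # scatter-first ordering is available and differs in general
  sf <- apply_pretreatment(sp, "SNV-2.19.5", scatter_first = TRUE)
  expect_false(isTRUE(all.equal(sf$absorbance, out$absorbance)))
  # stage failures carry the stage name
  tiny <- spectra_set(matrix(rnorm(8), 2), c(100, 90, 80, 70))
  expect_error(apply_pretreatment(tiny, "SNV-2.19.5"), "derivative")
})
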