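# Shared fixtures: tiny spectra sets and small generator configs, built in
# code so the suite needs no data files.

# small, fast generator config: coarse grid keeps matrices light
small_config <- function(seed = 1, n_samples = 20, step = 64, ...) {
  generator_config(n_samples = n_samples, seed = seed,
                   wavenumber_step = step, ...)
}

# deterministic toy spectra: rows are smooth functions on a descending grid
toy_spectra <- function(n = 4, n_wn = 40, wn_hi = 8000, step = 10) {
  wn <- seq(wn_hi, by = -step, length.out = n_wn)
  x <- t(vapply(seq_len(n), function(i) {
    i * exp(-((wn - 6000)^2) / (2 * 300^2)) + 0.01 * i * wn / 1000
  }, numeric(n_wn)))
  spectra_set(x, wn)
}

# spectra whose rows sample a polynomial of the wavenumber (for SG oracles)
poly_spectra <- function(coefs, n_wn = 41, wn_hi = 5000, step = 5) {
  wn <- seq(wn_hi, by = -step, length.out = n_wn)
  x <- matrix(0, length(coefs), n_wn)
  for (r in seq_along(coefs)) {
    x[r, ] <- vapply(wn, function(v)
      sum(coefs[[r]] * v^(seq_along(coefs[[r]]) - 1)), numeric(1))
  }
  spectra_set(x, wn)
}

# independent brute-force Kennard-Stone following the greedy definition;
# used as the oracle for small n
ks_brute <- function(X, k) {
  X <- as.matrix(X)
  D <- as.matrix(dist(sweep(X, 2, colMeans(X))))
  n <- nrow(X)
  best <- NULL
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (is.null(best) || D[i, j] > D[best[1], best[2]] + 1e-15) best <- c(i, j)
  }
  sel <- best
  while (length(sel) < k) {
    rem <- setdiff(seq_len(n), sel)
    dmin <- vapply(rem, function(r) min(D[r, sel]), numeric(1))
    sel <- c(sel, rem[which.max(dmin)])
  }
  sel
}
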