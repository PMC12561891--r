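#' Fit a single-response PLS regression by NIPALS
#'
#' Centered partial least squares regression with one response.  Each
#' latent variable (LV) takes the weight direction maximizing covariance
#' between the deflated spectra and the deflated response, then both
#' blocks are deflated by the extracted score.  Extraction stops early
#' (with fewer LVs than requested) once the residual covariance or score
#' norm falls below tolerance, i.e. when the centered X-block rank or the
#' predictable part of y is exhausted.
#'
#' @param X a [spectra_set()] or numeric matrix (rows = samples).
#' @param y a [reference_values()] object aligned by sample id, or a
#'   numeric vector in row order.
#' @param n_latent number of latent variables to extract,
#'   `1 <= n_latent <= min(n - 1, p)`.
#' @param center center X columns and y (default `TRUE`; standard for
#'   spectra).
#' @param scale divide X columns by their standard deviation (default
#'   `FALSE`; scatter-corrected spectra are already commensurate).
#' @param tol relative tolerance for early stopping.
#' @return A list of class `pls_model`: `n_latent` (LVs actually
#'   extracted), `x_mean`, `x_scale`, `y_mean`, `weights` (p x A),
#'   `loadings` (p x A), `y_loadings` (A), `scores` (n x A),
#'   `coefficients` (p, at `n_latent`), `wavenumbers`, `sample_ids`,
#'   `fitted`.
#' @export
fit_pls <- function(X, y, n_latent, center = TRUE, scale = FALSE,
                    tol = 1e-12) {
  wn <- NULL; ids <- NULL
  if (inherits(X, "spectra_set")) {
    y <- align_reference(y, X)
    wn <- X$wavenumbers
    ids <- X$sample_ids
    X <- X$absorbance
  } else {
    X <- as.matrix(X)
    if (inherits(y, "reference_values")) y <- y$value
    y <- as.numeric(y)
    if (length(y) != nrow(X)) stop_olivenir("X and y sizes differ")
  }
  n <- nrow(X); p <- ncol(X)
  n_latent <- as.integer(n_latent)
  max_admissible <- min(n - 1, p)
  if (n_latent < 1 || n_latent > max_admissible) {
    stop_olivenir("n_latent must lie in [1, ", max_admissible,
                  "] for ", n, " samples x ", p, " variables; got ",
                  n_latent)
  }
  x_mean <- if (center) colMeans(X) else rep(0, p)
  y_mean <- if (center) mean(y) else 0
  x_scale <- if (scale) {
    s <- apply(X, 2, sd)
    s[s == 0] <- 1
    s
  } else rep(1, p)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  yc <- y - y_mean

  W <- matrix(0, p, n_latent)
  P <- matrix(0, p, n_latent)
  Tm <- matrix(0, n, n_latent)
  q <- numeric(n_latent)
  x_norm0 <- sqrt(sum(Xc^2))
  y_norm0 <- sqrt(sum(yc^2))
  a_done <- 0L
  for (a in seq_len(n_latent)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw <= tol * max(x_norm0 * y_norm0, 1)) break
    w <- w / nw
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    if (tt <= (tol * max(x_norm0, 1))^2) break
    p_a <- drop(crossprod(Xc, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    a_done <- a
  }
  if (a_done == 0L) {
    # y carries no X-predictable signal (e.g. constant y): the mean model
    model <- structure(
      list(n_latent = 1L, x_mean = x_mean, x_scale = x_scale,
           y_mean = y_mean, weights = W[, 1, drop = FALSE],
           loadings = P[, 1, drop = FALSE], y_loadings = 0,
           scores = Tm[, 1, drop = FALSE], wavenumbers = wn,
           sample_ids = ids, centered = center, scaled = scale,
           null_model = TRUE),
      class = "pls_model")
    model$coefficients <- rep(0, p)
    model$fitted <- rep(y_mean, n)
    return(model)
  }
  W <- W[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  Tm <- Tm[, seq_len(a_done), drop = FALSE]
  q <- q[seq_len(a_done)]
  model <- structure(
    list(n_latent = a_done, x_mean = x_mean, x_scale = x_scale,
         y_mean = y_mean, weights = W, loadings = P, y_loadings = q,
         scores = Tm, wavenumbers = wn, sample_ids = ids,
         centered = center, scaled = scale),
    class = "pls_model")
  model$coefficients <- pls_coefficients(model, a_done)
  model$fitted <- y_mean +
    drop(sweep(sweep(X, 2, x_mean), 2, x_scale, "/") %*% model$coefficients)
  model
}

#' Regression coefficients of a PLS model at a given complexity
#'
#' @param model a [fit_pls()] model.
#' @param ncomp number of latent variables to use (default: all extracted).
#' @return Numeric coefficient vector over wavelengths (on the centered,
#'   scaled X scale).
#' @export
pls_coefficients <- function(model, ncomp = model$n_latent) {
  if (ncomp < 1 || ncomp > model$n_latent) {
    stop_olivenir("ncomp must lie in [1, ", model$n_latent, "]")
  }
  if (isTRUE(model$null_model)) return(rep(0, nrow(model$weights)))
  idx <- seq_len(ncomp)
  W <- model$weights[, idx, drop = FALSE]
  P <- model$loadings[, idx, drop = FALSE]
  drop(W %*% solve(crossprod(P, W), model$y_loadings[idx]))
}

#' Predict from a PLS model
#'
#' The prediction is the affine map
#' `y_mean + (x - x_mean) / x_scale %*% coefficients`.  When both the
#' model and the new data carry a wavenumber axis they must match exactly.
#'
#' @param object a [fit_pls()] model.
#' @param newdata a [spectra_set()] or numeric matrix.
#' @param ncomp latent variables to use (default: all extracted).
#' @param ... unused.
#' @return Numeric vector of predicted values.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$n_latent,
                              ...) {
  if (inherits(newdata, "spectra_set")) {
    if (!is.null(object$wavenumbers)) {
      if (length(newdata$wavenumbers) != length(object$wavenumbers) ||
          any(newdata$wavenumbers != object$wavenumbers)) {
        d <- if (length(newdata$wavenumbers) == length(object$wavenumbers))
          which(newdata$wavenumbers != object$wavenumbers)[1] else 1L
        stop_olivenir(
          "wavenumber axis of new spectra does not match the training ",
          "axis; first difference at position ", d, " (training ",
          object$wavenumbers[min(d, length(object$wavenumbers))],
          " vs new ", newdata$wavenumbers[min(d, length(newdata$wavenumbers))],
          " cm-1)")
      }
    }
    newdata <- newdata$absorbance
  }
  newdata <- as.matrix(newdata)
  b <- pls_coefficients(object, ncomp)
  Xc <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_scale, "/")
  drop(object$y_mean + Xc %*% b)
}

#' Cross-validation schemes
#'
#' `cv_loo()` is deterministic leave-one-out; `cv_kfold(k, seed)` shuffles
#' samples once with the given seed and deals them into `k` folds.
#'
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @return A list describing the scheme, for [cross_validate()].
#' @export
cv_loo <- function() structure(list(type = "loo"), class = "cv_scheme")

#' @rdname cv_loo
#' @export
cv_kfold <- function(k, seed = 1L) {
  if (k < 2) stop_olivenir("k-fold needs k >= 2")
  structure(list(type = "kfold", k = as.integer(k), seed = as.integer(seed)),
            class = "cv_scheme")
}

cv_folds <- function(scheme, n) {
  if (scheme$type == "loo") return(as.list(seq_len(n)))
  if (scheme$k > n) {
    stop_olivenir("fold count ", scheme$k, " exceeds sample count ", n)
  }
  perm <- withr::with_seed(scheme$seed, sample.int(n))
  split(perm, rep_len(seq_len(scheme$k), n))
}

#' Cross-validated latent-variable selection
#'
#' Computes RMSECV for every LV count from 1 to `max_lv` using held-out
#' predictions only: each fold's model is fit on the remaining samples and
#' produces predictions at every complexity.  The selected LV count is the
#' smallest one whose RMSECV is within `1e-12` of the minimum.
#'
#' @param X a [spectra_set()] or matrix.
#' @param y reference values aligned to `X`.
#' @param max_lv maximum LV count to consider; silently capped at the
#'   largest complexity every training fold supports.
#' @param scheme [cv_loo()] (default) or [cv_kfold()].
#' @param center,scale passed to [fit_pls()].
#' @return A list of class `cv_curve`: `rmsecv` (per LV), `selected_lv`,
#'   `predictions` (n x max_lv held-out prediction matrix), `n_refits`
#'   (number of model fits performed), `scheme`.
#' @export
cross_validate <- function(X, y, max_lv = 20, scheme = cv_loo(),
                           center = TRUE, scale = FALSE) {
  if (inherits(X, "spectra_set")) {
    y <- align_reference(y, X)
    Xm <- X$absorbance
  } else {
    Xm <- as.matrix(X)
    if (inherits(y, "reference_values")) y <- y$value
  }
  n <- nrow(Xm)
  folds <- cv_folds(scheme, n)
  min_train <- n - max(lengths(folds))
  A <- min(max_lv, min_train - 1, ncol(Xm))
  if (A < 1) stop_olivenir("not enough samples for cross-validation")
  pred <- matrix(NA_real_, n, A)
  n_refits <- 0L
  for (fold in folds) {
    train <- setdiff(seq_len(n), fold)
    fit <- fit_pls(Xm[train, , drop = FALSE], y[train], n_latent = A,
                   center = center, scale = scale)
    n_refits <- n_refits + 1L
    for (a in seq_len(A)) {
      a_use <- min(a, fit$n_latent)  # early-stopped fits reuse their max
      pred[fold, a] <- predict(fit, Xm[fold, , drop = FALSE],
                               ncomp = a_use)
    }
  }
  rmsecv <- vapply(seq_len(A), function(a) rmse(pred[, a], y), numeric(1))
  selected <- which(rmsecv <= min(rmsecv) + 1e-12)[1]
  structure(list(rmsecv = rmsecv, selected_lv = selected,
                 predictions = pred, n_refits = n_refits, scheme = scheme),
            class = "cv_curve")
}

#' Serialize / reload a PLS model as JSON
#'
#' Writes the axis, centering terms, per-LV weights/loadings and
#' coefficients at full double precision so that a reloaded model
#' reproduces predictions exactly.
#'
#' @param model a [fit_pls()] model.
#' @param path JSON file path.
#' @return `write_pls_model` returns `path` invisibly; `read_pls_model`
#'   returns the `pls_model`.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  payload <- list(
    n_latent = model$n_latent, x_mean = model$x_mean,
    x_scale = model$x_scale, y_mean = model$y_mean,
    weights = model$weights, loadings = model$loadings,
    y_loadings = model$y_loadings, coefficients = model$coefficients,
    wavenumbers = model$wavenumbers, sample_ids = model$sample_ids,
    centered = model$centered, scaled = model$scaled)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(
    n_latent = as.integer(d$n_latent), x_mean = as.numeric(d$x_mean),
    x_scale = as.numeric(d$x_scale), y_mean = as.numeric(d$y_mean),
    weights = as.matrix(d$weights), loadings = as.matrix(d$loadings),
    y_loadings = as.numeric(d$y_loadings),
    coefficients = as.numeric(d$coefficients),
    wavenumbers = if (is.null(d$wavenumbers)) NULL
                  else as.numeric(d$wavenumbers),
    sample_ids = d$sample_ids, centered = isTRUE(d$centered),
    scaled = isTRUE(d$scaled))
  class(model) <- "pls_model"
  model
}
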