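#' Kennard-Stone sample selection
#'
#' Greedy max-min selection on Euclidean distances between spectra: the
#' first two picks are the farthest pair, and every subsequent pick
#' maximizes its minimum distance to the already-selected samples.  The
#' procedure is deterministic; exact distance ties are broken towards the
#' lowest sample index.
#'
#' @param spectra a [spectra_set()] or a numeric matrix (rows = samples).
#' @param k number of samples to select, `2 <= k <= n`.
#' @param center subtract the mean spectrum before computing distances
#'   (default `TRUE`; mean-centering does not change Euclidean distances
#'   between rows but keeps the convention explicit and configurable).
#' @return Integer vector of length `k`: selected row indices in selection
#'   order.
#' @export
kennard_stone <- function(spectra, k, center = TRUE) {
  X <- if (inherits(spectra, "spectra_set")) spectra$absorbance
       else as.matrix(spectra)
  n <- nrow(X)
  if (k < 2 || k > n) {
    stop_olivenir("k must satisfy 2 <= k <= n (k = ", k, ", n = ", n, ")")
  }
  if (center) X <- sweep(X, 2, colMeans(X))
  D <- as.matrix(dist(X))
  # farthest pair; ties -> lexicographically smallest (i, j), i < j
  mx <- max(D)
  cand <- which(D == mx, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  selected <- c(cand[1, 1], cand[1, 2])
  remaining <- setdiff(seq_len(n), selected)
  while (length(selected) < k) {
    dmin <- apply(D[remaining, selected, drop = FALSE], 1, min)
    pick <- remaining[which.max(dmin)]  # first max = lowest index
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Split samples into cross-validation and prediction sets
#'
#' Applies [kennard_stone()] to pick `round(fraction * n)` representative
#' samples as the cross-validation set (Set 1); the remainder forms the
#' external prediction set (Set 2).  Set 1+2 denotes all samples.
#'
#' @param spectra a [spectra_set()] (typically already pretreated; the
#'   Euclidean distances are computed on whatever is passed in).
#' @param fraction fraction assigned to the cross-validation set,
#'   strictly between 0 and 1 (default 0.7).
#' @param center passed to [kennard_stone()].
#' @return A list of class `split_result` with integer index fields `all`,
#'   `cv`, `prediction` and matching id fields `cv_ids`, `prediction_ids`.
#' @examples
#' cfg <- generator_config(n_samples = 10, seed = 7, wavenumber_step = 64)
#' sp <- generate_spectra(generate_profiles(cfg), cfg)
#' split_sets(sp, 0.7)
#' @export
split_sets <- function(spectra, fraction = 0.7, center = TRUE) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop_olivenir("fraction must lie strictly between 0 and 1")
  }
  n <- nrow(spectra$absorbance)
  k <- round(fraction * n)
  if (k < 2 || k > n - 1) {
    stop_olivenir("fraction ", fraction, " leaves a degenerate split for n = ",
                  n, " (cv size ", k, ")")
  }
  cv <- sort(kennard_stone(spectra, k, center = center))
  pred <- setdiff(seq_len(n), cv)
  structure(
    list(all = seq_len(n), cv = cv, prediction = pred,
         cv_ids = spectra$sample_ids[cv],
         prediction_ids = spectra$sample_ids[pred]),
    class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("split_result: ", length(x$all), " samples = ", length(x$cv),
      " cross-validation (Set 1) + ", length(x$prediction),
      " prediction (Set 2)\n", sep = "")
  invisible(x)
}

#' Write / read a sample split as CSV
#'
#' Two columns: `sample_id` and `set` (`"cv"` or `"prediction"`).
#'
#' @param split a [split_sets()] result.
#' @param path CSV file path.
#' @return `write_split_csv` returns `path` invisibly; `read_split_csv`
#'   returns a data frame with columns `sample_id`, `set`.
#' @export
write_split_csv <- function(split, path) {
  d <- data.frame(
    sample_id = c(split$cv_ids, split$prediction_ids),
    set = rep(c("cv", "prediction"),
              c(length(split$cv_ids), length(split$prediction_ids))),
    stringsAsFactors = FALSE)
  data.table::fwrite(d, path)
  invisible(path)
}

#' @rdname write_split_csv
#' @export
read_split_csv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  if (!all(c("sample_id", "set") %in% names(d)) ||
      !all(d$set %in% c("cv", "prediction"))) {
    stop_olivenir("split CSV must have columns sample_id and ",
                  "set in {cv, prediction}")
  }
  d
}
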