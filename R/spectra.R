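#' Construct a spectra set
#'
#' A `spectra_set` is the X-block of every chemometric step in olivenir: a
#' numeric absorbance matrix (samples in rows) together with its wavenumber
#' axis.  The axis is stored in instrument order, strictly descending in
#' wavenumber (high energy first), as FT-NIR software exports it.
#'
#' @param absorbance numeric matrix, `n_samples x n_wavenumbers`; no missing
#'   or non-finite values.
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, strictly
#'   descending, same length as `ncol(absorbance)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the matrix rownames or `sample_001 ...`.
#' @return An object of class `spectra_set` with fields `wavenumbers`,
#'   `absorbance` (rownames = sample ids) and `sample_ids`.
#' @examples
#' wn <- seq(13333, 4001, by = -4)
#' x <- matrix(rnorm(3 * length(wn)), nrow = 3)
#' s <- spectra_set(x, wn)
#' s
#' @export
spectra_set <- function(absorbance, wavenumbers, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(absorbance)) {
    stop_olivenir("wavenumber axis has ", length(wavenumbers),
                  " points but absorbance has ", ncol(absorbance), " columns")
  }
  if (length(wavenumbers) < 2) {
    stop_olivenir("a spectra_set needs at least 2 wavenumbers")
  }
  if (any(diff(wavenumbers) >= 0)) {
    bad <- which(diff(wavenumbers) >= 0)[1]
    stop_olivenir("wavenumbers must be strictly descending; violation at ",
                  "positions ", bad, "-", bad + 1, " (",
                  wavenumbers[bad], " -> ", wavenumbers[bad + 1], ")")
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1, , drop = TRUE]
    stop_olivenir("non-finite absorbance at row ", bad[1],
                  ", column ", bad[2])
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(absorbance) %||%
      sprintf("sample_%03d", seq_len(nrow(absorbance)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance)) {
    stop_olivenir("sample_ids length (", length(sample_ids),
                  ") does not match the number of spectra (",
                  nrow(absorbance), ")")
  }
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1]
    stop_olivenir("duplicate sample id: '", dup, "'")
  }
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- format_wavenumber(wavenumbers)
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         sample_ids = sample_ids),
    class = "spectra_set"
  )
}

format_wavenumber <- function(wn) {
  format(wn, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set: ", nrow(x$absorbance), " samples x ",
      length(x$wavenumbers), " wavenumbers (",
      format_wavenumber(max(x$wavenumbers)), "-",
      format_wavenumber(min(x$wavenumbers)), " cm-1)\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by sample
#'
#' @param x a [spectra_set()].
#' @param i integer, logical or character (sample id) index.
#' @return A `spectra_set` containing the selected samples.
#' @export
subset_samples <- function(x, i) {
  stopifnot(inherits(x, "spectra_set"))
  ab <- x$absorbance[i, , drop = FALSE]
  spectra_set(ab, x$wavenumbers, sample_ids = rownames(ab))
}

# uniform-grid step (positive magnitude, cm^-1); errors if the axis is not
# uniform within tolerance -- Savitzky-Golay derivatives assume equal spacing
grid_step <- function(x, tol = 1e-8) {
  d <- diff(x$wavenumbers)
  h <- mean(d)
  if (max(abs(d - h)) > tol * max(1, abs(h))) {
    stop_olivenir("wavenumber grid is not uniform (max deviation ",
                  signif(max(abs(d - h)), 3), " cm-1)")
  }
  abs(h)
}

#' Per-assay reference values
#'
#' The y-block of a calibration: one antioxidant-capacity value per sample,
#' expressed in mM Trolox equivalents.
#'
#' @param sample_id character vector of unique sample ids.
#' @param value numeric vector of antioxidant capacity (mM Trolox).
#' @param assay one of `"DPPH"`, `"ABTS"`, `"ORAC"`.
#' @return A data frame of class `reference_values` with columns
#'   `sample_id`, `value` and attributes `assay` and `unit`.
#' @export
reference_values <- function(sample_id, value, assay) {
  assay <- match.arg(assay, .olivenir_assays)
  sample_id <- as.character(sample_id)
  value <- as.numeric(value)
  if (length(sample_id) != length(value)) {
    stop_olivenir("sample_id and value lengths differ")
  }
  if (anyDuplicated(sample_id)) {
    stop_olivenir("duplicate sample id: '",
                  sample_id[duplicated(sample_id)][1], "'")
  }
  if (anyNA(value) || any(!is.finite(value))) {
    stop_olivenir("reference values must be finite")
  }
  structure(
    data.frame(sample_id = sample_id, value = value,
               stringsAsFactors = FALSE),
    assay = assay, unit = "mM Trolox",
    class = c("reference_values", "data.frame")
  )
}

# align a reference_values object (or named/plain numeric) to the sample ids
# of a spectra_set; errors on any mismatch
align_reference <- function(y, spectra) {
  ids <- spectra$sample_ids
  if (inherits(y, "reference_values")) {
    missing_ids <- setdiff(ids, y$sample_id)
    extra_ids <- setdiff(y$sample_id, ids)
    if (length(missing_ids) || length(extra_ids)) {
      stop_olivenir(
        "sample ids of spectra and reference values do not match",
        if (length(missing_ids)) paste0("; missing from y: ",
          paste(head(missing_ids, 3), collapse = ", ")),
        if (length(extra_ids)) paste0("; unknown in X: ",
          paste(head(extra_ids, 3), collapse = ", ")))
    }
    return(y$value[match(ids, y$sample_id)])
  }
  y <- as.numeric(y)
  if (length(y) != length(ids)) {
    stop_olivenir("y has ", length(y), " values for ", length(ids),
                  " spectra")
  }
  y
}
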