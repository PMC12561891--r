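#' Read / write a spectra set as wide CSV
#'
#' The dialect is a header row `sample_id` followed by the wavenumbers in
#' cm^-1 (descending), then one row per sample.  Reading validates every
#' `spectra_set` invariant and reports the offending row/column on
#' failure.
#'
#' @param path CSV file path.
#' @return `read_spectra_csv` returns a [spectra_set()];
#'   `write_spectra_csv` returns `path` invisibly.
#' @export
read_spectra_csv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE, header = TRUE)
  if (names(d)[1] != "sample_id") {
    stop_olivenir("first column of a spectra CSV must be 'sample_id', got '",
                  names(d)[1], "'")
  }
  wn <- suppressWarnings(as.numeric(names(d)[-1]))
  if (anyNA(wn)) {
    bad <- which(is.na(wn))[1]
    stop_olivenir("non-numeric wavenumber header in column ", bad + 1,
                  ": '", names(d)[bad + 1], "'")
  }
  ab <- as.matrix(d[, -1, drop = FALSE])
  if (anyNA(ab)) {
    bad <- which(is.na(ab), arr.ind = TRUE)[1, ]
    stop_olivenir("missing absorbance at row ", bad[1], ", column ",
                  bad[2] + 1)
  }
  if (any(diff(wn) >= 0)) {
    bad <- which(diff(wn) >= 0)[1]
    stop_olivenir("wavenumber axis must be strictly descending; columns ",
                  bad + 1, "-", bad + 2, " hold ", wn[bad], " then ",
                  wn[bad + 1])
  }
  spectra_set(ab, wn, sample_ids = d$sample_id)
}

#' @rdname read_spectra_csv
#' @param x a [spectra_set()].
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  d <- data.frame(sample_id = x$sample_ids, x$absorbance,
                  check.names = FALSE, stringsAsFactors = FALSE)
  names(d) <- c("sample_id", format_wavenumber(x$wavenumbers))
  data.table::fwrite(d, path)
  invisible(path)
}

#' Read / write per-assay reference values as CSV
#'
#' Columns `sample_id`, `value` (mM Trolox).
#'
#' @param path CSV file path.
#' @param assay assay name the values belong to.
#' @return `read_reference_csv` returns a [reference_values()] object;
#'   `write_reference_csv` returns `path` invisibly.
#' @export
read_reference_csv <- function(path, assay) {
  d <- data.table::fread(path, data.table = FALSE)
  if (!all(c("sample_id", "value") %in% names(d))) {
    stop_olivenir("reference CSV must have columns sample_id, value")
  }
  reference_values(d$sample_id, d$value, assay)
}

#' @rdname read_reference_csv
#' @param y a [reference_values()] object.
#' @export
write_reference_csv <- function(y, path) {
  data.table::fwrite(as.data.frame(y)[, c("sample_id", "value")], path)
  invisible(path)
}

#' Read / write phenolic profiles as CSV
#'
#' Columns `sample_id` plus one concentration column (mg/g dry leaf) per
#' compound.
#'
#' @param path CSV file path.
#' @return `read_profiles_csv` returns a `phenolic_profile` data frame;
#'   `write_profiles_csv` returns `path` invisibly.
#' @export
read_profiles_csv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  if (!"sample_id" %in% names(d)) {
    stop_olivenir("profiles CSV must have a sample_id column")
  }
  missing_cmp <- setdiff(.olivenir_compounds, names(d))
  if (length(missing_cmp)) {
    stop_olivenir("profiles CSV is missing compound columns: ",
                  paste(missing_cmp, collapse = ", "))
  }
  d$sample_id <- as.character(d$sample_id)
  class(d) <- c("phenolic_profile", "data.frame")
  d
}

#' @rdname read_profiles_csv
#' @param profiles a `phenolic_profile` data frame.
#' @export
write_profiles_csv <- function(profiles, path) {
  data.table::fwrite(as.data.frame(profiles), path)
  invisible(path)
}
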