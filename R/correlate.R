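#' Pearson correlation with t-test p-value
#'
#' Product-moment correlation between two numeric vectors with the
#' two-sided p-value from the t statistic on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, both nonconstant.
#' @return A list with `r` and `p_value`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_olivenir("x and y lengths differ")
  if (length(x) < 3) stop_olivenir("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_olivenir("constant vector: correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Two-level significance stars
#'
#' `"**"` for p < 0.01, `"*"` for 0.01 <= p < 0.05, `""` otherwise.  A
#' pure function of the p-value.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Character vector of the same length.
#' @export
significance_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_olivenir("p-values must lie in [0, 1]")
  }
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Phenolic-compound / assay correlation table
#'
#' Pearson correlation of each phenolic concentration column against each
#' assay's reference values, with two-level significance marking.  All
#' tables must cover the same sample ids; assay values are aligned to the
#' profile rows by id.
#'
#' @param profiles a [generate_profiles()]-style data frame (`sample_id`
#'   plus one column per compound).
#' @param assay_values named list of [reference_values()] objects (one per
#'   assay).
#' @param p_adjust multiple-testing correction applied across all cells
#'   (`"none"`, the default, or any method of [stats::p.adjust()], e.g.
#'   `"bonferroni"`).
#' @return A data frame of class `correlation_table` with columns
#'   `compound`, `assay`, `r`, `p_value`, `stars`.
#' @export
correlation_table <- function(profiles, assay_values, p_adjust = "none") {
  compounds <- intersect(.olivenir_compounds, names(profiles))
  if (length(compounds) == 0) {
    stop_olivenir("profiles contain no known compound columns")
  }
  if (is.null(names(assay_values)) || any(names(assay_values) == "")) {
    stop_olivenir("assay_values must be a named list")
  }
  ids <- profiles$sample_id
  rows <- list()
  for (assay in names(assay_values)) {
    yv <- assay_values[[assay]]
    missing_ids <- setdiff(ids, yv$sample_id)
    extra_ids <- setdiff(yv$sample_id, ids)
    if (length(missing_ids) || length(extra_ids)) {
      stop_olivenir(
        "sample ids of assay '", assay, "' do not match the profiles",
        if (length(missing_ids)) paste0("; missing: ",
          paste(head(missing_ids, 3), collapse = ", ")),
        if (length(extra_ids)) paste0("; unknown: ",
          paste(head(extra_ids, 3), collapse = ", ")))
    }
    v <- yv$value[match(ids, yv$sample_id)]
    for (cmp in compounds) {
      pr <- pearson_r(profiles[[cmp]], v)
      rows[[length(rows) + 1]] <- data.frame(
        compound = cmp, assay = assay, r = pr$r, p_value = pr$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$stars <- significance_stars(out$p_value)
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Write / read a correlation table as CSV
#'
#' @param x a [correlation_table()] result.
#' @param path CSV file path.
#' @return `write_correlation_csv` returns `path` invisibly;
#'   `read_correlation_csv` returns the `correlation_table`.
#' @export
write_correlation_csv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_correlation_csv
#' @export
read_correlation_csv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  need <- c("compound", "assay", "r", "p_value", "stars")
  if (!all(need %in% names(d))) {
    stop_olivenir("correlation CSV must have columns: ",
                  paste(need, collapse = ", "))
  }
  d$stars[is.na(d$stars)] <- ""
  class(d) <- c("correlation_table", "data.frame")
  d
}
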