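#' Full kinetic area-under-curve statistic
#'
#' Sums every reading of a kinetic curve relative to the initial reading:
#' `AUC = F1/F1 + F2/F1 + ... + Fn/F1`.  With readings at a fixed interval
#' this is the (unit-spaced) area under the normalized decay curve,
#' including the leading term equal to 1.
#'
#' @param curve a [generate_kinetic_curve()] result, or any list with a
#'   numeric `signal` field.
#' @return The AUC as a single number.
#' @examples
#' auc_full(list(signal = c(100, 80, 60)))  # 1 + 0.8 + 0.6 = 2.4
#' @export
auc_full <- function(curve) {
  f <- as.numeric(curve$signal)
  if (length(f) < 1) stop_olivenir("curve has no readings")
  if (f[1] <= 0) {
    stop_olivenir("initial reading F1 must be > 0 (division by zero)")
  }
  sum(f / f[1])
}

#' Simplified two-point area-under-curve statistic
#'
#' Reduces the kinetic curve to its start and end readings.  The default
#' direction returns `F1 / Fn`; because an uninhibited well decays further
#' (smaller `Fn`), that ratio grows with radical activity and shrinks with
#' antioxidant content.  The reciprocal reading `Fn / F1` is exposed for
#' workflows that prefer a statistic increasing in antioxidant capacity.
#'
#' @param curve a kinetic curve (list with numeric `signal`).
#' @param direction `"start_over_end"` (default, `F1/Fn`) or
#'   `"end_over_start"` (`Fn/F1`).
#' @return The ratio as a single number.
#' @export
auc_simplified <- function(curve,
                           direction = c("start_over_end",
                                         "end_over_start")) {
  direction <- match.arg(direction)
  f <- as.numeric(curve$signal)
  if (length(f) < 2) stop_olivenir("curve needs at least 2 readings")
  f1 <- f[1]
  fn <- f[length(f)]
  den <- if (direction == "start_over_end") fn else f1
  if (den <= 0) {
    stop_olivenir("denominator reading is ", den, "; must be > 0")
  }
  if (direction == "start_over_end") f1 / fn else fn / f1
}

#' Fit a Trolox standard curve
#'
#' Ordinary least-squares line of assay response on standard concentration,
#' as used to convert raw assay responses into Trolox equivalents.  Typical
#' designs are five points between 0.05 and 1 mM (DPPH/ABTS) or six points
#' between 6.25 and 100 uM (ORAC).
#'
#' @param concentrations numeric standard concentrations, at least two
#'   distinct values.
#' @param responses assay responses, same length.
#' @param unit `"mM"` or `"uM"` -- the unit of `concentrations`; recorded so
#'   conversions can report mM Trolox regardless of curve design.
#' @return A list of class `standard_curve`: `concentrations`, `responses`,
#'   `slope`, `intercept`, `r_squared`, `unit`.
#' @export
fit_standard_curve <- function(concentrations, responses,
                               unit = c("mM", "uM")) {
  unit <- match.arg(unit)
  concentrations <- as.numeric(concentrations)
  responses <- as.numeric(responses)
  if (length(concentrations) != length(responses)) {
    stop_olivenir("concentrations and responses lengths differ")
  }
  if (length(unique(concentrations)) < 2) {
    stop_olivenir("standard curve needs >= 2 distinct concentrations ",
                  "(singular fit)")
  }
  fit <- lm(responses ~ concentrations)
  sst <- sum((responses - mean(responses))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(residuals(fit)^2) / sst
  structure(
    list(concentrations = concentrations, responses = responses,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, unit = unit),
    class = "standard_curve")
}

#' Convert an assay response to Trolox equivalents
#'
#' Inverts the standard curve, `(response - intercept) / slope`, applies
#' the extract dilution factor and converts to mM if the curve was built
#' in uM.  An optional blank response can be subtracted first.
#'
#' @param response raw assay response (or net AUC for kinetic assays).
#' @param curve a [fit_standard_curve()] object with nonzero slope.
#' @param dilution_factor total dilution of the extract (> 0), e.g. 2 for
#'   a 1:2 dilution or 50 for 1:50.
#' @param assay optional assay label to carry in the result.
#' @param blank response of the blank well, subtracted from `response`
#'   before conversion (default 0: no blank correction).
#' @return A list of class `trolox_equivalent` with fields `value`
#'   (mM Trolox), `assay` and `dilution_factor`.
#' @export
to_trolox_equivalent <- function(response, curve, dilution_factor = 1,
                                 assay = NA_character_, blank = 0) {
  stopifnot(inherits(curve, "standard_curve"))
  if (abs(curve$slope) < .Machine$double.eps) {
    stop_olivenir("standard curve slope is zero; cannot invert")
  }
  if (dilution_factor <= 0) {
    stop_olivenir("dilution_factor must be > 0")
  }
  conc <- (response - blank - curve$intercept) / curve$slope
  value <- conc * dilution_factor
  if (curve$unit == "uM") value <- value / 1000
  structure(list(value = value, assay = assay,
                 dilution_factor = dilution_factor),
            class = "trolox_equivalent")
}

#' Read long-format kinetic plate readings
#'
#' Expects columns `well`, `time_s`, `signal`; returns one `kinetic_curve`
#' per well, ordered by time.
#'
#' @param path CSV file path.
#' @param mode decay mode recorded on each curve.
#' @return Named list of `kinetic_curve` objects.
#' @export
read_kinetics_csv <- function(path, mode = c("fluorescence_decay",
                                             "absorbance_decay")) {
  mode <- match.arg(mode)
  d <- data.table::fread(path, data.table = FALSE)
  need <- c("well", "time_s", "signal")
  if (!all(need %in% names(d))) {
    stop_olivenir("kinetics CSV must have columns: ",
                  paste(need, collapse = ", "))
  }
  lapply(split(d, d$well), function(w) {
    w <- w[order(w$time_s), ]
    if (anyDuplicated(w$time_s)) {
      stop_olivenir("duplicate time points in well '", w$well[1], "'")
    }
    structure(list(times = w$time_s, signal = w$signal, mode = mode),
              class = "kinetic_curve")
  })
}
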