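#' Root mean square error
#'
#' `sqrt(sum((f - y)^2) / n)` between predicted and observed values; used
#' for RMSEC (calibration), RMSECV (cross-validation) and RMSEP
#' (prediction) depending on which set the pairs come from.
#'
#' @param predicted,observed numeric vectors of equal length >= 1.
#' @return The RMSE as a single nonnegative number.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop_olivenir("predicted and observed lengths differ")
  }
  if (length(predicted) == 0) stop_olivenir("empty input")
  sqrt(mean((predicted - observed)^2))
}

#' Residual predictive deviation
#'
#' Ratio of the standard deviation of the reference values of a set
#' (sample sd, n-1 denominator) to the RMSE achieved on that set.  An
#' exactly zero RMSE yields `+Inf` with a warning.
#'
#' @param reference_sd standard deviation of the measured reference values.
#' @param rmse_value the RMSE on the same set.
#' @return The RPD.
#' @export
rpd <- function(reference_sd, rmse_value) {
  if (rmse_value < 0) stop_olivenir("rmse_value must be >= 0")
  if (rmse_value == 0) {
    warning("RMSE is exactly 0; RPD reported as +Inf")
    return(Inf)
  }
  reference_sd / rmse_value
}

#' Interpret an RPD value
#'
#' Standard chemometric bands: an RPD of at least 3 is considered suitable
#' for quality-control use, between 2 and 3 for screening, and below 2 the
#' model is not recommended for quantitative application.
#'
#' @param value a positive RPD.
#' @return One of `"quality control"`, `"screening"`,
#'   `"not recommended"`.
#' @export
interpret_rpd <- function(value) {
  if (!is.numeric(value) || is.na(value) || value <= 0) {
    stop_olivenir("RPD must be a positive number")
  }
  if (value >= 3) "quality control"
  else if (value >= 2) "screening"
  else "not recommended"
}

# squared Pearson correlation; the R^2 definition used throughout the
# reports (matches scatter-plot R^2 of predicted vs observed)
r_squared_pearson <- function(predicted, observed) {
  if (sd(predicted) == 0 || sd(observed) == 0) return(NA_real_)
  cor(predicted, observed)^2
}

r_squared_sse <- function(predicted, observed) {
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / sst
}

#' Observed-versus-predicted regression diagnostics
#'
#' OLS line of predicted on observed values, the diagnostic behind the
#' usual scatter plot of a prediction set: a perfect model gives slope 1,
#' intercept 0, R^2 1.
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @return A list of class `observed_predicted_fit` with `slope`,
#'   `intercept`, `r_squared`.
#' @export
observed_predicted_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3) {
    stop_olivenir("need equal-length vectors with at least 3 pairs")
  }
  if (sd(observed) == 0) {
    stop_olivenir("observed values have zero variance")
  }
  fit <- lm(predicted ~ observed)
  sst <- sum((predicted - mean(predicted))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(residuals(fit)^2) / sst
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2),
            class = "observed_predicted_fit")
}

set_metrics <- function(predicted, observed) {
  e <- rmse(predicted, observed)
  rp <- suppressWarnings(rpd(sd(observed), e))
  list(n = length(observed),
       r_squared = r_squared_pearson(predicted, observed),
       r_squared_sse = r_squared_sse(predicted, observed),
       rmse = e, rpd = rp,
       rpd_category = if (is.finite(rp) || is.infinite(rp))
         interpret_rpd(rp) else NA_character_)
}

#' Evaluate one pretreatment/PLS pipeline
#'
#' Pretreats the spectra, (optionally) derives a Kennard-Stone split,
#' selects the LV count by cross-validation on Set 1, and reports R^2,
#' RMSE, RPD and the RPD category for the calibration, cross-validation
#' and prediction sets.
#'
#' In the default mode the calibration model is fit on Set 1 only, so the
#' prediction metrics come from a model that never saw Set 2 (the training
#' ids are recorded in the report as an audit trail).  With
#' `paper_mode = TRUE` the calibration model is fit on all samples
#' (Set 1+2) and that same model produces the Set 2 predictions -- the
#' protocol sometimes seen in applied NIR work, in which the prediction
#' set is a subset of the calibration data.
#'
#' @param X a raw [spectra_set()].
#' @param y reference values aligned by sample id.
#' @param pretreatment a [pretreatment_spec()] or code string.
#' @param split a [split_sets()] result; computed from the pretreated
#'   spectra at `fraction` when `NULL`.
#' @param cv_scheme [cv_loo()] (default) or [cv_kfold()].
#' @param max_lv maximum LV count for the cross-validation sweep.
#' @param n_latent fixed LV count; when given, the cross-validation sweep
#'   is skipped and the report carries no cv entry.
#' @param paper_mode calibrate on Set 1+2 instead of Set 1 (see Details).
#' @param fraction Set 1 fraction used when `split` is `NULL`.
#' @return A list of class `evaluation_report`: `assay`, `code`,
#'   `selected_lv`, `sets` (named list of per-set metric lists),
#'   `training_ids`, `split`.
#' @export
evaluate_model <- function(X, y, pretreatment, split = NULL,
                           cv_scheme = cv_loo(), max_lv = 20,
                           n_latent = NULL, paper_mode = FALSE,
                           fraction = 0.7) {
  spec <- as_pretreatment(pretreatment)
  yv <- align_reference(y, X)
  Xp <- apply_pretreatment(X, spec)
  if (is.null(split)) split <- split_sets(Xp, fraction)
  cv_idx <- split$cv
  pred_idx <- split$prediction
  X1 <- subset_samples(Xp, cv_idx)
  y1 <- yv[cv_idx]

  cvres <- NULL
  if (is.null(n_latent)) {
    cvres <- cross_validate(X1, y1, max_lv = max_lv, scheme = cv_scheme)
    n_latent <- cvres$selected_lv
  }
  cal_idx <- if (paper_mode) split$all else cv_idx
  X_cal <- subset_samples(Xp, cal_idx)
  y_cal <- yv[cal_idx]
  A <- min(n_latent, length(cal_idx) - 1, length(Xp$wavenumbers))
  model <- fit_pls(X_cal, y_cal, n_latent = A)

  sets <- list(calibration = set_metrics(model$fitted, y_cal))
  if (!is.null(cvres)) {
    a_cv <- min(n_latent, ncol(cvres$predictions))
    sets$cv <- set_metrics(cvres$predictions[, a_cv], y1)
  }
  y2_pred <- predict(model, subset_samples(Xp, pred_idx),
                     ncomp = min(model$n_latent, A))
  sets$prediction <- set_metrics(y2_pred, yv[pred_idx])

  structure(
    list(assay = if (inherits(y, "reference_values")) attr(y, "assay")
                 else NA_character_,
         code = format(spec), selected_lv = model$n_latent,
         sets = sets, training_ids = X_cal$sample_ids, split = split,
         paper_mode = paper_mode, model = model,
         predictions = list(prediction_ids = split$prediction_ids,
                            observed = yv[pred_idx],
                            predicted = y2_pred)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report [", x$code, "]",
      if (!is.na(x$assay)) paste0(" assay ", x$assay), ", ",
      x$selected_lv, " LV\n", sep = "")
  print(report_table(list(x)))
  invisible(x)
}

#' Tabulate evaluation reports
#'
#' One row per (pretreatment, set) combination with the usual columns of
#' an NIR model-evaluation table: R^2, RMSEC/RMSECV/RMSEP, RPD and the
#' RPD category.
#'
#' @param reports a list of [evaluate_model()] reports (or a
#'   [grid_search()] result).
#' @return A data frame.
#' @export
report_table <- function(reports) {
  if (inherits(reports, "grid_search_result")) reports <- reports$reports
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    do.call(rbind, lapply(names(r$sets), function(s) {
      m <- r$sets[[s]]
      data.frame(assay = r$assay, code = r$code, set = s, n = m$n,
                 selected_lv = r$selected_lv,
                 r_squared = m$r_squared, rmse = m$rmse, rpd = m$rpd,
                 rpd_category = m$rpd_category, stringsAsFactors = FALSE)
    }))
  }))
}

#' Grid search over pretreatment codes
#'
#' Evaluates every pretreatment code with [evaluate_model()] under a
#' shared sample split and ranks the reports by prediction RPD
#' (descending), then prediction R^2 (descending), then RMSEP
#' (ascending).
#'
#' @param X a raw [spectra_set()].
#' @param y reference values.
#' @param codes character vector of pretreatment codes (default
#'   [default_pretreatment_codes()]).
#' @param split shared [split_sets()] result; when `NULL` it is computed
#'   once from the spectra pretreated with the first code.
#' @param ... passed on to [evaluate_model()] (`cv_scheme`, `max_lv`,
#'   `paper_mode`, ...).
#' @param fraction Set 1 fraction used when `split` is `NULL`.
#' @return A list of class `grid_search_result` with `reports` (ranked),
#'   `ranking` (data frame of prediction metrics), `split`, and `errors`
#'   (named list of per-code failures, if any).
#' @export
grid_search <- function(X, y, codes = default_pretreatment_codes(),
                        split = NULL, fraction = 0.7, ...) {
  if (length(codes) < 1) stop_olivenir("need at least one code")
  if (is.null(split)) {
    split <- split_sets(apply_pretreatment(X, codes[[1]]), fraction)
  }
  reports <- list(); errors <- list()
  for (code in codes) {
    res <- tryCatch(
      evaluate_model(X, y, pretreatment = code, split = split, ...),
      error = function(e) e)
    if (inherits(res, "error")) errors[[code]] <- conditionMessage(res)
    else reports[[code]] <- res
  }
  if (length(reports) == 0) {
    stop_olivenir("all pretreatment codes failed: ",
                  paste(names(errors), unlist(errors),
                        sep = ": ", collapse = "; "))
  }
  key <- do.call(rbind, lapply(reports, function(r) {
    m <- r$sets$prediction
    data.frame(code = r$code, rpd_p = m$rpd, r2_p = m$r_squared,
               rmsep = m$rmse, stringsAsFactors = FALSE)
  }))
  ord <- order(-key$rpd_p, -key$r2_p, key$rmsep)
  structure(list(reports = reports[ord], ranking = key[ord, ],
                 split = split, errors = errors),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("grid_search_result over", nrow(x$ranking), "pretreatments\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Serialize / reload an evaluation report as JSON
#'
#' The numeric content of the report (per-set metrics, LV count, training
#' ids, split) is written losslessly; the fitted model itself is stored
#' separately via [write_pls_model()] if needed.
#'
#' @param report an [evaluate_model()] report.
#' @param path JSON file path.
#' @return `write_report_json` returns `path` invisibly;
#'   `read_report_json` returns the report (without the model object).
#' @export
write_report_json <- function(report, path) {
  payload <- list(assay = report$assay, code = report$code,
                  selected_lv = report$selected_lv, sets = report$sets,
                  training_ids = report$training_ids,
                  paper_mode = report$paper_mode,
                  cv_ids = report$split$cv_ids,
                  prediction_ids = report$split$prediction_ids)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  d$selected_lv <- as.integer(d$selected_lv)
  d$sets <- lapply(d$sets, function(m) {
    m$n <- as.integer(m$n)
    m[c("r_squared", "r_squared_sse", "rmse", "rpd")] <-
      lapply(m[c("r_squared", "r_squared_sse", "rmse", "rpd")], function(v)
        if (is.character(v) && v %in% c("Inf", "-Inf")) as.numeric(v)
        else as.numeric(v))
    m
  })
  class(d) <- "evaluation_report"
  d
}
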