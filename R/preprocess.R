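#' Savitzky-Golay smoothing and derivatives
#'
#' Applies a Savitzky-Golay filter to every spectrum: a local polynomial of
#' order `polyorder` is fit in a sliding window and evaluated (or
#' differentiated) at the window center.  Edges are handled by evaluating
#' the polynomial fitted to the first/last window, so the output grid
#' equals the input grid.  Derivatives are taken with respect to the
#' wavenumber axis (per cm^-1, using the uniform grid step), so a first
#' derivative of a band rising towards lower wavenumber is negative.
#'
#' @param spectra a [spectra_set()] on a uniform wavenumber grid.
#' @param window odd window length in points (> `polyorder`).
#' @param polyorder polynomial order of the local fit (default 2).
#' @param deriv_order derivative order, `0` (smoothing), `1` or `2`;
#'   must not exceed `polyorder`.
#' @return A `spectra_set` with the same axis and sample ids.
#' @export
savitzky_golay <- function(spectra, window, polyorder = 2, deriv_order = 0) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (window %% 2 == 0) {
    stop_olivenir("Savitzky-Golay window must be odd, got ", window)
  }
  if (window <= polyorder) {
    stop_olivenir("window (", window, ") must exceed polyorder (",
                  polyorder, ")")
  }
  if (deriv_order > polyorder) {
    stop_olivenir("deriv_order (", deriv_order,
                  ") must not exceed polyorder (", polyorder, ")")
  }
  if (window > length(spectra$wavenumbers)) {
    stop_olivenir("window (", window, ") exceeds the number of wavenumbers (",
                  length(spectra$wavenumbers), ")")
  }
  h <- grid_step(spectra)
  out <- t(apply(spectra$absorbance, 1, signal::sgolayfilt,
                 p = polyorder, n = window, m = deriv_order, ts = h))
  # columns run towards decreasing wavenumber: d/dnu = -(d/dx)
  if (deriv_order %% 2 == 1) out <- -out
  spectra_set(out, spectra$wavenumbers, spectra$sample_ids)
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum to mean 0 and (sample) standard
#' deviation 1, removing per-sample additive offsets and multiplicative
#' scaling caused by light scattering in powdered samples.
#'
#' @param spectra a [spectra_set()].
#' @return A `spectra_set` whose rows each have mean 0 and sd 1.
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  m <- rowMeans(spectra$absorbance)
  s <- apply(spectra$absorbance, 1, sd)
  tolr <- 1e-12 * pmax(1, abs(m))
  if (any(s <= tolr)) {
    bad <- spectra$sample_ids[which(s <= tolr)[1]]
    stop_olivenir("SNV undefined for (near-)constant spectrum of sample '",
                  bad, "'")
  }
  spectra_set((spectra$absorbance - m) / s, spectra$wavenumbers,
              spectra$sample_ids)
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * ref`
#' (ordinary least squares), and returns `(x - a) / b`.  Spectra of the
#' form `a + b * ref` with `b > 0` are mapped exactly back to the
#' reference.
#'
#' @param spectra a [spectra_set()].
#' @param reference reference spectrum (numeric, one value per wavenumber);
#'   defaults to the mean spectrum of the set.
#' @param tol minimum admissible `|b|`; a sample whose slope falls below it
#'   raises an error naming the sample.
#' @return A corrected `spectra_set`.
#' @export
msc <- function(spectra, reference = NULL, tol = 1e-10) {
  stopifnot(inherits(spectra, "spectra_set"))
  ref <- reference %||% colMeans(spectra$absorbance)
  if (length(ref) != length(spectra$wavenumbers)) {
    stop_olivenir("reference length (", length(ref),
                  ") does not match the wavenumber axis (",
                  length(spectra$wavenumbers), ")")
  }
  ref_c <- ref - mean(ref)
  denom <- sum(ref_c^2)
  if (denom <= 0) stop_olivenir("reference spectrum is constant")
  X <- spectra$absorbance
  b <- drop(X %*% ref_c) / denom           # per-row OLS slope
  a <- rowMeans(X) - b * mean(ref)
  if (any(abs(b) < tol)) {
    bad <- spectra$sample_ids[which(abs(b) < tol)[1]]
    stop_olivenir("MSC slope below tolerance for sample '", bad, "'")
  }
  spectra_set((X - a) / b, spectra$wavenumbers, spectra$sample_ids)
}

#' Build a pretreatment specification
#'
#' A pretreatment is a pipeline: Savitzky-Golay derivative (order
#' `deriv_order`, window `deriv_window`) -> Savitzky-Golay smoothing
#' (window `smooth_window`) -> scatter correction (`MSC`, `SNV` or none).
#' With `deriv_order = 0` the two Savitzky-Golay stages are skipped and
#' only the scatter correction (if any) applies; `scatter = "NONE"` with
#' `deriv_order = 0` is the identity.
#'
#' @param scatter `"MSC"`, `"SNV"` or `"NONE"`.
#' @param deriv_order 0, 1 or 2.
#' @param deriv_window,smooth_window odd window lengths >= 3 (required when
#'   `deriv_order > 0`).
#' @param polyorder Savitzky-Golay polynomial order (default 2).
#' @return A list of class `pretreatment_spec`.
#' @seealso [parse_pretreatment_code()] for the compact `"SNV-2.19.5"`
#'   notation.
#' @export
pretreatment_spec <- function(scatter = c("NONE", "MSC", "SNV"),
                              deriv_order = 0, deriv_window = NULL,
                              smooth_window = NULL, polyorder = 2) {
  scatter <- match.arg(scatter)
  if (!deriv_order %in% 0:2) {
    stop_olivenir("deriv_order must be 0, 1 or 2, got ", deriv_order)
  }
  if (deriv_order > 0) {
    for (w in c(deriv = deriv_window, smooth = smooth_window)) {
      if (is.null(w) || w < 3 || w %% 2 == 0 || w < polyorder + 1) {
        stop_olivenir("derivative and smoothing windows must be odd, >= 3 ",
                      "and >= polyorder + 1")
      }
    }
  }
  structure(list(scatter = scatter, deriv_order = as.integer(deriv_order),
                 deriv_window = if (deriv_order > 0)
                   as.integer(deriv_window),
                 smooth_window = if (deriv_order > 0)
                   as.integer(smooth_window),
                 polyorder = as.integer(polyorder)),
            class = "pretreatment_spec")
}

#' Parse a "SCATTER-a.b.c" pretreatment code
#'
#' The compact notation used in chemometric pretreatment tables:
#' `SCATTER-a.b.c` where `SCATTER` is `MSC` or `SNV`, `a` is the derivative
#' order (1 or 2), `b` the derivative window (points) and `c` the smoothing
#' window (points).  `format()` on the result reproduces the code exactly.
#'
#' @param code a code such as `"SNV-2.19.5"`.
#' @return A [pretreatment_spec()].
#' @examples
#' parse_pretreatment_code("MSC-1.19.5")
#' @export
parse_pretreatment_code <- function(code) {
  if (!is.character(code) || length(code) != 1) {
    stop_olivenir("pretreatment code must be a single string")
  }
  m <- regmatches(code,
    regexec("^(MSC|SNV)-([0-9]+)\\.([0-9]+)\\.([0-9]+)$", code))[[1]]
  if (length(m) == 0) {
    stop_olivenir("malformed pretreatment code '", code,
                  "': expected SCATTER-a.b.c with SCATTER in {MSC, SNV} ",
                  "(error at position 1)")
  }
  a <- as.integer(m[3]); b <- as.integer(m[4]); cc <- as.integer(m[5])
  if (!a %in% 1:2) {
    stop_olivenir("derivative order must be 1 or 2 in '", code,
                  "' (field a)")
  }
  if (b %% 2 == 0 || b < 3) {
    stop_olivenir("derivative window must be odd and >= 3 in '", code,
                  "' (field b)")
  }
  if (cc %% 2 == 0 || cc < 3) {
    stop_olivenir("smoothing window must be odd and >= 3 in '", code,
                  "' (field c)")
  }
  pretreatment_spec(scatter = m[2], deriv_order = a, deriv_window = b,
                    smooth_window = cc)
}

#' @export
format.pretreatment_spec <- function(x, ...) {
  if (x$deriv_order == 0 && x$scatter == "NONE") return("RAW")
  if (x$deriv_order == 0) return(x$scatter)
  sprintf("%s-%d.%d.%d", x$scatter, x$deriv_order, x$deriv_window,
          x$smooth_window)
}

#' @export
print.pretreatment_spec <- function(x, ...) {
  cat("pretreatment: ", format(x), "\n", sep = "")
  invisible(x)
}

as_pretreatment <- function(x) {
  if (inherits(x, "pretreatment_spec")) return(x)
  if (is.character(x)) return(parse_pretreatment_code(x))
  stop_olivenir("cannot interpret pretreatment of class ",
                paste(class(x), collapse = "/"))
}

#' Apply a pretreatment pipeline to spectra
#'
#' Runs the stages of a [pretreatment_spec()] in order: Savitzky-Golay
#' derivative, Savitzky-Golay smoothing, then scatter correction (the
#' standard order in NIR model development; `scatter_first = TRUE` swaps
#' the scatter correction to the front for sensitivity analysis).  Stage
#' failures are re-raised with the stage name attached.
#'
#' @param spectra a [spectra_set()].
#' @param spec a [pretreatment_spec()] or a code string such as
#'   `"SNV-2.19.5"`.
#' @param scatter_first apply the scatter correction before the derivative
#'   stages instead of after (default `FALSE`).
#' @param msc_reference optional fixed reference spectrum for MSC (e.g. a
#'   calibration-set mean); defaults to the mean of `spectra`.
#' @return A pretreated `spectra_set` on the same grid.
#' @export
apply_pretreatment <- function(spectra, spec, scatter_first = FALSE,
                               msc_reference = NULL) {
  spec <- as_pretreatment(spec)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop_olivenir("pretreatment stage '", name, "' failed: ",
                    conditionMessage(e))
    })
  }
  scatter_stage <- function(x) {
    switch(spec$scatter,
           NONE = x,
           SNV = run_stage("SNV", function() snv(x)),
           MSC = run_stage("MSC", function() msc(x, msc_reference)))
  }
  x <- spectra
  if (scatter_first) x <- scatter_stage(x)
  if (spec$deriv_order > 0) {
    x <- run_stage("derivative", function()
      savitzky_golay(x, spec$deriv_window, spec$polyorder,
                     spec$deriv_order))
    x <- run_stage("smoothing", function()
      savitzky_golay(x, spec$smooth_window, spec$polyorder, 0))
  }
  if (!scatter_first) x <- scatter_stage(x)
  x
}

#' The default pretreatment grid
#'
#' The six distinct pretreatment codes evaluated by default in
#' [grid_search()]: first or second derivatives with 5/13/19-point
#' windows, Savitzky-Golay smoothing, and MSC or SNV scatter correction.
#'
#' @return Character vector of pretreatment codes.
#' @export
default_pretreatment_codes <- function() {
  c("MSC-1.19.5", "SNV-2.13.9", "MSC-2.19.5", "SNV-2.19.5",
    "SNV-2.5.19", "MSC-2.5.19")
}
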