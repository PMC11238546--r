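# CAS assay and bioassay standard-curve calibration and inversion.
#
# The chrome azurol S (CAS) assay quantifies total siderophore chelating
# activity: siderophores strip Fe(III) from the CAS-Fe dye complex and
# decolorize it, so absorbance at 630 nm *decreases* with siderophore
# concentration. Concentrations are reported in desferrioxamine B (DF)
# equivalents against a standard curve. Two ranges are fit separately
# (standards 0-12.5 uM low, 15-30 uM high); strong samples are read
# sixfold diluted. The Arthrobacter JG-9 growth bioassay for hydroxamates
# uses the same calibrate-and-invert contract with a growth response.

#' Default CAS standard concentrations (uM desferrioxamine B)
#'
#' @format List with numeric vectors `low` (0, 1, 3, 5, 7.5, 12.5) and
#'   `high` (15, 20, 25, 30).
#' @export
CAS_STANDARDS <- list(low = c(0, 1, 3, 5, 7.5, 12.5),
                      high = c(15, 20, 25, 30))

#' Fit a linear standard curve
#'
#' Least-squares fit of response on concentration. The fit does not
#' assume a sign for the slope: CAS responses decrease with concentration,
#' bioassay growth responses increase.
#'
#' @param concentration Standard concentrations (uM), >= 3 distinct.
#' @param response Measured responses (absorbance at 630 nm for CAS).
#' @param range_label `"low"` or `"high"` (or any label), recorded on the
#'   curve and used by [assign_and_invert()].
#' @return Object of class `cas_curve`: list with `slope`, `intercept`,
#'   `range` (min/max standard concentration), `range_label`,
#'   `r_squared`, `residual_sd`, `n`, and the `fit` (an `lm`).
#' @examples
#' cur <- fit_standard_curve(c(0, 1, 3, 5, 7.5, 12.5),
#'                           0.8 - 0.02 * c(0, 1, 3, 5, 7.5, 12.5))
#' coef(cur)
#' @export
fit_standard_curve <- function(concentration, response,
                               range_label = "low") {
  if (length(concentration) != length(response)) {
    stop("concentration and response must have equal length", call. = FALSE)
  }
  if (length(unique(concentration)) < 3L) {
    stop("need >= 3 distinct standard concentrations", call. = FALSE)
  }
  if (stats::sd(response) == 0) {
    stop("standard curve is flat (constant response): not invertible",
         call. = FALSE)
  }
  fit <- stats::lm(response ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope == 0) {
    stop("standard curve is flat (slope 0): not invertible", call. = FALSE)
  }
  # exact (noise-free) standards trip summary.lm's perfect-fit warning;
  # an exact calibration line is a valid input here, not a problem
  smry <- suppressWarnings(summary(fit))
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    range = range(concentration),
    range_label = range_label,
    r_squared = smry$r.squared,
    residual_sd = smry$sigma,
    n = length(concentration),
    fit = fit
  ), class = "cas_curve")
}

#' @export
print.cas_curve <- function(x, ...) {
  cat("Standard curve (", x$range_label, " range, ",
      x$range[1], "-", x$range[2], " uM, n = ", x$n, ")\n", sep = "")
  cat("  response = ", format(x$intercept, digits = 6), " + ",
      format(x$slope, digits = 6), " x concentration\n", sep = "")
  cat("  R^2 = ", sprintf("%.4f", x$r_squared),
      ", residual SD = ", format(x$residual_sd, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.cas_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.cas_curve <- function(object, concentration, ...) {
  object$intercept + object$slope * concentration
}

#' Invert an assay reading to a concentration
#'
#' Back-calculates concentration = dilution_factor x
#' (response - intercept) / slope. Readings whose back-calculated
#' (undiluted) value falls outside the curve's standard range are flagged
#' as extrapolated, not rejected.
#'
#' @param response Measured response(s).
#' @param curve A `cas_curve`.
#' @param dilution_factor Dilution applied before reading (1 = neat,
#'   6 = sixfold diluted); reported concentrations are scaled back up.
#' @return Data.frame with columns `response`, `dilution_factor`,
#'   `concentration_uM`, `extrapolated`.
#' @export
invert_reading <- function(response, curve, dilution_factor = 1) {
  stopifnot(inherits(curve, "cas_curve"))
  if (any(dilution_factor <= 0)) {
    stop("dilution_factor must be > 0", call. = FALSE)
  }
  if (curve$slope == 0) stop("curve slope is 0: not invertible",
                             call. = FALSE)
  dilution_factor <- rep_len(dilution_factor, length(response))
  on_curve <- (response - curve$intercept) / curve$slope
  data.frame(
    response = response,
    dilution_factor = dilution_factor,
    concentration_uM = dilution_factor * on_curve,
    extrapolated = on_curve < curve$range[1] | on_curve > curve$range[2]
  )
}

#' Assign each reading to the low- or high-range curve and invert
#'
#' A reading is assigned to the curve whose standard range contains its
#' back-calculated value; when both ranges contain it the low-range curve
#' is preferred. Readings falling in neither range are inverted on the
#' curve whose range edge is nearest and flagged as extrapolated.
#'
#' @param response Measured responses.
#' @param low_curve,high_curve `cas_curve` objects for the two ranges.
#' @param dilution_factor Dilution factor(s), recycled.
#' @return Data.frame as [invert_reading()] plus a `curve` column.
#' @export
assign_and_invert <- function(response, low_curve, high_curve,
                              dilution_factor = 1) {
  dilution_factor <- rep_len(dilution_factor, length(response))
  out <- lapply(seq_along(response), function(i) {
    lo <- invert_reading(response[i], low_curve, dilution_factor[i])
    hi <- invert_reading(response[i], high_curve, dilution_factor[i])
    pick <- if (!lo$extrapolated) {
      cbind(lo, curve = low_curve$range_label)
    } else if (!hi$extrapolated) {
      cbind(hi, curve = high_curve$range_label)
    } else {
      # outside both: use whichever range edge is closer
      d_lo <- min(abs(lo$concentration_uM / dilution_factor[i] -
                        low_curve$range))
      d_hi <- min(abs(hi$concentration_uM / dilution_factor[i] -
                        high_curve$range))
      if (d_lo <= d_hi) cbind(lo, curve = low_curve$range_label)
      else cbind(hi, curve = high_curve$range_label)
    }
    pick
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
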