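# Basalt dissolution kinetics: blank/dilution correction, element release
# rates, fold-over-control, and AIC-selected concentration-response fits.
#
# Experimental frame: 0.05 g of washed 53-75 um basalt grains reacted with
# 10 mL of solution for 90 h per phase (water / ligand / water three-phase
# design), solutions diluted fivefold for ICP-MS, blanks deducted.

#' Blank and dilution correction of measured concentrations
#'
#' corrected = dilution_factor x measured - blank. Both measured-after-
#' dilution values and blanks must be on the same unit scale (the blank on
#' the undiluted scale). Negative corrected values are clipped to 0 and
#' flagged: concentrations are physical quantities.
#'
#' @param measured Measured (diluted) concentration(s).
#' @param blank Matched blank concentration(s), undiluted scale.
#' @param dilution_factor Dilution applied before measurement (default 5).
#' @param unit,blank_unit Unit tags; must match.
#' @return Data.frame with `corrected`, `clipped` (logical flag).
#' @examples
#' blank_and_dilution_correct(2, 1, 5)  # corrected 9
#' @export
blank_and_dilution_correct <- function(measured, blank,
                                       dilution_factor = 5,
                                       unit = "mg/L", blank_unit = unit) {
  unit <- rep_len(unit, length(measured))
  blank_unit <- rep_len(blank_unit, length(measured))
  if (any(unit != blank_unit)) {
    stop("unit mismatch between sample and blank", call. = FALSE)
  }
  corrected <- dilution_factor * measured - blank
  clipped <- corrected < 0
  corrected[clipped] <- 0
  data.frame(corrected = corrected, clipped = clipped)
}

#' Element release rate from a dissolution experiment
#'
#' R_X = n_X / (m t) with n_X the moles of element X released into the
#' reacted solution volume, m the basalt mass and t the duration; units
#' mol g^-1 h^-1. Invariant to the concentration unit supplied (uM or
#' mg/L) after conversion.
#'
#' @param concentration Blank/dilution-corrected concentration(s).
#' @param element Element symbol(s) (needed for mg/L and the output name).
#' @param volume_L Solution volume (L), default 0.010.
#' @param mass_g Basalt mass (g), default 0.05.
#' @param duration_h Reaction time (h), default 90.
#' @param unit Concentration unit (`"uM"`, `"mM"`, `"mg/L"`, ...).
#' @return Named numeric vector of rates, mol g^-1 h^-1.
#' @export
release_rate <- function(concentration, element, volume_L = 0.010,
                         mass_g = 0.05, duration_h = 90, unit = "uM") {
  if (any(c(volume_L, mass_g, duration_h) <= 0)) {
    stop("volume, mass and duration must all be > 0", call. = FALSE)
  }
  molar_mass(element)  # validate the symbol even for molar units
  mol_l <- concentration_to_mol_l(concentration, unit, element)
  stats::setNames(mol_l * volume_L / (mass_g * duration_h), element)
}

#' Default element set summed into the whole-rock dissolution rate
#'
#' Mg, Ca, Na, Si, Al, Ti and Fe. Mn is measured in these experiments but
#' excluded from the whole-rock sum by default; pass a custom set to
#' [release_rate_set()] to include it.
#'
#' @format Character vector of element symbols.
#' @export
R_BASALT_ELEMENTS <- c("Mg", "Ca", "Na", "Si", "Al", "Ti", "Fe")

#' Per-element release rates and their whole-rock sum
#'
#' @param rates Named numeric vector of per-element rates
#'   (mol g^-1 h^-1), e.g. from [release_rate()].
#' @param elements Elements summed into `R_basalt`; defaults to
#'   [R_BASALT_ELEMENTS]. Elements absent from `rates` raise an error.
#' @return Object of class `release_rate_set`: list with `rates`
#'   (per-element) and `R_basalt` (exact sum over `elements`).
#' @export
release_rate_set <- function(rates, elements = R_BASALT_ELEMENTS) {
  missing <- setdiff(elements, names(rates))
  if (length(missing)) {
    stop("rates missing for element(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(rates = rates,
                 elements = elements,
                 R_basalt = sum(rates[elements])),
            class = "release_rate_set")
}

#' @export
print.release_rate_set <- function(x, ...) {
  cat("Element release rates (mol g^-1 h^-1):\n")
  print(signif(x$rates, 4))
  cat("R_basalt (sum over ", paste(x$elements, collapse = "+"), "): ",
      format(x$R_basalt, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Fold change of a rate over the ligand-free control
#'
#' @param rate Treatment rate(s).
#' @param control_rate Control rate (> 0 for a defined fold).
#' @return Numeric fold(s); `NA` with a warning when the control is 0.
#' @export
fold_over_control <- function(rate, control_rate) {
  if (length(control_rate) != 1L) {
    stop("control_rate must be a single value", call. = FALSE)
  }
  if (control_rate <= 0) {
    warning("control rate is 0: fold change undefined")
    return(rep(NA_real_, length(rate)))
  }
  rate / control_rate
}

#' Fit and compare linear vs quadratic concentration-response models
#'
#' Ligand-promoted dissolution is first order in dissolved ligand at low
#' surface coverage and saturates as reactive surface sites fill, so a
#' quadratic (saturating, d < 0) polynomial often beats a straight line.
#' Both models are fit by OLS and compared by Akaike's Information
#' Criterion in the RSS form AIC = n log(RSS/n) + 2k, with k counting
#' coefficients plus the error variance. The lower AIC wins; on a tie the
#' model with fewer parameters (linear) wins.
#'
#' @param concentration Ligand concentrations (uM); >= 4 distinct values
#'   for the quadratic to be a candidate.
#' @param rate Observed rates (replicates allowed; supply one row per
#'   observation).
#' @return Object of class `response_fit`: list with per-model
#'   coefficients, RSS and AIC, `selected` (`"linear"` or `"quadratic"`),
#'   `n`, and the selected `lm` fit.
#' @export
fit_response <- function(concentration, rate) {
  keep <- is.finite(concentration) & is.finite(rate)
  x <- concentration[keep]; y <- rate[keep]
  if (length(x) < 3L) stop("need >= 3 points to fit", call. = FALSE)
  lin <- stats::lm(y ~ x)
  rss_lin <- sum(stats::residuals(lin)^2)
  n <- length(x)
  aic_rss <- function(rss, k) {
    # guard log(0): treat an exact fit as -Inf so it always wins on RSS
    if (rss <= 0) -Inf else n * log(rss / n) + 2 * k
  }
  aic_lin <- aic_rss(rss_lin, 3)  # intercept, slope, variance

  quad_ok <- length(unique(x)) >= 4L
  if (quad_ok) {
    quad <- stats::lm(y ~ x + I(x^2))
    rss_quad <- sum(stats::residuals(quad)^2)
    aic_quad <- aic_rss(rss_quad, 4)
  } else {
    quad <- NULL
    rss_quad <- NA_real_
    aic_quad <- NA_real_
  }

  # lower AIC wins; ties (including -Inf vs -Inf) go to the simpler model
  selected <- "linear"
  if (quad_ok && !is.na(aic_quad) && aic_quad < aic_lin) selected <- "quadratic"

  structure(list(
    linear = list(coefficients = stats::coef(lin), rss = rss_lin,
                  aic = aic_lin, k = 3),
    quadratic = if (quad_ok) list(coefficients = stats::coef(quad),
                                  rss = rss_quad, aic = aic_quad, k = 4),
    selected = selected,
    n = n,
    fit = if (selected == "quadratic") quad else lin
  ), class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat("Concentration-response fit (n = ", x$n, ")\n", sep = "")
  cat("  linear    AIC ", format(x$linear$aic, digits = 6),
      "  RSS ", format(x$linear$rss, digits = 4), "\n", sep = "")
  if (!is.null(x$quadratic)) {
    cat("  quadratic AIC ", format(x$quadratic$aic, digits = 6),
        "  RSS ", format(x$quadratic$rss, digits = 4), "\n", sep = "")
  } else {
    cat("  quadratic not a candidate (< 4 distinct concentrations)\n")
  }
  cat("  selected: ", x$selected, "\n", sep = "")
  invisible(x)
}

#' @export
coef.response_fit <- function(object, ...) {
  stats::coef(object$fit)
}

#' @export
predict.response_fit <- function(object, concentration, ...) {
  cf <- stats::coef(object$fit)
  if (object$selected == "quadratic") {
    cf[1] + cf[2] * concentration + cf[3] * concentration^2
  } else {
    cf[1] + cf[2] * concentration
  }
}

#' Pearson trend test
#'
#' Product-moment correlation with the usual t-based two-sided p-value.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return List with `r`, `p`, `n`, `flags`.
#' @export
trend_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                flags = "zero variance; correlation undefined"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       flags = character(0))
}

#' Process a tidy dissolution panel into rates, folds and fits
#'
#' Convenience wrapper over the atomic operations for a long-format panel
#' with columns `sample_id, phase, ligand, ligand_uM, element, value,
#' unit, dilution_factor, blank_value, mass_g, volume_L, duration_h`
#' (the layout written by [simulate_dissolution_panel()]). Rates are
#' computed per phase independently.
#'
#' @param panel Data.frame in the layout above.
#' @return Data.frame of per-row corrected concentrations and rates with
#'   a `clipped` flag.
#' @export
dissolution_rates <- function(panel) {
  need <- c("sample_id", "phase", "ligand", "ligand_uM", "element",
            "value", "unit", "dilution_factor", "blank_value",
            "mass_g", "volume_L", "duration_h")
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    stop("panel missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  corr <- blank_and_dilution_correct(panel$value, panel$blank_value,
                                     panel$dilution_factor,
                                     unit = panel$unit)
  rates <- vapply(seq_len(nrow(panel)), function(i) {
    release_rate(corr$corrected[i], panel$element[i],
                 volume_L = panel$volume_L[i], mass_g = panel$mass_g[i],
                 duration_h = panel$duration_h[i], unit = panel$unit[i])
  }, 0)
  cbind(panel[need[1:5]],
        corrected = corr$corrected, clipped = corr$clipped,
        rate_mol_g_h = rates)
}
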