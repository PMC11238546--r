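# Carbonate speciation, charge balance and CDR stoichiometry.
#
# Weathering of basaltic silicates by carbonic acid stores atmospheric CO2
# as dissolved bicarbonate: per mole of olivine-type mineral, 2 mol of
# divalent base cations and 4 mol of HCO3- enter solution, so divalent
# cation charge equivalents balance bicarbonate equivalents 1:1 and each
# mole of divalent cation accounts for 2 mol of CO2 (1 mol per monovalent).

#' Resolve pH and DIC into carbonate species fractions
#'
#' Given measured pH and total dissolved inorganic carbon (DIC), computes
#' the equilibrium fractions of H2CO3* (dissolved CO2 + true carbonic
#' acid), HCO3- and CO3^2-, and the bicarbonate concentration. Uses
#' freshwater dissociation constants on a concentration basis (activity
#' coefficients taken as 1, appropriate for dilute matrices such as 1 mM
#' KCl); defaults are the 25 degC values pK1 = 6.35, pK2 = 10.33.
#'
#' @param pH Measured pH (0 < pH < 14).
#' @param DIC Total dissolved inorganic carbon, mol/L (>= 0).
#' @param temperature Temperature in degC, metadata only (constants are
#'   supplied explicitly, not recomputed from temperature).
#' @param K1,K2 First and second carbonic-acid dissociation constants.
#'   Set `K2 = 0` to collapse to a two-species system.
#' @return Object of class `speciation_result`: list with `pH`, `DIC`,
#'   `temperature`, `K1`, `K2`, `fractions` (named, sums to 1),
#'   `hco3_mol_l`.
#' @examples
#' sp <- speciate(pH = 7.0, DIC = 1e-3)
#' sp$fractions["HCO3"]
#' @export
speciate <- function(pH, DIC, temperature = 25,
                     K1 = 10^-6.35, K2 = 10^-10.33) {
  stopifnot(length(pH) == 1L, length(DIC) == 1L)
  if (!is.finite(pH) || pH <= 0 || pH >= 14) {
    stop("non-physical pH: ", pH, call. = FALSE)
  }
  if (!is.finite(DIC) || DIC < 0) stop("DIC must be >= 0", call. = FALSE)
  if (K1 <= 0) stop("K1 must be > 0", call. = FALSE)
  if (K2 < 0) stop("K2 must be >= 0", call. = FALSE)

  h <- 10^(-pH)
  # alpha_1 = 1 / (1 + [H+]/K1 + K2/[H+]); alpha_0, alpha_2 follow from the
  # same denominator expressed relative to HCO3-.
  denom <- 1 + h / K1 + K2 / h
  a1 <- 1 / denom
  a0 <- (h / K1) / denom
  a2 <- (K2 / h) / denom
  fractions <- c(H2CO3 = a0, HCO3 = a1, CO3 = a2)

  structure(list(
    pH = pH, DIC = DIC, temperature = temperature, K1 = K1, K2 = K2,
    fractions = fractions,
    hco3_mol_l = a1 * DIC
  ), class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("Carbonate speciation at pH", format(x$pH),
      "(", x$temperature, "degC )\n")
  cat("  DIC:", format(x$DIC, digits = 6), "mol/L\n")
  cat("  fractions: H2CO3*", sprintf("%.4f", x$fractions[["H2CO3"]]),
      " HCO3-", sprintf("%.4f", x$fractions[["HCO3"]]),
      " CO3^2-", sprintf("%.4f", x$fractions[["CO3"]]), "\n")
  cat("  [HCO3-]:", format(x$hco3_mol_l, digits = 6), "mol/L\n")
  invisible(x)
}

#' Charge balance of a reacted weathering solution
#'
#' Sums the charge equivalents of released divalent base cations against
#' the anion equivalents (bicarbonate, chloride and optionally chelator
#' anion charge), and accounts for potassium lost from solution by
#' adsorption onto basalt surfaces and secondary clays.
#'
#' All concentrations in mol/L (equivalents computed internally).
#'
#' @param Ca,Mg Dissolved Ca2+ and Mg2+ (mol/L).
#' @param HCO3 Bicarbonate (mol/L), e.g. from [speciate()].
#' @param Cl Chloride (mol/L).
#' @param K_initial,K_final Potassium before/after reaction (mol/L).
#' @param chelator_anion_eq Charge contribution of dissolved chelator
#'   anions (eq/L); defaults to 0 as their speciation is usually unknown.
#' @return Object of class `charge_balance`: list with `cation_eq`,
#'   `anion_eq`, `residual` (cation - anion), `K_adsorbed_mol_l`,
#'   `K_adsorbed_fraction`, `flags`.
#' @export
charge_balance <- function(Ca, Mg, HCO3, Cl = 0,
                           K_initial = 0, K_final = 0,
                           chelator_anion_eq = 0) {
  vals <- c(Ca = Ca, Mg = Mg, HCO3 = HCO3, Cl = Cl,
            K_initial = K_initial, K_final = K_final)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all concentrations must be finite and >= 0", call. = FALSE)
  }
  flags <- character(0)
  k_ads <- K_initial - K_final
  if (k_ads < 0) {
    flags <- c(flags, "K_final exceeds K_initial; adsorption floored at 0")
    k_ads <- 0
  }
  k_frac <- if (K_initial > 0) k_ads / K_initial else NA_real_
  cation_eq <- 2 * Ca + 2 * Mg
  anion_eq <- HCO3 + Cl + chelator_anion_eq

  structure(list(
    cation_eq = cation_eq,
    anion_eq = anion_eq,
    residual = cation_eq - anion_eq,
    K_adsorbed_mol_l = k_ads,
    K_adsorbed_fraction = k_frac,
    flags = flags
  ), class = "charge_balance")
}

#' @export
print.charge_balance <- function(x, ...) {
  cat("Charge balance (eq/L): cations", format(x$cation_eq, digits = 6),
      "vs anions", format(x$anion_eq, digits = 6),
      "; residual", format(x$residual, digits = 6), "\n")
  if (!is.na(x$K_adsorbed_fraction)) {
    cat("  K adsorbed:", format(x$K_adsorbed_mol_l, digits = 6), "mol/L (",
        sprintf("%.1f%%", 100 * x$K_adsorbed_fraction), "of added K )\n")
  }
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' CO2 removal potential from released base cations
#'
#' Converts net cation release into moles and mass of CO2 stored as
#' bicarbonate, using the carbonic-acid weathering stoichiometry: 2 mol
#' CO2 per mol of divalent cation (Ca, Mg), 1 mol per mol of monovalent
#' cation (Na, K). Negative deltas (net loss) propagate through with a
#' flag rather than being clipped, so net accounting stays honest.
#'
#' @param delta_cations Named numeric vector of net cation release. Names
#'   must be element symbols among Ca, Mg, Na, K.
#' @param basis `"mol"` (values already in moles, or mol per kg/ha — any
#'   consistent molar unit) or `"mass"` (values in grams of element, or
#'   mg/kg etc.; converted via molar masses, output in matching molar and
#'   CO2-mass units).
#' @return Object of class `cdr_potential`: list with `cations_mol`
#'   (per-cation moles), `mol_co2`, `mass_co2_g` (mol x 44.01; interpret
#'   the mass unit consistently with the input unit), `flags`.
#' @examples
#' cdr_from_cations(c(Mg = 1))$mol_co2   # 2
#' cdr_from_cations(c(Na = 2))$mol_co2   # 2
#' @export
cdr_from_cations <- function(delta_cations, basis = c("mol", "mass")) {
  basis <- match.arg(basis)
  valence <- c(Ca = 2, Mg = 2, Na = 1, K = 1)
  nm <- names(delta_cations)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("delta_cations must be a named vector", call. = FALSE)
  }
  bad <- setdiff(nm, names(valence))
  if (length(bad)) {
    stop("unknown element(s) for CDR stoichiometry: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mol <- if (basis == "mass") {
    delta_cations / molar_mass(nm)
  } else {
    delta_cations
  }
  flags <- character(0)
  if (any(mol < 0)) {
    flags <- c(flags, paste0("negative net release for: ",
                             paste(nm[mol < 0], collapse = ", ")))
  }
  mol_co2 <- sum(valence[nm] * mol)
  structure(list(
    cations_mol = mol,
    mol_co2 = mol_co2,
    mass_co2_g = mol_co2 * CO2_MOLAR_MASS,
    flags = flags
  ), class = "cdr_potential")
}

#' @export
print.cdr_potential <- function(x, ...) {
  cat("CDR potential:", format(x$mol_co2, digits = 6), "mol CO2 (",
      format(x$mass_co2_g, digits = 6), "g CO2 )\n")
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' Regression of divalent-cation equivalents on bicarbonate equivalents
#'
#' Ordinary least squares of summed (Ca2+ + Mg2+) charge equivalents on
#' measured bicarbonate (plus chloride, if supplied pre-summed)
#' equivalents, reporting the slope, intercept, Pearson r and the root
#' mean square distance of the points from the 1:1 line — the check that
#' released base cations track alkalinity production.
#'
#' @param cation_eq Divalent cation charge equivalents (eq/L), numeric.
#' @param anion_eq Matching HCO3- (+ Cl-) equivalents (eq/L).
#' @return List with `slope`, `intercept`, `r`, `rmsd_identity`, `n`,
#'   `flags`.
#' @export
cation_hco3_regression <- function(cation_eq, anion_eq) {
  if (length(cation_eq) != length(anion_eq)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  keep <- is.finite(cation_eq) & is.finite(anion_eq)
  x <- anion_eq[keep]; y <- cation_eq[keep]
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  flags <- character(0)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                rmsd_identity = sqrt(mean((y - x)^2)), n = length(x),
                flags = "zero variance; regression undefined"))
  }
  fit <- stats::lm(y ~ x)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = stats::cor(x, y),
    rmsd_identity = sqrt(mean((y - x)^2)),
    n = length(x),
    flags = flags
  )
}
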