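# Shared constants and small helpers.

#' Atomic and molecular masses used throughout the package
#'
#' Standard atomic weights (g/mol) for the elements handled by the
#' dissolution and CDR modules, plus carbon dioxide.
#'
#' @format Named numeric vector, g/mol.
#' @export
ELEMENT_MOLAR_MASS <- c(
  Ca = 40.078, Mg = 24.305, Na = 22.990, K = 39.098,
  Si = 28.086, Al = 26.982, Ti = 47.867, Fe = 55.845,
  Mn = 54.938, P = 30.974
)

#' @rdname ELEMENT_MOLAR_MASS
#' @export
CO2_MOLAR_MASS <- 44.01

#' Molar mass of an element
#'
#' @param element Element symbol (e.g. `"Fe"`).
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(element) {
  m <- ELEMENT_MOLAR_MASS[element]
  if (anyNA(m)) {
    stop("unknown element symbol: ",
         paste(element[is.na(m)], collapse = ", "), call. = FALSE)
  }
  unname(m)
}

#' Convert a concentration to mol/L
#'
#' Accepts micromolar (`"uM"`), millimolar (`"mM"`), molar (`"M"`),
#' `"mol/L"`, or mass-based `"mg/L"` / `"ug/L"` (which require the element
#' symbol for the molar mass).
#'
#' @param value Numeric concentration(s).
#' @param unit Unit tag, one per value or a single tag recycled.
#' @param element Element symbol, needed for mass-based units.
#' @return Concentration in mol/L.
#' @export
concentration_to_mol_l <- function(value, unit, element = NULL) {
  unit <- rep_len(unit, length(value))
  out <- numeric(length(value))
  for (i in seq_along(value)) {
    out[i] <- switch(unit[i],
      "uM"    = value[i] * 1e-6,
      "µM" = value[i] * 1e-6,
      "mM"    = value[i] * 1e-3,
      "M"     = value[i],
      "mol/L" = value[i],
      "mg/L"  = {
        if (is.null(element)) stop("mg/L conversion needs an element symbol",
                                   call. = FALSE)
        el <- rep_len(element, length(value))[i]
        value[i] / 1000 / molar_mass(el)
      },
      "ug/L"  = {
        if (is.null(element)) stop("ug/L conversion needs an element symbol",
                                   call. = FALSE)
        el <- rep_len(element, length(value))[i]
        value[i] / 1e6 / molar_mass(el)
      },
      stop("unsupported concentration unit: ", unit[i], call. = FALSE)
    )
  }
  out
}

# Derive a deterministic per-stream sub-seed from one global seed so
# independent generators do not share a random stream. Kept below 2^31.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(hits = 104729L, dissolution = 1299709L, incubation = 15485863L,
               cas = 32452843L, misc = 49979687L)
  if (!stream %in% names(offsets)) stop("unknown stream: ", stream)
  as.integer((as.numeric(seed) + offsets[[stream]]) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
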