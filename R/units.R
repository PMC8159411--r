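#' @title Physical constants and energy-unit conversion
#' @name units
#' @description
#' All energies in the package flow through three units: hartree (atomic
#' units, the native unit of quantum-chemistry orbital energies), electron
#' volt (the conventional unit of conceptual-DFT indices), and kcal/mol
#' (the conventional unit of reaction free energies and barriers).
#' Conversions use full-precision CODATA-style constants rather than the
#' rounded factors common in print; rounding to printed precision is applied
#' only at the reporting stage (see [round_half_up()]).
NULL

#' Energy conversion factors and physical constants
#'
#' @format A named list:
#' \describe{
#'   \item{hartree_to_ev}{27.211386 eV per hartree}
#'   \item{ev_to_kcal}{23.060548 kcal/mol per eV}
#'   \item{R_kcal}{gas constant, 1.98720425e-3 kcal/(mol K)}
#'   \item{kB}{Boltzmann constant, 1.380649e-23 J/K}
#'   \item{h}{Planck constant, 6.62607015e-34 J s}
#'   \item{T_default}{298.15 K, room temperature, the default throughout}
#' }
#' @export
chemosel_constants <- list(
  hartree_to_ev = 27.211386,
  ev_to_kcal    = 23.060548,
  R_kcal        = 1.98720425e-3,
  kB            = 1.380649e-23,
  h             = 6.62607015e-34,
  T_default     = 298.15
)

.energy_units <- c("hartree", "eV", "kcal/mol")

# factor taking one unit to eV
.to_ev_factor <- c(
  hartree    = 27.211386,
  eV         = 1,
  `kcal/mol` = 1 / 23.060548
)

#' Normalize an energy unit name
#'
#' Accepts the canonical spellings used in CSV headers ("hartree", "eV",
#' "kcal/mol") plus common aliases ("au", "a.u.", "ev", "kcal_per_mol",
#' "kcal").
#'
#' @param unit character unit name.
#' @return canonical unit string.
#' @export
normalize_unit <- function(unit) {
  stopifnot(is.character(unit))
  key <- tolower(gsub("[ ._]", "", unit))
  map <- c(
    hartree = "hartree", au = "hartree", hartrees = "hartree",
    ev = "eV", electronvolt = "eV",
    `kcal/mol` = "kcal/mol", kcalmol = "kcal/mol", kcal = "kcal/mol",
    kcalpermol = "kcal/mol", `kcalmol-1` = "kcal/mol"
  )
  out <- unname(map[key])
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown energy unit: ", paste(unique(unit[bad]), collapse = ", "),
         " (expected one of ", paste(.energy_units, collapse = ", "), ")",
         call. = FALSE)
  }
  out
}

#' Convert energies between hartree, eV and kcal/mol
#'
#' Conversion is linear and exact up to floating point; round-trips through
#' any cycle of units reproduce the input to ~1e-12 relative.
#'
#' @param x numeric vector of energy magnitudes.
#' @param from,to unit names (see [normalize_unit()]).
#' @return numeric vector in `to` units.
#' @examples
#' energy_convert(1, "hartree", "eV")        # 27.211386
#' energy_convert(-0.38586, "hartree", "eV") # approx -10.5007
#' @export
energy_convert <- function(x, from, to) {
  stopifnot(is.numeric(x))
  from <- normalize_unit(from)
  to <- normalize_unit(to)
  x * .to_ev_factor[[from]] / .to_ev_factor[[to]]
}

#' Validate a temperature in kelvin
#'
#' @param T numeric scalar, kelvin.
#' @return the validated temperature, invisibly usable.
#' @export
check_temperature <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0) {
    stop("temperature must be a single finite value > 0 K", call. = FALSE)
  }
  T
}

#' Round half away from zero at a fixed number of decimals
#'
#' Printed chemistry values round half up (2.45 -> 2.5), unlike R's
#' banker's rounding.  Used for comparisons against literature values
#' reported at fixed decimal precision.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' RT in kcal/mol at a given temperature
#'
#' @param T temperature in kelvin.
#' @return RT in kcal/mol.
#' @export
rt_kcal <- function(T = chemosel_constants$T_default) {
  check_temperature(T)
  chemosel_constants$R_kcal * T
}
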