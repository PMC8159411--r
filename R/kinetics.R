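#' @title Free-energy differences to observables
#' @name kinetics
#' @description
#' Two-pathway Boltzmann statistics convert a free-energy gap
#' \eqn{\Delta\Delta G^\ddagger} between competing (e.g.
#' enantio-determining) transition states into an enantiomeric excess or a
#' product ratio, and the Eyring equation converts a single barrier into a
#' unimolecular rate constant.  All conversions assume a single gap per
#' competition (no Curtin--Hammett conformer averaging) and a transmission
#' coefficient of 1.
NULL

#' Enantiomeric excess from a transition-state free-energy gap
#'
#' ee = 100 (e^(ddg/RT) - 1) / (e^(ddg/RT) + 1) = 100 tanh(ddg / 2RT).
#' A 2.4 kcal/mol gap at room temperature gives 96.6% ee; 0.8 kcal/mol
#' gives 59%.
#'
#' @param ddg free-energy difference between the two competing transition
#'   states, kcal/mol; must be >= 0 (order the barriers first).
#' @param T temperature in kelvin (default 298.15).
#' @return ee in percent, in `[0, 100)`.
#' @examples
#' ee_from_ddg(2.4)  # 96.6 after rounding to 1 decimal
#' @export
ee_from_ddg <- function(ddg, T = chemosel_constants$T_default) {
  check_temperature(T)
  stopifnot(is.numeric(ddg), all(is.finite(ddg)))
  if (any(ddg < 0)) {
    stop("ddg must be >= 0: pass the barrier difference |dG(minor) - dG(major)|",
         call. = FALSE)
  }
  100 * tanh(ddg / (2 * rt_kcal(T)))
}

#' Free-energy gap implied by an enantiomeric excess
#'
#' Exact inverse of [ee_from_ddg()]: ddg = RT log((1 + e)/(1 - e)) with
#' e = ee/100.
#'
#' @param ee enantiomeric excess in percent, `0 <= ee < 100`.
#' @param T temperature in kelvin.
#' @return ddg in kcal/mol.
#' @export
ddg_from_ee <- function(ee, T = chemosel_constants$T_default) {
  check_temperature(T)
  stopifnot(is.numeric(ee), all(is.finite(ee)))
  if (any(ee < 0) || any(ee >= 100)) {
    stop("ee must lie in [0, 100): 100% ee implies an infinite gap",
         call. = FALSE)
  }
  e <- ee / 100
  rt_kcal(T) * log((1 + e) / (1 - e))
}

#' Product ratio from a free-energy gap
#'
#' r = e^(ddg/RT) >= 1, the Boltzmann ratio of the two channels; related
#' to ee by ee/100 = (r - 1)/(r + 1).
#'
#' @inheritParams ee_from_ddg
#' @return dimensionless major:minor ratio.
#' @export
ratio_from_ddg <- function(ddg, T = chemosel_constants$T_default) {
  check_temperature(T)
  stopifnot(is.numeric(ddg), all(is.finite(ddg)))
  if (any(ddg < 0)) stop("ddg must be >= 0", call. = FALSE)
  exp(ddg / rt_kcal(T))
}

#' Eyring rate constant from an activation free energy
#'
#' k = (k_B T / h) e^(-dg/RT), transmission coefficient 1.  At 298.15 K
#' the prefactor k_B T / h is about 6.21e12 per second.
#'
#' @param dg activation free energy in kcal/mol.
#' @param T temperature in kelvin.
#' @return rate constant in s^-1.
#' @export
eyring_rate <- function(dg, T = chemosel_constants$T_default) {
  check_temperature(T)
  stopifnot(is.numeric(dg), all(is.finite(dg)))
  with(chemosel_constants, kB * T / h) * exp(-dg / rt_kcal(T))
}
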