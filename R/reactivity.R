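#' @title Global conceptual-DFT reactivity indices
#' @name reactivity
#' @description
#' Global reactivity indices condense a species' frontier-orbital energies
#' into scalar descriptors of its electron-donating/accepting power:
#' chemical potential \eqn{\mu = (E_H + E_L)/2}, hardness
#' \eqn{\eta = E_L - E_H}, electrophilicity \eqn{\omega = \mu^2 / 2\eta},
#' and nucleophilicity \eqn{N = E_H - E_H(\mathrm{TCNE})} measured against
#' the HOMO of tetracyanoethylene, a very poor electron donor, so that N is
#' positive for ordinary nucleophiles.  All indices are reported in eV
#' regardless of input unit.
NULL

#' HOMO energy of the tetracyanoethylene (TCNE) nucleophilicity reference
#'
#' The conventional zero of the nucleophilicity scale: N(TCNE) = 0 by
#' construction.  Value in hartree.
#' @export
TCNE_EH_HARTREE <- -0.38586

#' Construct a frontier-orbital pair
#'
#' @param species_id character label for the species.
#' @param E_H,E_L HOMO and LUMO energies (numeric scalars).
#' @param unit unit of both energies, `"hartree"` or `"eV"`.
#' @return an `orbital_pair` object with energies stored in eV.
#' @examples
#' orbital_pair("ethylene", -13.7, -8.3, unit = "eV")
#' @export
orbital_pair <- function(species_id, E_H, E_L, unit = "eV") {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            is.numeric(E_H), length(E_H) == 1L, is.finite(E_H),
            is.numeric(E_L), length(E_L) == 1L, is.finite(E_L))
  eh <- energy_convert(E_H, unit, "eV")
  el <- energy_convert(E_L, unit, "eV")
  if (el <= eh) {
    stop("non-physical frontier gap for '", species_id,
         "': E_LUMO (", signif(el, 6), " eV) must lie above E_HOMO (",
         signif(eh, 6), " eV)", call. = FALSE)
  }
  structure(list(species_id = species_id, E_H_eV = eh, E_L_eV = el),
            class = "orbital_pair")
}

#' @export
print.orbital_pair <- function(x, ...) {
  cat(sprintf("<orbital_pair> %s: E_HOMO = %.4f eV, E_LUMO = %.4f eV\n",
              x$species_id, x$E_H_eV, x$E_L_eV))
  invisible(x)
}

.as_orbital_pair <- function(x) {
  if (!inherits(x, "orbital_pair")) {
    stop("expected an orbital_pair object; see orbital_pair()", call. = FALSE)
  }
  x
}

#' Electronic chemical potential
#'
#' \eqn{\mu = (E_H + E_L)/2}, the negative of the Mulliken
#' electronegativity.
#'
#' @param orbitals an [orbital_pair()].
#' @return chemical potential in eV.
#' @export
chemical_potential <- function(orbitals) {
  o <- .as_orbital_pair(orbitals)
  (o$E_H_eV + o$E_L_eV) / 2
}

#' Chemical hardness
#'
#' \eqn{\eta = E_L - E_H}, the frontier-orbital gap; strictly positive for
#' any valid pair.
#'
#' @inheritParams chemical_potential
#' @return hardness in eV.
#' @export
hardness <- function(orbitals) {
  o <- .as_orbital_pair(orbitals)
  o$E_L_eV - o$E_H_eV
}

#' Global electrophilicity index
#'
#' \eqn{\omega = \mu^2 / 2\eta}: the stabilization a species gains on
#' soaking up electrons from an idealized electron bath.  Non-negative by
#' construction.
#'
#' @inheritParams chemical_potential
#' @return electrophilicity in eV.
#' @export
electrophilicity <- function(orbitals) {
  chemical_potential(orbitals)^2 / (2 * hardness(orbitals))
}

#' Global nucleophilicity index
#'
#' \eqn{N = E_H(\mathrm{species}) - E_H(\mathrm{reference})} with the
#' tetracyanoethylene HOMO as the default reference, so N(TCNE) = 0 and
#' better electron donors score higher.
#'
#' @inheritParams chemical_potential
#' @param ref_E_H reference HOMO energy; defaults to [TCNE_EH_HARTREE].
#' @param ref_unit unit of `ref_E_H`.
#' @return nucleophilicity in eV.
#' @export
nucleophilicity <- function(orbitals, ref_E_H = TCNE_EH_HARTREE,
                            ref_unit = "hartree") {
  o <- .as_orbital_pair(orbitals)
  o$E_H_eV - energy_convert(ref_E_H, ref_unit, "eV")
}

#' All four global indices for one species
#'
#' @inheritParams nucleophilicity
#' @return a one-row data frame: `species`, `mu_eV`, `eta_eV`, `omega_eV`,
#'   `N_eV`.
#' @examples
#' pair <- orbital_pair("M2", -9, -1, unit = "eV")
#' global_indices(pair)
#' @export
global_indices <- function(orbitals, ref_E_H = TCNE_EH_HARTREE,
                           ref_unit = "hartree") {
  o <- .as_orbital_pair(orbitals)
  data.frame(
    species  = o$species_id,
    mu_eV    = chemical_potential(o),
    eta_eV   = hardness(o),
    omega_eV = electrophilicity(o),
    N_eV     = nucleophilicity(o, ref_E_H, ref_unit),
    stringsAsFactors = FALSE
  )
}

#' Global indices for a table of species
#'
#' Vectorized front end used by the CSV workflow: one output row per input
#' row, in input order.
#'
#' @param tbl data frame with columns `species`, `E_HOMO`, `E_LUMO`, `unit`
#'   (unit per row, `"hartree"` or `"eV"`).
#' @inheritParams nucleophilicity
#' @return data frame `species`, `mu_eV`, `eta_eV`, `omega_eV`, `N_eV`.
#' @export
global_indices_table <- function(tbl, ref_E_H = TCNE_EH_HARTREE,
                                 ref_unit = "hartree") {
  required <- c("species", "E_HOMO", "E_LUMO", "unit")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop("orbital table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tbl) == 0L) {
    return(data.frame(species = character(), mu_eV = numeric(),
                      eta_eV = numeric(), omega_eV = numeric(),
                      N_eV = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(tbl)), function(i) {
    pair <- orbital_pair(as.character(tbl$species[i]),
                         tbl$E_HOMO[i], tbl$E_LUMO[i],
                         unit = as.character(tbl$unit[i]))
    global_indices(pair, ref_E_H, ref_unit)
  })
  do.call(rbind, rows)
}
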