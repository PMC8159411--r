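#' @title Local Parr functions from vertical radical-ion spin populations
#' @name parr
#' @description
#' Parr functions localize global reactivity onto atoms.  The nucleophilic
#' Parr function \eqn{P^-_k} is the atomic spin density of the species'
#' vertical radical cation (where the hole sits is where electrons are
#' easiest to give); the electrophilic Parr function \eqn{P^+_k} is the
#' atomic spin density of the vertical radical anion (where the extra
#' electron sits is where one is easiest to accept).  The atom with maximal
#' \eqn{P^-_k} (\eqn{P^+_k}) is the preferred nucleophilic (electrophilic)
#' site.
NULL

#' Construct a per-atom spin population for a vertical radical ion
#'
#' @param species_id character label.
#' @param state `"radical_cation"` or `"radical_anion"`.
#' @param spin_density numeric vector of atomic spin densities (one
#'   unpaired electron: should sum to about 1; small negative values are
#'   admissible).
#' @param atom_index 1-based atom indices (default sequential).
#' @param atom_label optional atom labels (e.g. `"C6"`, `"Cbeta"`).
#' @param sum_tolerance allowed deviation of the raw sum from 1 before a
#'   warning is recorded (default 0.05).
#' @return a `spin_population` object.
#' @export
spin_population <- function(species_id, state, spin_density,
                            atom_index = seq_along(spin_density),
                            atom_label = paste0("A", atom_index),
                            sum_tolerance = 0.05) {
  state <- match.arg(state, c("radical_cation", "radical_anion"))
  stopifnot(is.numeric(spin_density), length(spin_density) >= 1L,
            all(is.finite(spin_density)),
            length(atom_index) == length(spin_density),
            length(atom_label) == length(spin_density))
  atom_index <- as.integer(atom_index)
  if (anyDuplicated(atom_index)) {
    stop("atom indices must be unique", call. = FALSE)
  }
  structure(list(species_id = species_id, state = state,
                 atom_index = atom_index,
                 atom_label = as.character(atom_label),
                 spin_density = as.numeric(spin_density),
                 sum_tolerance = sum_tolerance),
            class = "spin_population")
}

#' Parr function of a vertical radical-ion spin population
#'
#' Radical-cation spin density gives the nucleophilic Parr function
#' \eqn{P^-_k}; radical-anion spin density gives the electrophilic
#' \eqn{P^+_k}.
#'
#' @param pop a [spin_population()].
#' @param renormalize divide by the algebraic sum so values add to exactly
#'   1 (default `TRUE`).
#' @return a `parr_vector` object: fields `species_id`, `kind`
#'   (`"P_minus"` or `"P_plus"`), `atom_index`, `atom_label`, `value`, and
#'   `provenance` (records renormalization and any sum warning).
#' @examples
#' pop <- spin_population("M5", "radical_cation", c(0.5, 0.3, 0.2))
#' parr_function(pop)
#' @export
parr_function <- function(pop, renormalize = TRUE) {
  if (!inherits(pop, "spin_population")) {
    stop("expected a spin_population object", call. = FALSE)
  }
  s <- sum(pop$spin_density)
  if (s <= 0) {
    stop("sum of spin densities must be positive (got ", signif(s, 6), ")",
         call. = FALSE)
  }
  provenance <- character()
  if (abs(s - 1) > pop$sum_tolerance) {
    msg <- sprintf(
      "spin densities sum to %.4f (|sum - 1| exceeds tolerance %.3f)",
      s, pop$sum_tolerance)
    if (!renormalize) warning(msg, call. = FALSE)
    provenance <- c(provenance, msg)
  }
  value <- if (renormalize) pop$spin_density / s else pop$spin_density
  if (renormalize) provenance <- c(provenance, sprintf("renormalized by sum %.6g", s))
  kind <- if (pop$state == "radical_cation") "P_minus" else "P_plus"
  structure(list(species_id = pop$species_id, kind = kind,
                 atom_index = pop$atom_index, atom_label = pop$atom_label,
                 value = value, provenance = provenance),
            class = "parr_vector")
}

#' @export
print.parr_vector <- function(x, ...) {
  sym <- if (x$kind == "P_minus") "P-_k" else "P+_k"
  cat(sprintf("<parr_vector> %s (%s)\n", x$species_id, sym))
  print(data.frame(atom = x$atom_label, index = x$atom_index,
                   value = round(x$value, 4)))
  invisible(x)
}

#' Most reactive atom of a Parr vector
#'
#' Returns the atom with the maximal (signed) Parr value; ties are broken
#' toward the lowest atom index and flagged.
#'
#' @param parr a `parr_vector` from [parr_function()].
#' @param tie_tolerance absolute tolerance for declaring a tie (default 0,
#'   exact equality).
#' @return list with `atom_index`, `atom_label`, `value`, `tie` (logical),
#'   and `tied_with` (indices of co-maximal atoms, if any).
#' @export
reactive_site <- function(parr, tie_tolerance = 0) {
  if (!inherits(parr, "parr_vector")) {
    stop("expected a parr_vector object", call. = FALSE)
  }
  if (length(parr$value) == 0L) stop("empty Parr vector", call. = FALSE)
  vmax <- max(parr$value)
  at_max <- which(parr$value >= vmax - tie_tolerance)
  # lowest atom index among the co-maximal atoms wins
  winner <- at_max[which.min(parr$atom_index[at_max])]
  list(atom_index = parr$atom_index[winner],
       atom_label = parr$atom_label[winner],
       value = parr$value[winner],
       tie = length(at_max) > 1L,
       tied_with = setdiff(parr$atom_index[at_max], parr$atom_index[winner]))
}

#' Parr functions for a spin-population table
#'
#' Table front end over [parr_function()]: input rows are grouped by
#' `(species, state)` and each group yields one Parr vector.
#'
#' @param tbl data frame with columns `species`, `state`, `atom_index`,
#'   `atom_label`, `spin_density`.
#' @param renormalize passed to [parr_function()].
#' @return data frame `species`, `kind`, `atom_index`, `atom_label`,
#'   `parr_value` in input order.
#' @export
parr_table <- function(tbl, renormalize = TRUE) {
  required <- c("species", "state", "atom_index", "atom_label", "spin_density")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop("spin table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(tbl$species, tbl$state, sep = "\r")
  out <- lapply(unique(key), function(k) {
    g <- tbl[key == k, , drop = FALSE]
    pv <- parr_function(
      spin_population(as.character(g$species[1]), as.character(g$state[1]),
                      g$spin_density, g$atom_index, g$atom_label),
      renormalize = renormalize)
    data.frame(species = pv$species_id, kind = pv$kind,
               atom_index = pv$atom_index, atom_label = pv$atom_label,
               parr_value = pv$value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
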