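#' @title CSV and JSON input/output dialects
#' @name io
#' @description
#' Plain-text table dialects shared by the command-line workflow:
#' orbital energies (`species,E_HOMO,E_LUMO,unit`), spin populations
#' (`species,state,atom_index,atom_label,spin_density`), LFER calibration
#' points (`label,omega_E_eV,N_Nu_eV,barrier_kcal,excluded,reason`) and
#' pathway profiles (`pathway,point_name,kind,g_rel_kcal`).  All files
#' are UTF-8 comma-separated with a header row.
NULL

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop(path, " lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tbl
}

#' Read an orbital-energy CSV
#' @param path file with header `species,E_HOMO,E_LUMO,unit`.
#' @return data frame in the orbital dialect.
#' @export
read_orbital_csv <- function(path) {
  .read_csv_checked(path, c("species", "E_HOMO", "E_LUMO", "unit"))
}

#' Read a spin-population CSV
#' @param path file with header
#'   `species,state,atom_index,atom_label,spin_density`.
#' @return data frame in the spin dialect.
#' @export
read_spin_csv <- function(path) {
  .read_csv_checked(path, c("species", "state", "atom_index", "atom_label",
                            "spin_density"))
}

#' Read an LFER calibration CSV
#' @param path file with header
#'   `label,omega_E_eV,N_Nu_eV,barrier_kcal,excluded,reason`.
#' @return data frame; `excluded` coerced to logical.
#' @export
read_calibration_csv <- function(path) {
  tbl <- .read_csv_checked(path, c("label", "omega_E_eV", "N_Nu_eV",
                                   "barrier_kcal", "excluded", "reason"))
  tbl$excluded <- as.logical(tbl$excluded)
  tbl$reason[is.na(tbl$reason)] <- ""
  tbl
}

#' Read a multi-pathway profile CSV
#'
#' @param path file with header `pathway,point_name,kind,g_rel_kcal`;
#'   point order within a pathway is file order; `kind` is `min` or `ts`.
#' @return named list of [pathway_profile()] objects in first-appearance
#'   order.
#' @export
read_profile_csv <- function(path) {
  tbl <- .read_csv_checked(path, c("pathway", "point_name", "kind",
                                   "g_rel_kcal"))
  profiles_from_table(tbl)
}

#' Build pathway profiles from a long table
#' @param tbl data frame with columns `pathway`, `point_name`, `kind`,
#'   `g_rel_kcal`.
#' @return named list of [pathway_profile()] objects.
#' @export
profiles_from_table <- function(tbl) {
  ids <- unique(tbl$pathway)
  out <- lapply(ids, function(id) {
    g <- tbl[tbl$pathway == id, , drop = FALSE]
    pathway_profile(id, g$point_name, g$kind, g$g_rel_kcal)
  })
  names(out) <- ids
  out
}

#' Write a data frame as CSV (no row names, no quoting surprises)
#' @param tbl data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a report object as JSON
#'
#' Deterministic serialization (no digit truncation, unboxed scalars) so
#' repeated runs with identical inputs are byte-identical.
#'
#' @param x list or data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
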