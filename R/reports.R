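#' @title End-to-end workflow runners and selectivity reports
#' @name reports
#' @description
#' Thin orchestration over the computational modules: indices from an
#' orbital table, barrier predictions from Nu/E pairs, and the full
#' pathway ranking with the kinetics-plus-thermodynamics product call.
#' Every report echoes its configuration and model provenance so a run
#' can be audited and reproduced; JSON output is deterministic.
NULL

.schema_version <- "1"

#' Workflow configuration
#'
#' @param temperature kelvin (default 298.15).
#' @param irreversibility_threshold kcal/mol (default 10).
#' @param rounding_mode `"full_precision"` or `"paper_comparison"` (round
#'   reported barriers/ee to the 1-decimal precision of printed
#'   literature values).
#' @param seed integer seed echoed into reports (used by synthetic-input
#'   generation).
#' @return a validated `run_config` list.
#' @export
run_config <- function(temperature = chemosel_constants$T_default,
                       irreversibility_threshold = 10,
                       rounding_mode = c("full_precision",
                                         "paper_comparison"),
                       seed = NA_integer_) {
  check_temperature(temperature)
  stopifnot(is.numeric(irreversibility_threshold),
            irreversibility_threshold >= 0)
  rounding_mode <- match.arg(rounding_mode)
  structure(list(temperature = temperature,
                 irreversibility_threshold = irreversibility_threshold,
                 rounding_mode = rounding_mode,
                 seed = seed), class = "run_config")
}

.config_echo <- function(config) {
  list(schema_version = .schema_version,
       tool = "chemosel",
       version = as.character(utils::packageVersion("chemosel")),
       temperature_K = config$temperature,
       irreversibility_threshold_kcal = config$irreversibility_threshold,
       rounding_mode = config$rounding_mode,
       seed = if (is.na(config$seed)) NULL else config$seed)
}

#' Global indices for an orbital table, as a report
#'
#' Rows with a non-positive frontier gap are reported as per-row errors;
#' the remaining rows still compute.
#'
#' @param config a [run_config()].
#' @param orbital_tbl data frame in the orbital dialect (or a path to an
#'   orbital CSV).
#' @return list: `config`, `indices` (data frame), `errors` (data frame
#'   of failed rows, possibly empty), `n_failed`.
#' @export
run_indices <- function(config = run_config(), orbital_tbl) {
  if (is.character(orbital_tbl)) orbital_tbl <- read_orbital_csv(orbital_tbl)
  ok <- list(); bad <- list()
  if (nrow(orbital_tbl) == 0L) {
    warning("orbital table has no data rows", call. = FALSE)
  }
  for (i in seq_len(nrow(orbital_tbl))) {
    res <- tryCatch(
      global_indices(orbital_pair(as.character(orbital_tbl$species[i]),
                                  orbital_tbl$E_HOMO[i],
                                  orbital_tbl$E_LUMO[i],
                                  unit = as.character(orbital_tbl$unit[i]))),
      error = function(e) e)
    if (inherits(res, "error")) {
      bad[[length(bad) + 1L]] <- data.frame(
        row = i, species = as.character(orbital_tbl$species[i]),
        message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      ok[[length(ok) + 1L]] <- res
    }
  }
  empty <- data.frame(species = character(), mu_eV = numeric(),
                      eta_eV = numeric(), omega_eV = numeric(),
                      N_eV = numeric(), stringsAsFactors = FALSE)
  list(config = .config_echo(config),
       indices = if (length(ok)) do.call(rbind, ok) else empty,
       errors = if (length(bad)) do.call(rbind, bad) else
         data.frame(row = integer(), species = character(),
                    message = character(), stringsAsFactors = FALSE),
       n_failed = length(bad))
}

#' Barrier predictions for Nu/E pairs, as a report fragment
#'
#' @param config a [run_config()].
#' @param pairs_tbl data frame with columns `label`, `omega_E_eV`,
#'   `N_Nu_eV` (or a calibration CSV path; barrier/excluded columns are
#'   ignored here).
#' @param model an [lfer_model()], or `"published"`.
#' @return list: `config`, `model` (coefficients + provenance),
#'   `predictions` (ranked data frame from [rank_pairs()]).
#' @export
run_predict <- function(config = run_config(), pairs_tbl,
                        model = "published") {
  if (is.character(pairs_tbl)) {
    pairs_tbl <- .read_csv_checked(pairs_tbl,
                                   c("label", "omega_E_eV", "N_Nu_eV"))
  }
  if (identical(model, "published")) {
    message("no model supplied; using the published calibration")
    model <- published_model()
  }
  pairs <- lapply(seq_len(nrow(pairs_tbl)), function(i)
    reactivity_pair(as.character(pairs_tbl$label[i]),
                    pairs_tbl$omega_E_eV[i], pairs_tbl$N_Nu_eV[i]))
  ranked <- rank_pairs(model, pairs,
                       paper_rounding = config$rounding_mode == "paper_comparison")
  list(config = .config_echo(config),
       model = list(intercept = model$intercept, slope = model$slope,
                    r_squared = model$r_squared, n_points = model$n_points,
                    provenance = model$provenance),
       predictions = ranked)
}

#' Full selectivity report over competing pathways
#'
#' Ranks profiles by the kinetics-plus-thermodynamics rule; when Nu/E
#' pairs are supplied, predicted barriers are shown beside the
#' profile-derived effective barriers with a rank-agreement flag.  Pair
#' labels are matched to pathway ids.
#'
#' @param config a [run_config()].
#' @param profiles named list of [pathway_profile()] (or a profile CSV
#'   path).
#' @param pairs_tbl optional data frame/CSV path with `label`,
#'   `omega_E_eV`, `N_Nu_eV`, labels matching pathway ids.
#' @param model an [lfer_model()] for predictions (default published).
#' @return a list of class `selectivity_report`: `config`, `ranking`
#'   table, `winner`, `winner_product`, `regime`, `orders_agree`, and
#'   (with pairs) `predicted_vs_computed` plus `prediction_rank_agrees`.
#' @export
run_rank <- function(config = run_config(), profiles, pairs_tbl = NULL,
                     model = published_model()) {
  if (is.character(profiles)) profiles <- read_profile_csv(profiles)
  if (is.data.frame(profiles)) profiles <- profiles_from_table(profiles)
  sel <- select_main_product(profiles,
                             threshold = config$irreversibility_threshold)
  report <- list(config = .config_echo(config),
                 ranking = sel$table,
                 winner = sel$winner,
                 winner_product = sel$winner_product,
                 regime = sel$regime,
                 orders_agree = sel$orders_agree)
  if (!is.null(pairs_tbl)) {
    pred <- run_predict(config, pairs_tbl, model)$predictions
    merged <- merge(sel$table[, c("pathway_id", "dg_total")],
                    pred[, c("label", "sum_index", "dg_predicted")],
                    by.x = "pathway_id", by.y = "label", all.x = TRUE)
    both <- !is.na(merged$dg_predicted)
    report$predicted_vs_computed <- merged
    report$prediction_rank_agrees <-
      sum(both) >= 2L &&
      identical(order(merged$dg_predicted[both]),
                order(merged$dg_total[both]))
  }
  class(report) <- "selectivity_report"
  report
}

#' @export
print.selectivity_report <- function(x, ...) {
  cat(sprintf("<selectivity_report> %s control; winner: %s -> %s\n",
              x$regime, x$winner, x$winner_product))
  print(x$ranking)
  if (!is.null(x$predicted_vs_computed)) {
    cat(sprintf("predicted vs computed barriers (%s):\n",
                if (isTRUE(x$prediction_rank_agrees)) "ranks agree"
                else "ranks differ or not comparable"))
    print(x$predicted_vs_computed)
  }
  invisible(x)
}
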