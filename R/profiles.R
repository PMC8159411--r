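#' @title Multi-step free-energy profiles and pathway ranking
#' @name profiles
#' @description
#' A mechanistic pathway is an alternating ladder of minima and transition
#' states with Gibbs energies relative to a common entry point (0).  The
#' kinetically relevant quantity of a multi-step pathway is not any
#' single-step barrier but the effective (energetic-span style) barrier:
#' the largest climb from a preceding resting minimum to a later
#' transition state.  Competing pathways are then ranked by the
#' kinetics-plus-thermodynamics rule: among irreversible pathways (product
#' well below the entry), the lowest effective barrier wins; if none is
#' irreversible, product stability decides (thermodynamic control).
NULL

#' Construct a pathway free-energy profile
#'
#' @param pathway_id text label, e.g. `"[3+3] annulation"`.
#' @param point_name character vector of stationary-point names.
#' @param kind character vector, each `"min"` or `"ts"`; the profile must
#'   start and end with a minimum and strictly alternate.
#' @param g_rel Gibbs energies in kcal/mol relative to the entry point;
#'   the first minimum must be 0.
#' @param product_name optional name of the product (defaults to the last
#'   minimum).
#' @return a `pathway_profile` object; `product_g` is the final minimum's
#'   energy.
#' @examples
#' pathway_profile("[3+3]", c("R", "TS", "P"), c("min", "ts", "min"),
#'                 c(0, 10, -5))
#' @export
pathway_profile <- function(pathway_id, point_name, kind, g_rel,
                            product_name = NULL) {
  kind <- match.arg(kind, c("min", "ts"), several.ok = TRUE)
  n <- length(point_name)
  stopifnot(n >= 1L, length(kind) == n, length(g_rel) == n,
            is.numeric(g_rel), all(is.finite(g_rel)))
  if (kind[1] != "min" || kind[n] != "min") {
    stop("profile '", pathway_id, "' must start and end with a minimum",
         call. = FALSE)
  }
  if (n > 1L && any(kind[-1] == kind[-n])) {
    stop("profile '", pathway_id,
         "' must alternate minima and transition states", call. = FALSE)
  }
  if (abs(g_rel[1]) > 1e-9) {
    stop("profile '", pathway_id, "' entry minimum must sit at 0 kcal/mol ",
         "(got ", g_rel[1], ")", call. = FALSE)
  }
  if (is.null(product_name)) product_name <- point_name[n]
  structure(list(pathway_id = as.character(pathway_id),
                 point_name = as.character(point_name),
                 kind = kind, g_rel = as.numeric(g_rel),
                 product_name = as.character(product_name),
                 product_g = g_rel[n]),
            class = "pathway_profile")
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat(sprintf("<pathway_profile> %s -> %s (%.1f kcal/mol)\n",
              x$pathway_id, x$product_name, x$product_g))
  print(data.frame(point = x$point_name, kind = x$kind,
                   g_rel = x$g_rel))
  invisible(x)
}

#' Effective (span-style) barrier of a pathway
#'
#' dG_total = max over transition states TS of
#' `g(TS) - min(g of minima at or before TS)`, the worst climb out of any
#' upstream resting state.  For a profile with no transition state the
#' barrier is 0 and flagged.
#'
#' @param profile a [pathway_profile()].
#' @return list with `pathway_id`, `dg_total` (kcal/mol), `limiting_ts`,
#'   `limiting_ref_minimum` (names of the maximizing pair), `barrierless`
#'   flag, `product_name`, `product_g`.
#' @export
effective_barrier <- function(profile) {
  if (!inherits(profile, "pathway_profile")) {
    stop("expected a pathway_profile", call. = FALSE)
  }
  ts_idx <- which(profile$kind == "ts")
  if (length(ts_idx) == 0L) {
    return(list(pathway_id = profile$pathway_id, dg_total = 0,
                limiting_ts = NA_character_,
                limiting_ref_minimum = profile$point_name[1],
                barrierless = TRUE,
                product_name = profile$product_name,
                product_g = profile$product_g))
  }
  best <- -Inf; best_ts <- NA_integer_; best_min <- NA_integer_
  for (i in ts_idx) {
    prior_min <- which(profile$kind == "min" & seq_along(profile$kind) < i)
    j <- prior_min[which.min(profile$g_rel[prior_min])]
    span <- profile$g_rel[i] - profile$g_rel[j]
    if (span > best) { best <- span; best_ts <- i; best_min <- j }
  }
  list(pathway_id = profile$pathway_id, dg_total = best,
       limiting_ts = profile$point_name[best_ts],
       limiting_ref_minimum = profile$point_name[best_min],
       barrierless = FALSE,
       product_name = profile$product_name,
       product_g = profile$product_g)
}

#' Is a pathway irreversible at the working temperature?
#'
#' A pathway is taken as irreversible when its product lies at least
#' `threshold` kcal/mol below the entry point (boundary inclusive):
#' re-crossing the exothermic drop is then negligible at room
#' temperature.
#'
#' @param profile a [pathway_profile()].
#' @param threshold minimum exothermicity in kcal/mol (default 10).
#' @return logical.
#' @export
classify_reversibility <- function(profile, threshold = 10) {
  if (!inherits(profile, "pathway_profile")) {
    stop("expected a pathway_profile", call. = FALSE)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold), threshold >= 0)
  profile$product_g <= -threshold
}

#' Rank competing pathways and call the main product
#'
#' Implements the kinetics-plus-thermodynamics selection rule.  All
#' profiles must share the entry reference (their first minima must carry
#' the same name); among irreversible pathways the one with the lowest
#' effective barrier is the predicted main product.  If no pathway is
#' irreversible the ranking falls back to product stability
#' (thermodynamic control) and the regime is flagged.
#'
#' @param profiles list of [pathway_profile()] objects.
#' @param threshold irreversibility threshold, kcal/mol (default 10).
#' @return list of class `selectivity_ranking`: `table` (one row per
#'   pathway: `pathway_id`, `dg_total`, `limiting_ts`,
#'   `limiting_ref_minimum`, `product_name`, `product_g`, `irreversible`,
#'   `rank`), `winner`, `winner_product`, `regime` (`"kinetic"` or
#'   `"thermodynamic"`), and `orders_agree` (do the kinetic and
#'   thermodynamic orders coincide?).
#' @export
select_main_product <- function(profiles, threshold = 10) {
  if (inherits(profiles, "pathway_profile")) profiles <- list(profiles)
  if (!is.list(profiles) || length(profiles) == 0L ||
      !all(vapply(profiles, inherits, NA, "pathway_profile"))) {
    stop("profiles must be a non-empty list of pathway_profile objects",
         call. = FALSE)
  }
  entries <- vapply(profiles, function(p) p$point_name[1], "")
  if (length(unique(entries)) > 1L) {
    stop("profiles do not share an entry reference: ",
         paste(unique(entries), collapse = " vs "), call. = FALSE)
  }
  rows <- lapply(profiles, function(p) {
    a <- effective_barrier(p)
    data.frame(pathway_id = a$pathway_id, dg_total = a$dg_total,
               limiting_ts = a$limiting_ts,
               limiting_ref_minimum = a$limiting_ref_minimum,
               product_name = a$product_name, product_g = a$product_g,
               irreversible = classify_reversibility(p, threshold),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  kin_order <- order(tab$dg_total)
  thermo_order <- order(tab$product_g)
  if (any(tab$irreversible)) {
    regime <- "kinetic"
    cand <- which(tab$irreversible)
    winner <- cand[which.min(tab$dg_total[cand])]
    ord <- order(!tab$irreversible, tab$dg_total)
  } else {
    regime <- "thermodynamic"
    winner <- which.min(tab$product_g)
    ord <- thermo_order
  }
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    winner = tab$pathway_id[1],
    winner_product = tab$product_name[1],
    regime = regime,
    orders_agree = identical(kin_order, thermo_order),
    threshold = threshold
  ), class = "selectivity_ranking")
}

#' @export
print.selectivity_ranking <- function(x, ...) {
  cat(sprintf("<selectivity_ranking> %s control; winner: %s -> %s\n",
              x$regime, x$winner, x$winner_product))
  cat(sprintf("  kinetic and thermodynamic orders %s\n",
              if (x$orders_agree) "agree" else "differ"))
  print(x$table)
  invisible(x)
}
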