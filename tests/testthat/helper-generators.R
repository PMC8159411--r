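# Shared generators and independent oracles for property-style tests.

# random valid frontier-orbital pair (HOMO below LUMO by construction)
random_orbital_pair <- function(id = "x") {
  e_h <- stats::runif(1, -15, -5)
  gap <- stats::runif(1, 0.5, 10)
  orbital_pair(id, e_h, e_h + gap, unit = "eV")
}

# random alternating free-energy profile: entry minimum at 0, n_steps
# TS/minimum pairs with energies drawn wide enough to exercise upstream
# resting states
random_profile <- function(id = "p", max_steps = 7) {
  n_steps <- sample.int(max_steps, 1)
  g <- 0
  for (s in seq_len(n_steps)) {
    last_min <- g[length(g)]
    g <- c(g, last_min + stats::runif(1, 0.1, 15),  # ts above its minimum
           last_min + stats::runif(1, -12, 8))      # next minimum
  }
  n <- length(g)
  kind <- rep(c("min", "ts"), length.out = n)
  pathway_profile(id, paste0(ifelse(kind == "ts", "TS", "M"), seq_len(n)),
                  kind, g)
}

# exhaustive-enumeration oracle for the effective barrier: maximum of
# g(TS) - g(minimum) over every (TS, earlier minimum) pair
oracle_effective_barrier <- function(profile) {
  g <- profile$g_rel
  kind <- profile$kind
  best <- 0
  found <- FALSE
  for (i in seq_along(g)) {
    if (kind[i] != "ts") next
    for (j in seq_len(i - 1)) {
      if (kind[j] != "min") next
      best <- if (!found) g[i] - g[j] else max(best, g[i] - g[j])
      found <- TRUE
    }
  }
  best
}

# closed-form ordinary-least-squares oracle (normal equations)
oracle_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  se_slope <- sqrt(sum(resid^2) / (length(x) - 2) / sum((x - xb)^2))
  list(intercept = intercept, slope = slope, se_slope = se_slope)
}
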