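test_that("the published predictor has the calibrated coefficients", {
  m <- published_model()
  expect_equal(m$intercept, 51.8)
  expect_equal(m$slope, 5.9)
  expect_equal(m$n_points, 3L)
  expect_equal(m$provenance, "published")
  expect_equal(predict_barrier(m, 0)$dg_predicted, 51.8)
  expect_equal(predict_barrier(m, 51.8 / 5.9)$dg_predicted, 0,
               tolerance = 1e-12)
})

test_that("predicted barriers reproduce the printed reference values", {
  m <- published_model()
  expected <- c(`7.27` = 8.9, `7.65` = 6.7, `6.92` = 11.0,
                `6.28` = 14.7, `5.42` = 19.8)
  for (s in names(expected)) {
    expect_equal(
      predict_barrier(m, as.numeric(s), paper_rounding = TRUE)$dg_predicted,
      unname(expected[s]))
  }
  # flat model echoes its intercept
  flat <- lfer_model(12.3, 0)
  expect_equal(predict_barrier(flat, 99)$dg_predicted, 12.3)
  # extrapolation outside the calibration window is flagged
  expect_true(predict_barrier(m, 9.5)$extrapolated)
  expect_false(predict_barrier(m, 6.5)$extrapolated)
})

test_that("reactivity_pair carries a consistent index sum", {
  pr <- reactivity_pair("R2- -> M2", omega_E = 1.548, N_Nu = 4.459)
  expect_equal(pr$sum_index, 1.548 + 4.459, tolerance = 1e-12)
  expect_equal(predict_barrier(published_model(), pr)$sum_index,
               pr$sum_index)
})

test_that("fit_lfer recovers an exact line and honors exclusions", {
  x <- c(6.0, 6.7, 7.1)
  y <- 51.8 - 5.9 * x
  m <- fit_lfer(x, y)
  expect_equal(m$intercept, 51.8, tolerance = 1e-9)
  expect_equal(m$slope, 5.9, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  # refitting through the predictor reproduces the inputs
  for (i in seq_along(x)) {
    expect_equal(predict_barrier(m, x[i])$dg_predicted, y[i],
                 tolerance = 1e-9)
  }
  # an excluded strained point does not perturb the line
  m2 <- fit_lfer(c(x, 6.3), c(y, 28.0),
                 excluded = c(FALSE, FALSE, FALSE, TRUE),
                 reason = c("", "", "", "four-membered-ring strain"))
  expect_equal(m2$slope, 5.9, tolerance = 1e-9)
  expect_equal(m2$n_points, 3L)
  expect_equal(m2$excluded$reason, "four-membered-ring strain")
})

test_that("noisy calibration recovers the slope, matching the closed-form oracle", {
  set.seed(42)
  n <- 50
  x <- stats::runif(n, 5.3, 7.7)
  y <- 51.8 - 5.9 * x + stats::rnorm(n, sd = 0.3)
  m <- fit_lfer(x, y)
  ora <- oracle_ols(x, y)
  expect_equal(m$intercept, ora$intercept, tolerance = 1e-9)
  expect_equal(-m$slope, ora$slope, tolerance = 1e-9)
  expect_equal(m$slope_se, ora$se_slope, tolerance = 1e-9)
  expect_lt(abs(m$slope - 5.9), 3 * m$slope_se)
})

test_that("degenerate calibrations and bad exclusions are rejected", {
  expect_error(fit_lfer(c(6, 6), c(10, 12)), "degenerate")
  expect_error(fit_lfer(6, 10), "at least 2")
  expect_error(fit_lfer(c(6, 7, 8), c(10, 9, 8),
                        excluded = c(TRUE, TRUE, FALSE),
                        reason = c("strain", "strain", "")), "at least 2")
  expect_error(fit_lfer(c(6, 7), c(10, 9), excluded = c(TRUE, FALSE),
                        reason = c("", "")), "reason")
})

test_that("rank_pairs orders by predicted barrier, flags ties, keeps input order on ties", {
  m <- published_model()
  ranked <- rank_pairs(m, c(5.42, 6.28, 6.92, 6.92))
  expect_equal(ranked$sum_index, c(6.92, 6.92, 6.28, 5.42))
  expect_equal(ranked$tie, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ranked$rank, 1:4)
  # descending sum order whenever the slope is positive (sort oracle)
  set.seed(9)
  for (i in 1:10) {
    sums <- stats::runif(sample(2:8, 1), 4, 9)
    r <- rank_pairs(m, sums)
    expect_equal(r$sum_index, sort(sums, decreasing = TRUE))
  }
  expect_equal(nrow(rank_pairs(m, 7.0)), 1)
  expect_error(rank_pairs(m, list()), "non-empty")
})

test_that("prediction is strictly decreasing in the index sum for b > 0", {
  m <- published_model()
  s <- seq(4, 9, by = 0.25)
  dg <- vapply(s, function(x) predict_barrier(m, x)$dg_predicted, 0)
  expect_true(all(diff(dg) < 0))
})
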