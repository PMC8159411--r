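test_that("profile validation enforces the alternation and entry rules", {
  expect_error(pathway_profile("p", c("R", "TS"), c("min", "ts"), c(0, 5)),
               "end with a minimum")
  expect_error(pathway_profile("p", c("TS", "M"), c("ts", "min"), c(5, 0)),
               "start")
  expect_error(pathway_profile("p", c("R", "M", "P"),
                               c("min", "min", "min"), c(0, 1, 2)),
               "alternate")
  expect_error(pathway_profile("p", c("R", "TS", "P"), c("min", "ts", "min"),
                               c(1, 5, -2)), "entry")
})

test_that("effective barrier handles single steps, upstream resting states and truncation", {
  p1 <- pathway_profile("one", c("R", "TS", "P"), c("min", "ts", "min"),
                        c(0, 10, -5))
  a1 <- effective_barrier(p1)
  expect_equal(a1$dg_total, 10)
  expect_equal(a1$limiting_ref_minimum, "R")

  # a deep intermediate raises the second TS's effective climb: 4-(-8)=12
  p2 <- pathway_profile("two", c("R", "TS1", "M1", "TS2", "P"),
                        c("min", "ts", "min", "ts", "min"),
                        c(0, 5, -8, 4, -20))
  a2 <- effective_barrier(p2)
  expect_equal(a2$dg_total, 12)
  expect_equal(a2$limiting_ts, "TS2")
  expect_equal(a2$limiting_ref_minimum, "M1")

  # truncated single-step profile: the catalyst-addition barrier of 16.5
  p3 <- pathway_profile("entry step", c("R", "TS1", "M1"),
                        c("min", "ts", "min"), c(0, 16.5, 10.8))
  expect_equal(effective_barrier(p3)$dg_total, 16.5)

  # no transition state: barrierless flag
  p4 <- pathway_profile("flat", "R", "min", 0)
  a4 <- effective_barrier(p4)
  expect_equal(a4$dg_total, 0)
  expect_true(a4$barrierless)
})

test_that("effective barrier matches exhaustive enumeration on random profiles", {
  set.seed(20)
  for (i in 1:500) {
    p <- random_profile(paste0("p", i))
    expect_lte(length(p$g_rel), 15)
    expect_equal(effective_barrier(p)$dg_total, oracle_effective_barrier(p),
                 tolerance = 1e-12)
    expect_gte(effective_barrier(p)$dg_total, 0)
  }
})

test_that("dg_total is shift-invariant and ignores benign downstream points", {
  set.seed(21)
  for (i in 1:30) {
    p <- random_profile(paste0("p", i), max_steps = 5)
    a <- effective_barrier(p)
    # uniform shifts cancel in all spans (rebuild relative to shifted entry)
    shifted <- p
    shifted$g_rel <- p$g_rel - p$g_rel[1]
    expect_equal(effective_barrier(shifted)$dg_total, a$dg_total)
    # appending a step whose climb from the deepest resting state stays
    # below the limiting span changes nothing
    safe_ts <- min(p$g_rel[p$kind == "min"]) + a$dg_total - 0.5
    ext <- pathway_profile(p$pathway_id,
                           c(p$point_name, "TSx", "Px"),
                           c(p$kind, "ts", "min"),
                           c(p$g_rel, safe_ts, min(p$g_rel) - 1))
    expect_equal(effective_barrier(ext)$dg_total, a$dg_total)
  }
})

test_that("reversibility classification uses an inclusive exothermicity threshold", {
  mk <- function(pg) pathway_profile("p", c("R", "TS", "P"),
                                     c("min", "ts", "min"), c(0, 5, pg))
  expect_true(classify_reversibility(mk(-23.7)))
  expect_false(classify_reversibility(mk(0)))
  expect_true(classify_reversibility(mk(-10)))     # boundary inclusive
  expect_false(classify_reversibility(mk(-9.99)))
  expect_true(classify_reversibility(mk(-5), threshold = 5))
})

test_that("select_main_product applies the kinetics+thermodynamics rule", {
  mk <- function(id, ts, pg, prod = paste0("P_", id))
    pathway_profile(id, c("R", "TS", prod), c("min", "ts", "min"),
                    c(0, ts, pg), product_name = prod)
  # four irreversible pathways: lowest effective barrier wins
  profs <- list(mk("amidation", 31.0, -15), mk("[2+2]", 28.0, -16),
                mk("[3+2]", 24.5, -18), mk("[3+3]", 9.9, -23.7))
  sel <- select_main_product(profs)
  expect_equal(sel$winner, "[3+3]")
  expect_equal(sel$regime, "kinetic")
  expect_equal(sel$table$dg_total, c(9.9, 24.5, 28.0, 31.0))

  # single profile is its own winner
  expect_equal(select_main_product(list(mk("only", 12, -20)))$winner, "only")

  # both irreversible, 6.2 beats 9.1
  two <- select_main_product(list(mk("[3+2]", 9.1, -20), mk("[3+3]", 6.2, -25)))
  expect_equal(two$winner, "[3+3]")

  # no irreversible pathway: thermodynamic control flagged
  th <- select_main_product(list(mk("a", 5, -2), mk("b", 9, -7)))
  expect_equal(th$regime, "thermodynamic")
  expect_equal(th$winner, "b")

  # reversible pathways are ranked after irreversible ones even if faster
  mixed <- select_main_product(list(mk("fast-reversible", 3, -1),
                                    mk("slow-irreversible", 15, -20)))
  expect_equal(mixed$winner, "slow-irreversible")

  # stability: duplicating a losing pathway does not change the winner
  dup <- select_main_product(c(profs, list(mk("amidation2", 31.0, -15))))
  expect_equal(dup$winner, "[3+3]")

  expect_error(select_main_product(list()), "non-empty")
  expect_error(select_main_product(list(
    mk("a", 5, -12),
    pathway_profile("b", c("Other", "TS", "P"), c("min", "ts", "min"),
                    c(0, 5, -12)))), "entry reference")
})
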