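test_that("closed-form Hueckel spectra are reproduced", {
  a <- -11; b <- -2.7
  # ethylene (K2): alpha +/- beta
  r2 <- huckel_solve(chain_system(2, alpha = a, beta = b))
  expect_equal(r2$energies, c(a + b, a - b), tolerance = 1e-9)
  expect_equal(r2$homo_index, 1L)
  # butadiene: alpha +/- 1.618 beta, alpha +/- 0.618 beta (golden ratio)
  phi <- (1 + sqrt(5)) / 2
  r4 <- huckel_solve(chain_system(4, alpha = a, beta = b))
  expect_equal(r4$energies,
               sort(a + b * c(phi, phi - 1, 1 - phi, -phi)),
               tolerance = 1e-9)
  # benzene: alpha+2b, alpha+b (x2), alpha-b (x2), alpha-2b
  r6 <- huckel_solve(cycle_system(6, alpha = a, beta = b))
  expect_equal(r6$energies, a + b * c(2, 1, 1, -1, -1, -2),
               tolerance = 1e-9)
  expect_equal(r6$homo_degeneracy, 2L)
  expect_equal(r6$lumo_degeneracy, 2L)
})

test_that("eigenvectors are orthonormal and frontier orbitals export cleanly", {
  r <- huckel_solve(chain_system(6))
  C <- r$coefficients
  expect_equal(t(C) %*% C, diag(6), tolerance = 1e-9)
  op <- huckel_orbital_pair(r)
  expect_s3_class(op, "orbital_pair")
  expect_lt(op$E_H_eV, op$E_L_eV)
})

test_that("pairing symmetry and trace identity hold for random alternant systems", {
  set.seed(13)
  for (i in 1:100) {
    n <- 2 * sample(2:7, 1)
    s <- random_system(n, alpha = -11, beta = -2.7)
    r <- huckel_solve(s)
    # trace: eigenvalues sum to n * alpha
    expect_equal(sum(r$energies), n * s$alpha, tolerance = 1e-8)
    # pairing theorem: spectrum symmetric about alpha for bipartite skeletons
    dev <- sort(r$energies - s$alpha)
    expect_equal(dev, -rev(dev), tolerance = 1e-8)
    # closed-shell even systems always give a usable orbital pair
    expect_lt(r$energies[r$homo_index], r$energies[r$lumo_index] + 1e-12)
  }
})

test_that("invalid pi systems are rejected", {
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
  expect_error(pi_system("disc", A), "disconnected")
  expect_error(pi_system("posbeta", matrix(c(0, 1, 1, 0), 2), beta = 1),
               "negative")
  expect_error(huckel_solve(chain_system(5)), "odd electron")
  B <- matrix(c(0, 2, 2, 0), 2)
  expect_error(pi_system("weights", B), "0/1")
})

test_that("orbital tables carry Hueckel frontier energies in the CSV dialect", {
  a <- -11; b <- -2.7
  tbl <- generate_orbital_table(list(chain_system(2, "ethylene"),
                                     chain_system(4, "butadiene"),
                                     cycle_system(6, "benzene")))
  expect_equal(names(tbl), c("species", "E_HOMO", "E_LUMO", "unit"))
  expect_equal(tbl$E_HOMO[tbl$species == "ethylene"], a + b)
  expect_equal(tbl$E_LUMO[tbl$species == "ethylene"], a - b)
  # benzene's degenerate frontier levels collapse to single values
  expect_equal(tbl$E_HOMO[tbl$species == "benzene"], a + b, tolerance = 1e-9)
  expect_equal(tbl$E_LUMO[tbl$species == "benzene"], a - b, tolerance = 1e-9)
  # N(ethylene) < N(butadiene): the longer polyene is the better donor
  idx <- global_indices_table(tbl)
  expect_lt(idx$N_eV[idx$species == "ethylene"],
            idx$N_eV[idx$species == "butadiene"])
  # empty input: header-only table
  expect_equal(nrow(generate_orbital_table(list())), 0)
})

test_that("synthetic spin densities are squared SOMO coefficients summing to 1", {
  # ethylene cation: symmetric [0.5, 0.5]
  sc <- generate_spin_table(chain_system(2), "radical_cation")
  expect_equal(sc$spin_density, c(0.5, 0.5), tolerance = 1e-9)
  # butadiene anion: end-heavy sin-coefficient pattern
  sa <- generate_spin_table(chain_system(4), "radical_anion")
  expect_equal(sa$spin_density, c(0.3618034, 0.1381966, 0.1381966, 0.3618034),
               tolerance = 1e-6)
  set.seed(31)
  for (i in 1:20) {
    s <- random_system(2 * sample(2:6, 1))
    for (st in c("radical_cation", "radical_anion")) {
      tbl <- generate_spin_table(s, st)
      expect_equal(sum(tbl$spin_density), 1, tolerance = 1e-12)
      # feeds parr_local cleanly
      pv <- parr_table(tbl)
      expect_equal(sum(pv$parr_value), 1, tolerance = 1e-9)
    }
  }
})
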