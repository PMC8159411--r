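#' @title Hueckel molecular-orbital generator for synthetic inputs
#' @name huckel
#' @description
#' A minimal pi-only Hueckel model supplies realistic frontier-orbital
#' energies and spin populations without any electronic-structure
#' software: H = alpha I + beta A for a conjugated skeleton with adjacency
#' matrix A, a single Coulomb parameter alpha and resonance parameter
#' beta < 0.  Neutral even-atom systems (one pi electron per atom, closed
#' shell) yield a HOMO/LUMO pair; squared coefficients of the singly
#' occupied orbital of a vertical radical ion serve as synthetic spin
#' densities.  Defaults alpha = -11 eV, beta = -2.7 eV put synthetic
#' omega/N indices in the realistic 0-8 eV window.
NULL

#' Construct a conjugated pi system
#'
#' @param name text label.
#' @param adjacency symmetric 0/1 matrix with zero diagonal describing the
#'   conjugated skeleton; must be connected.
#' @param alpha Coulomb parameter in eV (default -11).
#' @param beta resonance parameter in eV, negative (default -2.7).
#' @return a `pi_system` object.
#' @export
pi_system <- function(name, adjacency, alpha = -11, beta = -2.7) {
  A <- as.matrix(adjacency)
  n <- nrow(A)
  stopifnot(n >= 2L, ncol(A) == n, is.numeric(alpha), is.numeric(beta))
  if (beta >= 0) stop("beta must be negative", call. = FALSE)
  if (any(A != t(A))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal",
                              call. = FALSE)
  if (!all(A %in% c(0, 1))) stop("adjacency entries must be 0/1",
                                 call. = FALSE)
  # connectivity via matrix powers of (I + A)
  reach <- diag(n) + A
  m <- reach
  for (i in seq_len(n)) m <- (m %*% reach > 0) * 1
  if (any(m == 0)) stop("pi system '", name, "' is disconnected",
                        call. = FALSE)
  structure(list(name = as.character(name), n_atoms = n, adjacency = A,
                 alpha = alpha, beta = beta),
            class = "pi_system")
}

#' Linear polyene chain of n atoms
#' @param n number of atoms (>= 2).
#' @param name optional label.
#' @inheritParams pi_system
#' @return a `pi_system`.
#' @export
chain_system <- function(n, name = paste0("chain", n), alpha = -11,
                         beta = -2.7) {
  stopifnot(n >= 2L)
  A <- matrix(0, n, n)
  idx <- seq_len(n - 1)
  A[cbind(idx, idx + 1)] <- 1
  A[cbind(idx + 1, idx)] <- 1
  pi_system(name, A, alpha, beta)
}

#' Monocyclic ring of n atoms
#' @inheritParams chain_system
#' @return a `pi_system`.
#' @export
cycle_system <- function(n, name = paste0("cycle", n), alpha = -11,
                         beta = -2.7) {
  stopifnot(n >= 3L)
  s <- chain_system(n, name, alpha, beta)
  s$adjacency[1, n] <- s$adjacency[n, 1] <- 1
  pi_system(name, s$adjacency, alpha, beta)
}

#' Random conjugated skeleton (tree plus optional even-cycle closure)
#'
#' Draws a random labelled tree on `n` atoms (random attachment), and with
#' probability `p_cycle` closes one ring of even length so the skeleton
#' stays alternant (bipartite).  Used for property-style testing; the seed
#' is the caller's responsibility.
#'
#' @param n number of atoms.
#' @param p_cycle probability of closing one even ring (default 0.3).
#' @inheritParams chain_system
#' @return a `pi_system`.
#' @export
random_system <- function(n, name = paste0("rand", n), alpha = -11,
                          beta = -2.7, p_cycle = 0.3) {
  stopifnot(n >= 2L)
  A <- matrix(0, n, n)
  for (i in seq(2, n)) {
    j <- if (i == 2) 1L else sample.int(i - 1L, 1L)
    A[i, j] <- A[j, i] <- 1
  }
  if (n >= 4L && stats::runif(1) < p_cycle) {
    # bipartition by depth parity from atom 1; closing a ring between
    # opposite classes keeps the graph bipartite (even ring)
    depth <- rep(NA_integer_, n); depth[1] <- 0L
    queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] == 1 & is.na(depth))
      depth[nb] <- depth[v] + 1L
      queue <- c(queue, nb)
    }
    odd <- which(depth %% 2L == 1L); even <- which(depth %% 2L == 0L)
    cand <- expand.grid(i = even, j = odd)
    cand <- cand[A[cbind(cand$i, cand$j)] == 0 & cand$i != cand$j, ]
    if (nrow(cand)) {
      k <- cand[sample.int(nrow(cand), 1L), ]
      A[k$i, k$j] <- A[k$j, k$i] <- 1
    }
  }
  pi_system(name, A, alpha, beta)
}

#' Solve the Hueckel eigenproblem
#'
#' Diagonalizes H = alpha I + beta A and identifies the HOMO/LUMO of the
#' neutral closed-shell system (one pi electron per atom; even atom count
#' required).
#'
#' @param system a [pi_system()].
#' @return a `huckel_result`: `energies` (ascending, eV), `coefficients`
#'   (orthonormal eigenvectors in columns, matching `energies`),
#'   `homo_index`, `lumo_index`, `homo_degeneracy`, `lumo_degeneracy`,
#'   and the input `system`.
#' @examples
#' huckel_solve(chain_system(2))$energies  # alpha + beta, alpha - beta
#' @export
huckel_solve <- function(system) {
  if (!inherits(system, "pi_system")) stop("expected a pi_system",
                                           call. = FALSE)
  n <- system$n_atoms
  if (n %% 2L != 0L) {
    stop("odd electron count: the neutral closed-shell model needs an even ",
         "number of atoms (got ", n, ")", call. = FALSE)
  }
  H <- system$alpha * diag(n) + system$beta * system$adjacency
  eig <- eigen(H, symmetric = TRUE)
  energies <- rev(eig$values)               # ascending
  coeff <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  homo <- n %/% 2L
  lumo <- homo + 1L
  tol <- 1e-9 * max(1, abs(system$beta))
  structure(list(
    energies = energies, coefficients = coeff,
    homo_index = homo, lumo_index = lumo,
    homo_degeneracy = sum(abs(energies - energies[homo]) < tol),
    lumo_degeneracy = sum(abs(energies - energies[lumo]) < tol),
    system = system
  ), class = "huckel_result")
}

#' Frontier-orbital pair of a Hueckel solution
#'
#' Degenerate frontier levels collapse to their unique energy value.
#'
#' @param result a `huckel_result`.
#' @return an [orbital_pair()] in eV.
#' @export
huckel_orbital_pair <- function(result) {
  stopifnot(inherits(result, "huckel_result"))
  orbital_pair(result$system$name,
               result$energies[result$homo_index],
               result$energies[result$lumo_index], unit = "eV")
}

#' Orbital-energy table for a set of pi systems
#'
#' Emits the orbital CSV dialect consumed by [global_indices_table()].
#'
#' @param systems list of [pi_system()] objects (may be empty).
#' @return data frame `species`, `E_HOMO`, `E_LUMO`, `unit` (eV).
#' @export
generate_orbital_table <- function(systems) {
  if (inherits(systems, "pi_system")) systems <- list(systems)
  if (length(systems) == 0L) {
    return(data.frame(species = character(), E_HOMO = numeric(),
                      E_LUMO = numeric(), unit = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(systems, function(s) {
    r <- huckel_solve(s)
    data.frame(species = s$name,
               E_HOMO = r$energies[r$homo_index],
               E_LUMO = r$energies[r$lumo_index],
               unit = "eV", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Synthetic spin-population table for a vertical radical ion
#'
#' The spin density of the vertical radical cation (anion) is the squared
#' coefficient vector of the orbital the electron left from (arrived in):
#' the neutral system's HOMO (LUMO).  Sums to 1 exactly by orbital
#' normalization.
#'
#' @param system a [pi_system()] with an even atom count.
#' @param state `"radical_cation"` or `"radical_anion"`.
#' @return data frame in the spin CSV dialect: `species`, `state`,
#'   `atom_index`, `atom_label`, `spin_density`.
#' @export
generate_spin_table <- function(system, state = c("radical_cation",
                                                  "radical_anion")) {
  state <- match.arg(state)
  r <- huckel_solve(system)
  somo <- if (state == "radical_cation") r$homo_index else r$lumo_index
  dens <- r$coefficients[, somo]^2
  dens <- dens / sum(dens)  # exact unit sum despite rounding
  data.frame(species = system$name, state = state,
             atom_index = seq_len(system$n_atoms),
             atom_label = paste0("C", seq_len(system$n_atoms)),
             spin_density = dens, stringsAsFactors = FALSE)
}
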