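# Forward-model surrogate for MD: a self-consistent RISM/HNC structure
# solver, toy-system factory, finite-sampling noise generator, and synthetic
# particle-count ensembles for the IMC estimator.

#' Settings of the structure solver
#'
#' @param mixing Picard mixing factor in (0, 1].
#' @param tol residual tolerance on the maximum RDF change per iteration.
#' @param max_iter maximum Picard iterations.
#' @param seed optional seed recorded for noise generators.
#' @export
solver_settings <- function(mixing = 0.2, tol = 1e-10, max_iter = 20000L,
                            seed = NULL) {
  if (!(mixing > 0 && mixing <= 1)) stop("mixing must be in (0, 1]")
  if (tol <= 0) stop("tolerance must be positive")
  structure(list(mixing = mixing, tol = tol, max_iter = as.integer(max_iter),
                 seed = seed),
            class = "solver_settings")
}

# batched reduced-RISM solve for H given C on interior wave vectors:
# H = (I - Omega C rho)^-1 Omega C Omega, per k.
rism_h_from_c <- function(chat, om, rho) {
  n_t <- dim(chat)[1L]
  nk <- dim(chat)[3L]
  if (n_t == 1L) {
    c1 <- chat[1, 1, ]; o1 <- om[1, 1, ]
    return(array(o1^2 * c1 / (1 - rho[1L] * o1 * c1), dim = dim(chat)))
  }
  if (n_t == 2L) {
    o11 <- om[1, 1, ]; o12 <- om[1, 2, ]; o22 <- om[2, 2, ]
    c11 <- chat[1, 1, ]; c12 <- chat[1, 2, ]; c22 <- chat[2, 2, ]
    e11 <- o11 * c11 + o12 * c12; e12 <- o11 * c12 + o12 * c22
    e21 <- o12 * c11 + o22 * c12; e22 <- o12 * c12 + o22 * c22
    b11 <- e11 * o11 + e12 * o12; b12 <- e11 * o12 + e12 * o22
    b21 <- e21 * o11 + e22 * o12; b22 <- e21 * o12 + e22 * o22
    m11 <- 1 - e11 * rho[1L]; m12 <- -e12 * rho[2L]
    m21 <- -e21 * rho[1L];    m22 <- 1 - e22 * rho[2L]
    det <- m11 * m22 - m12 * m21
    H <- array(0, dim = dim(chat))
    H[1, 1, ] <- (m22 * b11 - m12 * b21) / det
    H[1, 2, ] <- (m22 * b12 - m12 * b22) / det
    H[2, 1, ] <- (-m21 * b11 + m11 * b21) / det
    H[2, 2, ] <- (-m21 * b12 + m11 * b22) / det
    return(H)
  }
  H <- array(0, dim = dim(chat))
  I_t <- diag(n_t)
  for (kk in seq_len(nk)) {
    Om <- matrix(om[, , kk], n_t, n_t)
    Ck <- matrix(chat[, , kk], n_t, n_t)
    E <- Om %*% Ck
    H[, , kk] <- solve(I_t - E %*% diag(rho, n_t), E %*% Om)
  }
  H
}

#' Self-consistent RISM/HNC structure solver (forward model)
#'
#' Computes the RDFs produced by a set of pair potentials by alternating the
#' symmetry-reduced RISM equation with the hypernetted-chain closure,
#' Picard-mixing the indirect correlation `gamma = h - c` until the maximum
#' RDF change per sweep drops below tolerance. Deterministic given inputs;
#' serves as the stand-in for the MD forward map so the whole coarse-graining
#' loop can be exercised end to end.
#'
#' If a Picard sweep produces a non-finite iterate (mixing too aggressive for
#' a steep potential), the solve restarts cold with the mixing factor reduced
#' fourfold, up to two times, before giving up.
#'
#' @param u potential [stacked_field()] (kJ/mol), decayed to zero by `r_cut`.
#' @param comp a [composition()].
#' @param omega `intramolecular_matrix` (default: free single beads).
#' @param settings a [solver_settings()].
#' @param gamma_init optional warm-start matrix of indirect correlations.
#' @return RDF [stacked_field()] with attributes `c` (direct correlation
#'   field), `gamma`, `residual`, `iterations`.
#' @export
solve_structure <- function(u, comp, omega = NULL,
                            settings = solver_settings(),
                            gamma_init = NULL) {
  grid <- u$grid
  if (is.null(omega))
    omega <- build_omega(lapply(u$types, molecule_graph), grid)
  if (!identical(omega$types, u$types))
    stop("bead types of u and omega do not match")
  n <- grid$n_points
  n_i <- length(u$interactions)
  n_t <- length(u$types)
  beta <- 1 / comp$kT
  mayer <- exp(-beta * u$values)               # n x n_i
  fm <- fourier_matrices(grid)
  f <- conversion_factors(omega)
  rho <- rho_molecular(omega, comp)
  om_int <- omega$omega[, , -1L, drop = FALSE]
  # map unordered interaction columns into (a, b) positions of type matrices
  pair_idx <- t(vapply(u$interactions, function(lab)
    match(split_pair(lab), u$types), integer(2)))
  gam <- if (is.null(gamma_init)) matrix(0, n, n_i) else gamma_init
  g_prev <- mayer * exp(gam)
  history <- numeric(0)
  for (it in seq_len(settings$max_iter)) {
    g_r <- mayer * exp(gam)
    c_r <- g_r - 1 - gam                       # HNC closure for c(r)
    c_int <- fm$F %*% c_r[-1L, , drop = FALSE]
    chat <- array(0, c(n_t, n_t, n - 1L))
    for (m in seq_len(n_i)) {
      a <- pair_idx[m, 1L]; b <- pair_idx[m, 2L]
      chat[a, b, ] <- c_int[, m] * f[a, b]
      chat[b, a, ] <- chat[a, b, ]
    }
    Hhat <- rism_h_from_c(chat, om_int, rho)
    gam_hat <- matrix(0, n - 1L, n_i)
    for (m in seq_len(n_i)) {
      a <- pair_idx[m, 1L]; b <- pair_idx[m, 2L]
      gam_hat[, m] <- Hhat[a, b, ] / f[a, b] - c_int[, m]
    }
    gam_new <- matrix(0, n, n_i)
    gam_new[-1L, ] <- fm$Finv %*% gam_hat
    gam_new[1L, ] <- (grid$dk / (2 * pi^2)) *
      as.numeric(crossprod(gam_hat, grid$k[-1L]^2))
    gam <- gam + settings$mixing * (gam_new - gam)
    g_now <- mayer * exp(gam)
    res <- max(abs(g_now - g_prev))
    if (!is.finite(res)) {
      if (settings$mixing > 0.02) {
        slower <- settings
        slower$mixing <- settings$mixing / 4
        slower$max_iter <- settings$max_iter * 3L
        return(solve_structure(u, comp, omega, slower, gamma_init = NULL))
      }
      stop("structure solver diverged (non-finite iterate); the potential ",
           "is likely too attractive for a homogeneous fluid at this state")
    }
    g_prev <- g_now
    history <- c(history, res)
    if (res < settings$tol) {
      g <- stacked_field(grid, u$types, pmax(g_now, 0), kind = "rdf")
      c_sf <- stacked_field(grid, u$types, g_now - 1 - gam,
                            kind = "correlation")
      attr(g, "c") <- c_sf
      attr(g, "gamma") <- gam
      attr(g, "residual") <- res
      attr(g, "iterations") <- it
      return(g)
    }
  }
  stop(sprintf(paste0("structure solver did not converge within %d iterations",
                      " (last residuals: %s)"), settings$max_iter,
               paste(signif(utils::tail(history, 5), 3), collapse = ", ")))
}

#' Tabulated Lennard-Jones potential
#'
#' `4 eps ((sigma/r)^12 - (sigma/r)^6)`, capped at `cap` near \eqn{r = 0};
#' optionally shifted upward to yield zero at the cutoff (and zero beyond).
#'
#' @param sigma,eps LJ parameters (nm, kJ/mol).
#' @param grid a [radial_grid()].
#' @param r_cut cutoff used for shifting (default grid `r_cut`).
#' @param shifted shift to zero at the cutoff.
#' @param cap repulsive cap near r = 0 (kJ/mol).
#' @export
lj_table <- function(sigma, eps, grid, r_cut = grid$r_cut, shifted = FALSE,
                     cap = 1e6) {
  r <- grid$r
  v <- rep(cap, grid$n_points)
  rp <- r[-1L]
  v[-1L] <- pmin(4 * eps * ((sigma / rp)^12 - (sigma / rp)^6), cap)
  if (shifted) {
    i_cut <- as.integer(floor(r_cut / grid$dr + 1e-9)) + 1L
    v <- v - v[i_cut]
    v[seq_along(v) >= i_cut] <- 0
    v[1L] <- cap
  }
  cg_curve(grid, v, kind = "potential")
}

#' Add finite-sampling noise to an RDF
#'
#' Zero-mean Gaussian noise whose per-bin standard deviation follows counting
#' statistics, `sd_i = sqrt(g_i / (4 pi r_i^2 dr rho N n_frames))`, so the
#' noise measure of the result scales as the inverse square root of the
#' number of frames. Negative results are clipped to zero; reproducible by
#' seed.
#'
#' @param g RDF [cg_curve()] or [stacked_field()].
#' @param comp a [composition()] (`rho`, `N` taken as totals).
#' @param n_frames number of frames emulated (> 0).
#' @param seed RNG seed.
#' @export
add_sampling_noise <- function(g, comp, n_frames, seed = NULL) {
  if (n_frames <= 0) stop("n_frames must be positive")
  if (!is.null(seed)) set.seed(seed)
  noise_one <- function(values, grid) {
    r <- grid$r
    sd <- numeric(length(values))
    nz <- r > 0
    sd[nz] <- sqrt(values[nz] /
                     (4 * pi * r[nz]^2 * grid$dr * sum(comp$rho) *
                        sum(comp$counts) * n_frames))
    pmax(values + stats::rnorm(length(values), sd = sd), 0)
  }
  if (inherits(g, "stacked_field")) {
    for (lab in g$interactions)
      g$values[, lab] <- noise_one(g$values[, lab], g$grid)
    return(g)
  }
  cg_curve(g$grid, noise_one(g$values, g$grid), kind = "rdf")
}

#' Synthetic particle-count ensemble
#'
#' Draws pair-count vectors from a multivariate normal with prescribed mean
#' and covariance (a fixture for the IMC covariance estimator). Zero
#' covariance yields constant samples.
#'
#' @param mean mean pair-count vector.
#' @param cov covariance matrix (positive semidefinite).
#' @param n_frames number of samples.
#' @param seed RNG seed.
#' @return matrix, one row per frame.
#' @export
sample_imc_ensemble <- function(mean, cov, n_frames, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(mean)
  cov <- as.matrix(cov)
  e <- eigen(cov, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  A <- e$vectors %*% diag(sqrt(lam), p)
  Z <- matrix(stats::rnorm(n_frames * p), n_frames, p)
  sweep(Z %*% t(A), 2L, mean, `+`)
}

#' Built-in toy systems
#'
#' Named desk-scale fixtures: `single_lj` (one-bead LJ fluid), `ne_ar`
#' (1:1 neon-argon mixture with the literature LJ parameters,
#' sigma_Ne = 0.278 nm, eps_Ne = 0.28869 kJ/mol, sigma_Ar = 0.3401 nm,
#' eps_Ar = 0.978628 kJ/mol, geometric-average cross interaction, T = 100 K),
#' and `trimer` (rigid symmetric A-B-A molecule, multiplicities
#' n_A = 2, n_B = 1, a hexane-like three-bead fluid). Each entry carries
#' `grid`, `comp`, `molecules`, `omega` and the generating potentials `u`.
#'
#' @return named list of fixtures.
#' @export
toy_systems <- function() {
  out <- list()

  grid1 <- radial_grid(1024, 0.0025, r_cut = 1.2)
  comp1 <- composition(c(A = 800), volume = 100, temperature = 120)
  u1 <- stacked_field(grid1, "A", kind = "potential")
  sf_curve(u1, "A", "A") <- lj_table(0.34, 1.0, grid1, shifted = TRUE)
  out$single_lj <- list(grid = grid1, comp = comp1,
                        molecules = list(molecule_graph("A")),
                        omega = build_omega(list(molecule_graph("A")), grid1),
                        u = u1)

  grid2 <- radial_grid(1024, 0.0025, r_cut = 0.9, r_res = 1.4)
  comp2 <- composition(c(Ar = 500, Ne = 500), volume = 100, temperature = 100)
  sig <- c(Ne = 0.278, Ar = 0.3401)
  eps <- c(Ne = 0.28869, Ar = 0.978628)
  u2 <- stacked_field(grid2, c("Ne", "Ar"), kind = "potential")
  for (lab in u2$interactions) {
    ab <- split_pair(lab)
    sf_curve(u2, ab[1], ab[2]) <- lj_table(sqrt(sig[[ab[1]]] * sig[[ab[2]]]),
                                           sqrt(eps[[ab[1]]] * eps[[ab[2]]]),
                                           grid2, shifted = TRUE)
  }
  mols2 <- list(molecule_graph("Ar"), molecule_graph("Ne"))
  out$ne_ar <- list(grid = grid2, comp = comp2, molecules = mols2,
                    omega = build_omega(mols2, grid2), u = u2,
                    sigma = sig, eps = eps)

  grid3 <- radial_grid(1024, 0.0025, r_cut = 1.2, r_res = 1.6)
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- d[2, 3] <- d[3, 2] <- 0.25
  d[1, 3] <- d[3, 1] <- 0.5
  mol3 <- molecule_graph(c("A", "B", "A"), distances = d)
  comp3 <- composition(c(A = 600, B = 300), volume = 100, temperature = 300)
  u3 <- stacked_field(grid3, c("A", "B"), kind = "potential")
  sf_curve(u3, "A", "A") <- lj_table(0.35, 0.8, grid3, shifted = TRUE)
  sf_curve(u3, "A", "B") <- lj_table(0.33, 0.6, grid3, shifted = TRUE)
  sf_curve(u3, "B", "B") <- lj_table(0.31, 0.5, grid3, shifted = TRUE)
  out$trimer <- list(grid = grid3, comp = comp3, molecules = list(mol3),
                     omega = build_omega(list(mol3), grid3), u = u3)
  out
}
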