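# Shared fixtures and independent oracles. Expensive objects are built once
# per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small soft-core single-bead fluid: g > 0 everywhere, no onset handling
# needed, fast to solve. The workhorse for Jacobian oracle tests.
soft_single <- function(n = 64, dr = 0.02, r_cut = min(1.2, (n - 4) * dr),
                        amp = 2.0, s = 0.3) {
  grid <- radial_grid(n, dr, r_cut = r_cut)
  comp <- composition(c(A = 500), volume = 100, temperature = 120)
  u <- stacked_field(grid, "A", kind = "potential")
  u$values[, 1] <- amp * exp(-(grid$r / s)^2)
  u <- cut_and_shift(u, r_cut)
  om <- build_omega(molecule_graph("A"), grid)
  list(grid = grid, comp = comp, u = u, om = om,
       settings = solver_settings(tol = 1e-13))
}

soft_mixture <- function(n = 64, dr = 0.02, r_cut = min(1.2, (n - 4) * dr)) {
  grid <- radial_grid(n, dr, r_cut = r_cut)
  comp <- composition(c(A = 400, B = 600), volume = 100, temperature = 120)
  u <- stacked_field(grid, c("A", "B"), kind = "potential")
  u$values[, "A-A"] <- 1.5 * exp(-(grid$r / 0.30)^2)
  u$values[, "A-B"] <- 2.0 * exp(-(grid$r / 0.35)^2)
  u$values[, "B-B"] <- 1.0 * exp(-(grid$r / 0.25)^2)
  u <- cut_and_shift(u, r_cut)
  om <- build_omega(lapply(c("A", "B"), molecule_graph), grid)
  list(grid = grid, comp = comp, u = u, om = om,
       settings = solver_settings(tol = 1e-13))
}

# Ne-Ar surrogate target (the closed-loop study conditions): noise-free
# surrogate RDFs, onset window down to 1e-4.
ne_ar_target <- function() {
  fixture("ne_ar_target", function() {
    sys <- toy_systems()$ne_ar
    win <- onset_fit_window(1e-4, 0.1)
    g_raw <- solve_structure(sys$u, sys$comp, sys$omega,
                             solver_settings(tol = 1e-12))
    list(sys = sys, win = win, g_raw = g_raw,
         g_tgt = extrapolate_onset(g_raw, win),
         p_tgt = virial_pressure(g_raw, sys$u, sys$comp))
  })
}

trimer_structure <- function() {
  fixture("trimer_structure", function() {
    tr <- toy_systems()$trimer
    g <- solve_structure(tr$u, tr$comp, tr$omega,
                         solver_settings(tol = 1e-12, mixing = 0.15))
    c(tr, list(g = g))
  })
}

# Oracle: full site-site RISM for the rigid A-B-A trimer (sites A, B, A with
# explicit 3x3 matrices per wave vector), solving c' from h' and
# site-averaging. Skips k = 0 (singular intramolecular matrix), which the
# inverse transform ignores.
full_rism_trimer_c <- function(h_sf, mol, rho_mol, grid) {
  stopifnot(identical(mol$sites, c("A", "B", "A")))
  b1 <- mol$distances[1, 2]
  b2 <- mol$distances[1, 3]
  sinc <- function(k, b) ifelse(k * b == 0, 1, sin(k * b) / (k * b))
  ftv <- function(v) cgiter:::ft_values(v, grid)
  hAA <- ftv(h_sf$values[, "A-A"])
  hAB <- ftv(h_sf$values[, "A-B"])
  hBB <- ftv(h_sf$values[, "B-B"])
  n <- grid$n_points
  cfull <- matrix(0, n, 3)
  for (kk in 2:n) {
    k <- grid$k[kk]
    om <- diag(3)
    om[1, 2] <- om[2, 1] <- om[2, 3] <- om[3, 2] <- sinc(k, b1)
    om[1, 3] <- om[3, 1] <- sinc(k, b2)
    H <- matrix(c(hAA[kk], hAB[kk], hAA[kk],
                  hAB[kk], hBB[kk], hAB[kk],
                  hAA[kk], hAB[kk], hAA[kk]), 3, 3)
    C <- solve(om, H) %*% solve(om + rho_mol * H)
    cfull[kk, ] <- c(C[1, 1], C[1, 2], C[2, 2])
  }
  out <- stacked_field(grid, c("A", "B"), kind = "correlation")
  out$values[, "A-A"] <- cgiter:::ift_values(cfull[, 1], grid)
  out$values[, "A-B"] <- cgiter:::ift_values(cfull[, 2], grid)
  out$values[, "B-B"] <- cgiter:::ift_values(cfull[, 3], grid)
  out
}

# Oracle: forward-map Jacobian dg/du by central finite differences of the
# structure solver.
fd_forward_jacobian <- function(sys, n_out, eps = 1e-4) {
  n_i <- length(sys$u$interactions)
  J <- matrix(0, n_i * n_out, n_i * n_out)
  for (m in seq_len(n_i)) for (j in seq_len(n_out)) {
    up <- sys$u; up$values[1L + j, m] <- up$values[1L + j, m] + eps
    um <- sys$u; um$values[1L + j, m] <- um$values[1L + j, m] - eps
    gp <- solve_structure(up, sys$comp, sys$om, sys$settings)
    gm <- solve_structure(um, sys$comp, sys$om, sys$settings)
    J[, (m - 1L) * n_out + j] <-
      as.numeric(gp$values[1L + seq_len(n_out), ] -
                   gm$values[1L + seq_len(n_out), ]) / (2 * eps)
  }
  J
}

# Oracle: equality-constrained weighted least squares via Lagrange
# multipliers (KKT system solved densely).
lagrange_constrained_lsq <- function(J, W, res, K, d) {
  A <- W * J
  b <- W * res
  m <- nrow(K)
  KKT <- rbind(cbind(2 * crossprod(A), t(K)),
               cbind(K, matrix(0, m, m)))
  rhs <- c(2 * crossprod(A, b), d)
  sol <- solve(KKT, rhs)
  sol[seq_len(ncol(J))]
}

hnc_dudg_matrix <- function(sys, g_tgt, g_k, n_out) {
  h <- stacked_field(sys$grid, g_k$types, g_k$values - 1)
  red <- reduce_correlations(h, sys$om, sys$comp)
  D <- suppressWarnings(dcdh_real(dcdh_k(red, sys$om, sys$comp),
                                  n_out = n_out))
  jacobian_hnc(g_tgt, g_k, D, sys$comp$kT)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
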