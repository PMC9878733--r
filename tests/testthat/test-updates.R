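test_that("Newton step is the Jacobian-inverse image of the residual", {
  set.seed(1)
  n <- 12
  J <- matrix(rnorm(n * n), n, n) + 5 * diag(n)   # forward map dg/du
  J_inv <- solve(J)
  expect_equal(newton_step(J_inv, rep(0, n)), rep(0, n))
  # on a linear forward model one step reaches the target exactly
  u0 <- rnorm(n); g0 <- rnorm(n); g_tgt <- rnorm(n)
  du <- newton_step(J_inv, g_tgt - g0)
  g1 <- g0 + as.numeric(J %*% du)
  expect_equal(g1, g_tgt, tolerance = 1e-10)
  expect_error(newton_step(J_inv, rep(0, n - 1)), "length")
  expect_error(newton_step(J[, -1], rep(0, n)), "square")
})

test_that("Gauss-Newton with unit weights and a square system reduces to
          Newton, and constraints are always feasible", {
  set.seed(2)
  n <- 10
  J <- matrix(rnorm(n * n), n, n) + 4 * diag(n)
  attr(J, "interactions") <- "A-A"
  res <- rnorm(n)
  du_newton <- newton_step(solve(J), res)
  du_gn <- gauss_newton_step(J, NULL, res, rcond = 1e-12)
  expect_equal(du_gn, du_newton, tolerance = 1e-10)
  # any constraint set is satisfied to high accuracy after the solve
  K <- rbind(rnorm(n), c(rep(1, n)))
  cons <- list(constraint_row(K[1, ], 0.3, "pressure"),
               constraint_row(K[2, ], -0.1, "pe"))
  du_c <- gauss_newton_step(J, NULL, res, constraints = cons, rcond = 1e-12)
  expect_lt(max(abs(K %*% du_c - c(0.3, -0.1))), 1e-10)
  # scaling multiplies the final update
  expect_equal(gauss_newton_step(J, NULL, res, scale = 0.67, rcond = 1e-12),
               0.67 * du_gn, tolerance = 1e-12)
  dup <- list(constraint_row(K[1, ], 0.3, "c1"),
              constraint_row(2 * K[1, ], 0.6, "c2"))
  expect_error(gauss_newton_step(J, NULL, res, constraints = dup),
               "rank-deficient")
})

test_that("constrained Gauss-Newton matches a Lagrange-multiplier brute
          force solve on a 6-point problem", {
  set.seed(3)
  n <- 6
  J <- matrix(rnorm(2 * n * n), 2 * n, n)
  attr(J, "interactions") <- "A-A"
  W <- runif(2 * n, 0.5, 2)
  res <- rnorm(2 * n)
  K <- rbind(rnorm(n), rnorm(n))
  d <- c(0.2, -0.5)
  cons <- list(constraint_row(K[1, ], d[1], "pressure"),
               constraint_row(K[2, ], d[2], "kbi:A-A"))
  du <- gauss_newton_step(J, W, res, constraints = cons, rcond = 1e-12)
  du_oracle <- lagrange_constrained_lsq(J, W, res, K, d)
  expect_lt(max(abs(du - du_oracle)), 1e-8)
})

test_that("selective reduction freezes potentials and ignores targets
          like pinning variables in the full system", {
  set.seed(4)
  labs <- c("A-A", "A-B", "B-B")
  n <- 5
  J <- matrix(rnorm(9 * n * n), 3 * n, 3 * n) + 2 * diag(3 * n)
  attr(J, "interactions") <- labs
  res <- rnorm(3 * n)
  sel_full <- selection(labs)
  red_full <- selective_reduce(J, res, sel_full)
  expect_identical(red_full$J[, ], J[, ])
  # only the cross interaction active, only its RDF targeted
  sel <- selection("A-B")
  red <- selective_reduce(J, res, sel)
  expect_equal(dim(red$J), c(n, n))
  expect_equal(red$residual, res[(n + 1):(2 * n)])
  du <- gauss_newton_step(J, NULL, res, selection = sel, rcond = 1e-12)
  expect_true(all(du[c(1:n, (2 * n + 1):(3 * n))] == 0))
  # oracle: solve the reduced square system directly (frozen variables at 0)
  du_pin <- solve(J[(n + 1):(2 * n), (n + 1):(2 * n)],
                  res[(n + 1):(2 * n)])
  expect_equal(du[(n + 1):(2 * n)], as.numeric(du_pin), tolerance = 1e-8)
  expect_error(selection(character(0)), "at least one")
})

test_that("virial pressure reduces to the ideal gas law for zero potential
          and matches a hand-evaluated single-bin virial", {
  grid <- radial_grid(64, 0.02, r_cut = 1.0)
  comp <- composition(c(A = 500), volume = 100, temperature = 120)
  ones <- stacked_field(grid, "A", 1, kind = "rdf")
  u0 <- stacked_field(grid, "A", kind = "potential")
  p_id <- virial_pressure(ones, u0, comp)
  expect_equal(p_id, 5 * comp$kT * 16.6053906, tolerance = 1e-6)
  # single nonzero force bin evaluated by hand
  u1 <- u0
  j <- 20L
  u1$values[1 + j, 1] <- 0.5   # force at midpoints j and j+1
  p1 <- virial_pressure(ones, u1, comp)
  rmid <- grid_midpoints(grid, grid$n_cut)
  hand <- (2 * pi / 3) * 25 *
    (rmid[j]^3 * (-0.5 / grid$dr) + rmid[j + 1]^3 * (0.5 / grid$dr)) *
    grid$dr * 16.6053906
  expect_equal(p1 - p_id, hand, tolerance = 1e-6)
})

test_that("splitting one species into two identical halves leaves the
          pressure invariant", {
  sys <- soft_single()
  g0 <- solve_structure(sys$u, sys$comp, sys$om, sys$settings)
  p_one <- virial_pressure(g0, sys$u, sys$comp)
  comp2 <- composition(c(A = 250, B = 250), 100, 120)
  grid <- sys$grid
  u2 <- stacked_field(grid, c("A", "B"), kind = "potential")
  g2 <- stacked_field(grid, c("A", "B"), 1, kind = "rdf")
  for (lab in u2$interactions) {
    u2$values[, lab] <- sys$u$values[, 1]
    g2$values[, lab] <- g0$values[, 1]
  }
  expect_equal(virial_pressure(g2, u2, comp2), p_one, tolerance = 1e-12)
})

test_that("Kirkwood-Buff integrals integrate the total correlation", {
  grid <- radial_grid(200, 0.01, r_cut = 1.5)
  ones <- stacked_field(grid, "A", 1, kind = "rdf")
  expect_equal(unname(kirkwood_buff(ones)), 0)
  # excluded-core step function: G ~ -(4 pi / 3) a^3 + O(dr^2)
  a <- 0.5
  gv <- as.numeric(grid$r >= a)
  step <- stacked_field(grid, "A", matrix(gv, ncol = 1), kind = "rdf")
  G <- unname(kirkwood_buff(step))
  direct <- sum(4 * pi * grid$r[2:(grid$n_res + 1)]^2 *
                  (gv[2:(grid$n_res + 1)] - 1)) * grid$dr
  expect_equal(G, direct)
  expect_lt(abs(G + 4 * pi * a^3 / 3), 0.05)
  # halving dr improves the discrete integral roughly quadratically
  grid2 <- radial_grid(400, 0.005, r_cut = 1.5)
  gv2 <- as.numeric(grid2$r >= a)
  G2 <- unname(kirkwood_buff(
    stacked_field(grid2, "A", matrix(gv2, ncol = 1), kind = "rdf")))
  expect_lt(abs(G2 + 4 * pi * a^3 / 3), abs(G + 4 * pi * a^3 / 3))
})

test_that("intermolecular potential energy is a hand-checkable discrete
          integral and intensive under system doubling", {
  grid <- radial_grid(32, 0.04, r_cut = 1.0)
  comp <- composition(c(A = 200), 50, 120)
  ones <- stacked_field(grid, "A", 1, kind = "rdf")
  u0 <- stacked_field(grid, "A", kind = "potential")
  expect_equal(intermolecular_pe(ones, u0, comp), 0)
  u1 <- u0; j <- 7L
  u1$values[1 + j, 1] <- -1.3
  pe <- intermolecular_pe(ones, u1, comp)
  hand <- (200 * 200 / 50) * 4 * pi * grid$r[1 + j]^2 * (-1.3) * grid$dr /
    (2 * 200)
  expect_equal(pe, hand, tolerance = 1e-12)
  comp_big <- composition(c(A = 400), 100, 120)
  expect_equal(intermolecular_pe(ones, u1, comp_big), pe, tolerance = 1e-12)
})

test_that("pressure constraint coefficients equal finite differences of the
          virial pressure and scale with composition", {
  sys <- soft_mixture(n = 48)
  g0 <- solve_structure(sys$u, sys$comp, sys$om, sys$settings)
  con <- pressure_constraint(g0, sys$u, sys$comp,
                             p_tgt = virial_pressure(g0, sys$u, sys$comp))
  expect_equal(con$rhs, 0)
  n <- sys$grid$n_cut
  eps <- 1e-5
  for (probe in list(c(1, 5L), c(2, 17L), c(3, 30L))) {
    m <- probe[1]; j <- probe[2]
    up <- sys$u; up$values[1 + j, m] <- up$values[1 + j, m] + eps
    um <- sys$u; um$values[1 + j, m] <- um$values[1 + j, m] - eps
    fd <- (virial_pressure(g0, up, sys$comp) -
             virial_pressure(g0, um, sys$comp)) / (2 * eps)
    coef <- -con$coefficients[(m - 1) * n + j]   # K = -dp/du
    expect_equal(coef, fd, tolerance = 1e-6)
  }
  # coefficients carry the (2 - delta) rho_a rho_b prefactor
  comp2 <- composition(c(A = 800, B = 600), 100, 120)  # double N_A
  con2 <- pressure_constraint(g0, sys$u, comp2, p_tgt = 0)
  i_aa <- seq_len(n)
  expect_equal(con2$coefficients[i_aa], 4 * con$coefficients[i_aa],
               tolerance = 1e-12)
  i_ab <- n + seq_len(n)
  expect_equal(con2$coefficients[i_ab], 2 * con$coefficients[i_ab],
               tolerance = 1e-12)
})

test_that("KBI constraint rows chain the integral weights through the step
          Jacobian and are exact on a linear forward model", {
  set.seed(6)
  grid <- radial_grid(20, 0.05, r_cut = 0.9)
  n <- grid$n_res
  gv <- 1 + 0.2 * sin(grid$r * 5)
  g_k <- stacked_field(grid, "A", matrix(gv, ncol = 1), kind = "rdf")
  g_tgt <- stacked_field(grid, "A", matrix(gv + 0.05 * cos(grid$r * 3),
                                           ncol = 1), kind = "rdf")
  J <- matrix(rnorm(n * n), n, n) + 3 * diag(n)
  attr(J, "interactions") <- "A-A"
  rows <- kbi_constraint(g_k, g_tgt, J)
  expect_length(rows, 1)
  expect_equal(rows[[1]]$rhs,
               unname(kirkwood_buff(g_k) - kirkwood_buff(g_tgt)))
  expect_error(kbi_constraint(g_k, g_tgt, J, interactions = "A-B"),
               "not in system")
  # linear forward model: one constrained step reproduces the target KBI
  du <- gauss_newton_step(J[, seq_len(grid$n_cut)], NULL,
                          as.numeric(g_tgt$values[2:(n + 1), 1] -
                                       g_k$values[2:(n + 1), 1]),
                          constraints = rows, rcond = 1e-12)
  # predicted new RDF from the linear model
  g_new <- g_k
  g_new$values[2:(n + 1), 1] <- g_k$values[2:(n + 1), 1] +
    as.numeric(J[, seq_len(grid$n_cut)] %*% du)
  expect_equal(unname(kirkwood_buff(g_new)), unname(kirkwood_buff(g_tgt)),
               tolerance = 1e-8)
  # the all-interactions mode emits one row per interaction
  gm <- stacked_field(grid, c("A", "B"), 1, kind = "rdf")
  Jm <- diag(3 * n); attr(Jm, "interactions") <- gm$interactions
  expect_length(kbi_constraint(gm, gm, Jm), 3)
})

test_that("potential-energy constraint coefficients match finite differences
          and the row vanishes at the target", {
  sys <- soft_single(n = 48)
  g0 <- solve_structure(sys$u, sys$comp, sys$om, sys$settings)
  pe0 <- intermolecular_pe(g0, sys$u, sys$comp)
  con <- pe_constraint(g0, sys$u, sys$comp, pe_tgt = pe0)
  expect_equal(con$rhs, 0)
  n <- sys$grid$n_cut
  eps <- 1e-5
  for (j in c(3L, 25L)) {
    up <- sys$u; up$values[1 + j, 1] <- up$values[1 + j, 1] + eps
    um <- sys$u; um$values[1 + j, 1] <- um$values[1 + j, 1] - eps
    fd <- (intermolecular_pe(g0, up, sys$comp) -
             intermolecular_pe(g0, um, sys$comp)) / (2 * eps)
    expect_equal(-con$coefficients[j], fd, tolerance = 1e-6)
  }
})
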