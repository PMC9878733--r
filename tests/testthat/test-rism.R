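test_that("single-bead molecules give the identity intramolecular matrix", {
  g <- radial_grid(32, 0.05)
  om <- build_omega(molecule_graph("A"), g)
  expect_equal(om$omega[1, 1, ], rep(1, 32))
  om2 <- build_omega(lapply(c("A", "B"), molecule_graph), g)
  for (kk in c(1, 16, 32))
    expect_equal(om2$omega[, , kk], diag(2), ignore_attr = TRUE)
})

test_that("rigid pairs contribute sin(kb)/(kb) with multiplicity factors", {
  g <- radial_grid(64, 0.02)
  b <- 0.31
  d <- matrix(c(0, b, b, 0), 2, 2)
  om <- build_omega(molecule_graph(c("A", "B"), distances = d), g)
  expect_equal(om$omega["A", "B", 1], 1)  # k -> 0 limit of sinc
  kk <- 20
  expect_equal(om$omega["A", "B", kk],
               sin(g$k[kk] * b) / (g$k[kk] * b))
  expect_error(build_omega(molecule_graph(c("A", "B")), g), "missing")
})

test_that("reduced trimer matrix agrees with the explicit orthonormal
          site-space transformation", {
  g <- radial_grid(64, 0.02)
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- d[2, 3] <- d[3, 2] <- 0.25
  d[1, 3] <- d[3, 1] <- 0.5
  om <- build_omega(molecule_graph(c("A", "B", "A"), distances = d), g)
  # explicit block transformation: sites ordered (A, A, B); the first column
  # of each block is n_a^{-1/2}, completed to an orthonormal basis
  Tm <- rbind(c(1 / sqrt(2), 1 / sqrt(2), 0),
              c(1 / sqrt(2), -1 / sqrt(2), 0),
              c(0, 0, 1))
  sinc <- function(k, b) ifelse(k * b == 0, 1, sin(k * b) / (k * b))
  for (kk in c(2, 17, 49)) {
    k <- g$k[kk]
    w_site <- matrix(c(1, sinc(k, 0.5), sinc(k, 0.25),
                       sinc(k, 0.5), 1, sinc(k, 0.25),
                       sinc(k, 0.25), sinc(k, 0.25), 1), 3, 3)
    red <- t(Tm) %*% w_site %*% Tm   # symmetric components at (1,1), (1,3)
    expect_lt(abs(om$omega["A", "A", kk] - red[1, 1]), 1e-10)
    expect_lt(abs(om$omega["A", "B", kk] - red[1, 3]), 1e-10)
    expect_lt(abs(om$omega["B", "B", kk] - red[3, 3]), 1e-10)
  }
})

test_that("reduction is the identity for unit multiplicities and maps 0 to 0", {
  sys <- soft_mixture(n = 48)
  g0 <- solve_structure(sys$u, sys$comp, sys$om, sys$settings)
  h <- stacked_field(sys$grid, g0$types, g0$values - 1)
  red <- reduce_correlations(h, sys$om, sys$comp)
  for (lab in h$interactions) {
    ab <- strsplit(lab, "-")[[1]]
    expect_equal(red$Hhat[ab[1], ab[2], ],
                 cgiter:::ft_values(h$values[, lab], sys$grid))
  }
  zero <- stacked_field(sys$grid, c("A", "B"))
  expect_true(all(reduce_correlations(zero, sys$om, sys$comp)$Hhat == 0))
  # inverse operation restores the field
  back <- correlations_field(red)
  expect_lt(max(abs(back$values[-1, ] - h$values[-1, ])), 1e-10)
})

test_that("single-bead direct correlation follows c = h/(1 + rho h) in k", {
  g <- radial_grid(64, 0.02)
  comp <- composition(c(A = 50), volume = 100, temperature = 1 / k_boltzmann)
  om <- build_omega(molecule_graph("A"), g)
  # place a spike in k space, transform to r, and push through the machinery
  j0 <- 12L
  hk <- rep(0, 64); hk[1 + j0] <- 1
  h_r <- cgiter:::ift_values(hk, g)
  h <- stacked_field(g, "A", matrix(h_r, 64, 1))
  red <- reduce_correlations(h, om, comp)
  c_sf <- direct_correlation(red, om, comp)
  ck <- cgiter:::ft_values(c_sf$values[, 1], g)
  expect_equal(ck[1 + j0], 1 / (1 + 0.5 * 1) * 1, tolerance = 1e-8)
  # h = 0 -> c = 0
  zero <- stacked_field(g, "A")
  expect_true(all(abs(direct_correlation(
    reduce_correlations(zero, om, comp), om, comp)$values) < 1e-14))
})

test_that("full and reduced RISM give identical site-averaged c on the
          rigid symmetric trimer", {
  tr <- trimer_structure()
  h <- stacked_field(tr$grid, tr$g$types, tr$g$values - 1)
  red <- reduce_correlations(h, tr$omega, tr$comp)
  c_red <- direct_correlation(red, tr$omega, tr$comp)
  rho_mol <- tr$comp$counts[["B"]] / tr$comp$volume
  c_full <- full_rism_trimer_c(h, tr$molecules[[1]], rho_mol, tr$grid)
  expect_lt(max(abs(c_red$values[-1, ] - c_full$values[-1, ])), 1e-10)
})

test_that("HNC closure returns zero potential for the ideal structure and
          reduces to Boltzmann inversion when c = h", {
  g <- radial_grid(64, 0.02, r_cut = 1.2)
  comp <- composition(c(A = 10), 100, 120)
  ones <- stacked_field(g, "A", 1, kind = "rdf")
  zero_c <- stacked_field(g, "A")
  u <- hnc_guess(ones, zero_c, comp$kT, r_cut = NULL)
  expect_true(all(abs(u$values[-1, ]) < 1e-14))
  # c = h: u = kT (h - c - ln g) = -kT ln g, the low-density inversion
  gv <- 1 + 0.3 * exp(-(g$r - 0.5)^2 / 0.02)
  rdf <- stacked_field(g, "A", matrix(gv, 64, 1), kind = "rdf")
  h_as_c <- stacked_field(g, "A", matrix(gv - 1, 64, 1))
  u2 <- hnc_guess(rdf, h_as_c, comp$kT, r_cut = NULL)
  expect_equal(u2$values[-1, 1], -comp$kT * log(gv[-1]), tolerance = 1e-12)
  bad <- stacked_field(g, "A", matrix(c(0, rep(0, 10), gv[-(1:11)]), 64, 1),
                       kind = "rdf")
  expect_error(hnc_guess(bad, zero_c, comp$kT), "extrapolate")
})

test_that("HNC inversion recovers the potential that generated the
          surrogate structure", {
  sys <- soft_single()
  g0 <- solve_structure(sys$u, sys$comp, sys$om, sys$settings)
  u_rec <- hnc_guess(g0, attr(g0, "c"), sys$comp$kT)
  idx <- 2:(1 + sys$grid$n_cut)
  expect_lt(max(abs(u_rec$values[idx, 1] - sys$u$values[idx, 1])), 1e-8)
})

test_that("k-space derivative matches the single-bead closed form and the
          zero-density identity", {
  g <- radial_grid(64, 0.02)
  comp <- composition(c(A = 50), 100, 1 / k_boltzmann)   # rho = 0.5, kT = 1
  om <- build_omega(molecule_graph("A"), g)
  j0 <- 9L
  hk <- rep(0, 64); hk[1 + j0] <- 2   # rho * h_hat = 1 at the spike
  h <- stacked_field(g, "A", matrix(cgiter:::ift_values(hk, g), 64, 1))
  op <- dcdh_k(reduce_correlations(h, om, comp), om, comp)
  el <- dcdh_element(op, "A", "A", "A", "A")
  expect_equal(el[1 + j0], 1 / (1 + 0.5 * 2)^2, tolerance = 1e-8)
  expect_equal(el[1 + j0], 1 / 4, tolerance = 1e-8)
  # rho -> 0: identity map on matched interactions
  tiny <- composition(c(A = 1e-9), 100, 1 / k_boltzmann)
  op0 <- dcdh_k(reduce_correlations(h, om, tiny), om, tiny)
  expect_equal(dcdh_element(op0, "A", "A", "A", "A"),
               rep(1, 64), tolerance = 1e-6)
})

test_that("k-space derivative matches finite differences of the direct
          correlation for a two-type mixture", {
  sys <- soft_mixture(n = 48)
  g0 <- solve_structure(sys$u, sys$comp, sys$om, sys$settings)
  h <- stacked_field(sys$grid, g0$types, g0$values - 1)
  red <- reduce_correlations(h, sys$om, sys$comp)
  op <- dcdh_k(red, sys$om, sys$comp)
  # perturb the reduced H_AB at one wave vector, recompute C, compare slope
  kk <- 15L
  eps <- 1e-6
  rho <- cgiter:::rho_molecular(sys$om, sys$comp)
  Om <- matrix(sys$om$omega[, , kk], 2, 2)
  solve_c <- function(Hk) solve(Om, Hk) %*% solve(Om + diag(rho) %*% Hk)
  H0 <- matrix(red$Hhat[, , kk], 2, 2)
  # symmetric (unordered) perturbation of the A-B source element; with unit
  # multiplicities reduced and site-averaged variables coincide
  dH <- matrix(c(0, eps, eps, 0), 2, 2)
  Cf <- solve_c(H0 + dH)
  Cb <- solve_c(H0 - dH)
  fd <- (Cf - Cb) / (2 * eps)
  types <- c("A", "B")
  for (tgt in list(c(1, 1), c(1, 2), c(2, 2))) {
    fd_sym <- (fd[tgt[1], tgt[2]] + fd[tgt[2], tgt[1]]) / 2
    merged <- cgiter:::dcdh_merged_element(op, types[tgt], c("A", "B"))[kk]
    expect_equal(merged, fd_sym, tolerance = 1e-5)
  }
})

test_that("real-space derivative conjugation maps the identity to the
          identity and matches forward finite differences", {
  sys <- soft_single(n = 48)
  g0 <- solve_structure(sys$u, sys$comp, sys$om, sys$settings)
  h <- stacked_field(sys$grid, g0$types, g0$values - 1)
  op <- dcdh_k(reduce_correlations(h, sys$om, sys$comp), sys$om, sys$comp)
  # identity operator: overwrite U, W with ones at every k
  op_id <- op
  op_id$U[1, 1, ] <- 1
  op_id$W[1, 1, ] <- 1
  M <- suppressWarnings(dcdh_real(op_id, n_out = 20))
  expect_lt(max(abs(M - diag(20))), 1e-10)
  # FD of real-space c under real-space h perturbations
  n_out <- sys$grid$n_points - 1L
  D <- suppressWarnings(dcdh_real(op, n_out = n_out))
  eps <- 1e-6
  for (j in c(5L, 20L)) {
    hp <- h; hp$values[1 + j, 1] <- hp$values[1 + j, 1] + eps
    hm <- h; hm$values[1 + j, 1] <- hm$values[1 + j, 1] - eps
    cp <- direct_correlation(reduce_correlations(hp, sys$om, sys$comp),
                             sys$om, sys$comp)
    cm <- direct_correlation(reduce_correlations(hm, sys$om, sys$comp),
                             sys$om, sys$comp)
    fd <- (cp$values[1 + seq_len(n_out), 1] -
             cm$values[1 + seq_len(n_out), 1]) / (2 * eps)
    expect_lt(max(abs(D[, j] - fd)) / max(abs(fd)), 1e-4)
  }
  expect_error(dcdh_real(op, n_out = 40, require_double = TRUE), "double")
})

test_that("derivative blocks obey the transpose symmetry for a
          single-molecule-type fluid", {
  sys <- soft_mixture(n = 48)
  g0 <- solve_structure(sys$u, sys$comp, sys$om, sys$settings)
  h <- stacked_field(sys$grid, g0$types, g0$values - 1)
  op <- dcdh_k(reduce_correlations(h, sys$om, sys$comp), sys$om, sys$comp)
  D <- suppressWarnings(dcdh_real(op, n_out = 30))
  # compare with the finite-difference matrix, which is the symmetric truth
  eps <- 1e-6
  j <- 12L
  for (ms in 1:3) {
    hp <- h; hp$values[1 + j, ms] <- hp$values[1 + j, ms] + eps
    hm <- h; hm$values[1 + j, ms] <- hm$values[1 + j, ms] - eps
    cp <- direct_correlation(reduce_correlations(hp, sys$om, sys$comp),
                             sys$om, sys$comp)
    cm <- direct_correlation(reduce_correlations(hm, sys$om, sys$comp),
                             sys$om, sys$comp)
    fd <- as.numeric(cp$values[1 + seq_len(30), ] -
                       cm$values[1 + seq_len(30), ]) / (2 * eps)
    col <- D[, (ms - 1) * 30 + j]
    expect_lt(max(abs(col - fd)) / max(abs(fd), 1e-12), 2e-4)
  }
})
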