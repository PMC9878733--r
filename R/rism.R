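# Symmetry-reduced RISM machinery: intramolecular density functions,
# direct correlation function, its derivative with respect to the total
# correlation function, and the HNC closure.
#
# Conventions. Site-site RISM for a molecular liquid reads (k-space, matrices
# over all n_td sites per molecule set, rho the per-site molecular density)
#   h' = w' c' w' + w' c' rho h'
# Indistinguishable sites allow a block-orthogonal similarity transformation
# that collapses the site matrices to n_t x n_t type matrices. Trajectory
# analysis produces site-averaged h, not h'; the reduced matrices are obtained
# directly via the multiplicity factors
#   H_ab = sqrt(n_a n_b) h_ab,   C_ab = sqrt(n_a n_b) c_ab,
# with the density matrix in the reduced equation being the per-molecule
# density of the species that owns each type. The reduced equation
#   H = W C W + W C rho H      (W here: reduced intramolecular matrix Omega)
# is solved for C as  C = Omega^-1 H (Omega + rho H)^-1.

#' Molecule connectivity and intramolecular distance specification
#'
#' Sites carry bead-type labels; sites of equal type are treated as
#' indistinguishable (multiplicity `n_a`). Intramolecular site-pair distances
#' are either fixed (rigid molecule: full symmetric `distances` matrix in nm)
#' or tabulated normalized distance distributions (`distributions`, a list
#' keyed `"i-j"` by site indices with [cg_curve()] values `p(b)`).
#'
#' @param sites character vector of bead-type labels, one per site.
#' @param distances symmetric numeric matrix of site-site distances (nm),
#'   diagonal zero; `NULL` for single-site molecules.
#' @param distributions named list of distance distributions, keyed `"i-j"`.
#' @export
molecule_graph <- function(sites, distances = NULL, distributions = NULL) {
  stopifnot(is.character(sites), length(sites) >= 1L)
  n_s <- length(sites)
  if (!is.null(distances)) {
    distances <- as.matrix(distances)
    if (nrow(distances) != n_s || ncol(distances) != n_s)
      stop("distances must be an n_sites x n_sites matrix")
    if (max(abs(distances - t(distances))) > 1e-12)
      stop("distances must be symmetric")
  }
  mult <- table(sites)
  structure(list(sites = sites, n_sites = n_s,
                 types = sort(unique(sites)),
                 mult = stats::setNames(as.integer(mult), names(mult)),
                 distances = distances, distributions = distributions),
            class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("molecule_graph: %d site(s) [%s]; types: %s\n", x$n_sites,
              paste(x$sites, collapse = "-"),
              paste(sprintf("%s (n=%d)", x$types, x$mult[x$types]), collapse = ", ")))
  invisible(x)
}

# sin(kb)/(kb) with the k -> 0 limit
sinc_kb <- function(k, b) {
  out <- rep(1, length(k))
  nz <- k * b != 0
  out[nz] <- sin(k[nz] * b) / (k[nz] * b)
  out
}

omega_pair_values <- function(mol, i, j, k) {
  if (i == j) return(rep(1, length(k)))
  if (!is.null(mol$distances)) {
    b <- mol$distances[i, j]
    if (!is.finite(b) || b <= 0)
      stop(sprintf("missing intramolecular distance for site pair %d-%d", i, j))
    return(sinc_kb(k, b))
  }
  key <- paste(min(i, j), max(i, j), sep = "-")
  p <- mol$distributions[[key]]
  if (is.null(p))
    stop(sprintf("missing intramolecular distance spec for site pair %d-%d", i, j))
  b <- p$grid$r
  w <- p$values
  w <- w / sum(w)                      # normalize the tabulated distribution
  vapply(k, function(kk) sum(w * sinc_kb(kk, b)), numeric(1))
}

#' Symmetry-reduced intramolecular density matrix
#'
#' Builds the `n_t x n_t` reduced matrix `Omega(k)` for every wave vector.
#' A rigid site pair at distance `b` contributes `sin(kb)/(kb)`; tabulated
#' distance distributions contribute their radial transform; self terms are 1.
#' The reduced element is `Omega_ab = (n_a n_b)^{-1/2} sum_{i in a, j in b}
#' omega_ij`, which applies the multiplicity (conversion) factors so that the
#' explicit site-space transformation is never needed. Types belonging to
#' different molecule species have zero off-diagonal elements. Single-bead
#' molecules give the identity at every k.
#'
#' @param molecules a [molecule_graph()] or list of them (disjoint type sets).
#' @param grid a [radial_grid()] supplying the wave vectors.
#' @return object of class `intramolecular_matrix` with fields `omega`
#'   (`n_t x n_t x n_points` array over k), `types`, `mult` (per-type site
#'   multiplicity), and `species` (molecule index owning each type).
#' @export
build_omega <- function(molecules, grid) {
  if (inherits(molecules, "molecule_graph")) molecules <- list(molecules)
  types <- sort(unique(unlist(lapply(molecules, `[[`, "types"))))
  all_types <- unlist(lapply(molecules, `[[`, "types"))
  if (anyDuplicated(all_types))
    stop("bead types must belong to exactly one molecule species")
  n_t <- length(types)
  k <- grid$k
  om <- array(0, c(n_t, n_t, grid$n_points),
              dimnames = list(types, types, NULL))
  mult <- stats::setNames(rep(1L, n_t), types)
  species <- stats::setNames(rep(NA_integer_, n_t), types)
  for (m in seq_along(molecules)) {
    mol <- molecules[[m]]
    mult[mol$types] <- mol$mult[mol$types]
    species[mol$types] <- m
    for (a in mol$types) for (b in mol$types) {
      if (match(a, types) > match(b, types)) next
      ia <- which(mol$sites == a)
      ib <- which(mol$sites == b)
      acc <- rep(0, length(k))
      for (i in ia) for (j in ib) {
        if (a == b && i == j) { acc <- acc + 1; next }
        acc <- acc + omega_pair_values(mol, i, j, k)
      }
      val <- acc / sqrt(length(ia) * length(ib))
      om[a, b, ] <- val
      om[b, a, ] <- val
    }
  }
  structure(list(omega = om, types = types, mult = mult, species = species,
                 grid = grid),
            class = "intramolecular_matrix")
}

#' @export
print.intramolecular_matrix <- function(x, ...) {
  cat(sprintf("intramolecular_matrix: %d type(s) [%s] on %d wave vectors\n",
              length(x$types), paste(x$types, collapse = ", "),
              x$grid$n_points))
  invisible(x)
}

# per-type molecular density (molecules of the owning species per volume)
rho_molecular <- function(omega, comp) {
  if (!identical(omega$types, comp$types))
    stop("bead types of omega and composition do not match")
  as.numeric(comp$rho[omega$types] / omega$mult[omega$types])
}

conversion_factors <- function(omega) {
  m <- as.numeric(omega$mult[omega$types])
  sqrt(outer(m, m))
}

#' Reduce site-averaged correlations to symmetry-adapted matrices
#'
#' Takes the site-averaged total correlation functions `h_ab` (what trajectory
#' analysis produces), Fourier transforms them and applies the multiplicity
#' factors `sqrt(n_a n_b)` to obtain the reduced matrices `H(k)`. With all
#' multiplicities 1 the reduction is the identity.
#'
#' @param h a [stacked_field()] of total correlation functions `h = g - 1`.
#' @param omega an `intramolecular_matrix` from [build_omega()].
#' @param comp a [composition()].
#' @return object of class `reduced_correlations` with `Hhat`
#'   (`n_t x n_t x n_points` array over k), `hhat`, `factors`, `rho_mol`.
#' @export
reduce_correlations <- function(h, omega, comp) {
  stopifnot(inherits(h, "stacked_field"))
  if (!identical(h$types, omega$types))
    stop("bead types of the field and omega do not match")
  types <- omega$types
  n_t <- length(types)
  n <- h$grid$n_points
  f <- conversion_factors(omega)
  hhat <- array(0, c(n_t, n_t, n), dimnames = list(types, types, NULL))
  for (a in seq_len(n_t)) for (b in a:n_t) {
    hk <- ft_values(h$values[, pair_label(types[a], types[b])], h$grid)
    hhat[a, b, ] <- hk
    hhat[b, a, ] <- hk
  }
  Hhat <- hhat * array(f, c(n_t, n_t, n))
  structure(list(Hhat = Hhat, hhat = hhat, factors = f,
                 rho_mol = rho_molecular(omega, comp),
                 types = types, grid = h$grid),
            class = "reduced_correlations")
}

#' @export
print.reduced_correlations <- function(x, ...) {
  cat(sprintf("reduced_correlations: %d x %d matrices on %d wave vectors\n",
              length(x$types), length(x$types), x$grid$n_points))
  invisible(x)
}

#' Recover the site-averaged field from reduced correlations
#'
#' Inverse of [reduce_correlations()]: divides out the multiplicity factors
#' and transforms back to real space.
#' @param red a `reduced_correlations` object.
#' @param kind curve kind of the output field.
#' @export
correlations_field <- function(red, kind = "correlation") {
  types <- red$types
  sf <- stacked_field(red$grid, types, kind = kind)
  for (a in seq_along(types)) for (b in a:length(types)) {
    hk <- red$Hhat[a, b, ] / red$factors[a, b]
    sf$values[, pair_label(types[a], types[b])] <- ift_values(hk, red$grid)
  }
  sf
}

#' Direct correlation function from total correlation (reduced RISM)
#'
#' Solves the reduced RISM equation per wave vector for the adapted direct
#' correlation matrix, `C = Omega^-1 H (Omega + rho H)^-1`, divides out the
#' multiplicity factors and transforms back to a real-space stacked field.
#' For a single bead type this is the familiar `c_hat = h_hat/(1 + rho h_hat)`.
#'
#' @param H a `reduced_correlations` object from [reduce_correlations()].
#' @param omega matching `intramolecular_matrix`.
#' @param comp a [composition()].
#' @return a [stacked_field()] with the direct correlation functions `c_ab(r)`.
#' @export
direct_correlation <- function(H, omega, comp) {
  types <- H$types
  n_t <- length(types)
  n <- H$grid$n_points
  rho <- diag(rho_molecular(omega, comp), n_t)
  chat <- array(0, c(n_t, n_t, n))
  # k = 0 is skipped: for rigid molecules Omega(0) is rank-deficient (all
  # sites fully correlated) and the k = 0 component never enters the inverse
  # transform; the stored value is a quadratic extrapolation for display.
  for (kk in 2:n) {
    Om <- matrix(omega$omega[, , kk], n_t, n_t)
    Hk <- matrix(H$Hhat[, , kk], n_t, n_t)
    Z <- Om + rho %*% Hk
    Ck <- tryCatch(solve(Om, Hk) %*% solve(Z),
                   error = function(e)
                     stop(sprintf("singular RISM matrix at k = %g nm^-1",
                                  H$grid$k[kk]), call. = FALSE))
    Ck <- (Ck + t(Ck)) / 2
    chat[, , kk] <- Ck / H$factors
  }
  chat[, , 1L] <- 3 * chat[, , 2L] - 3 * chat[, , 3L] + chat[, , 4L]
  sf <- stacked_field(H$grid, types, kind = "correlation")
  for (a in seq_len(n_t)) for (b in a:n_t)
    sf$values[, pair_label(types[a], types[b])] <- ift_values(chat[a, b, ], H$grid)
  sf
}

#' HNC closure potential from RDF and direct correlation
#'
#' Pointwise hypernetted-chain closure `u = kT (h - c - ln g)` with
#' `h = g - 1`. The two orientations of each cross interaction are averaged
#' (automatic in the unordered representation used here). The result is cut at
#' `r_cut` and shifted so it is exactly zero at and beyond the cutoff. The
#' value at \eqn{r = 0} is set by linear continuation of the first two interior
#' points (the onset carries a capped repulsive value by convention).
#'
#' @param g [stacked_field()] of RDFs (onset-extrapolated, \eqn{g > 0} for \eqn{r > 0}).
#' @param c [stacked_field()] of direct correlation functions.
#' @param kT thermal energy in kJ/mol.
#' @param r_cut cutoff in nm (default: the grid's `r_cut`); `NULL` to skip
#'   cutting/shifting.
#' @return a [stacked_field()] of potentials (kJ/mol).
#' @export
hnc_guess <- function(g, c, kT, r_cut = g$grid$r_cut) {
  stopifnot(inherits(g, "stacked_field"), inherits(c, "stacked_field"))
  if (!same_grid(g$grid, c$grid)) stop("g and c are on different grids")
  u <- stacked_field(g$grid, g$types, kind = "potential")
  for (lab in g$interactions) {
    gv <- g$values[, lab]
    if (any(gv[-1L] <= 0))
      stop("g has nonpositive values inside the evaluation range for ", lab,
           "; extrapolate the RDF onset first (see extrapolate_onset)")
    uv <- kT * ((gv - 1) - c$values[, lab] - log(gv))
    uv[1L] <- 2 * uv[2L] - uv[3L]
    u$values[, lab] <- uv
  }
  if (!is.null(r_cut)) u <- cut_and_shift(u, r_cut)
  u
}

#' Cut a potential field at the cutoff and shift it to zero beyond
#'
#' @param u [stacked_field()] of potentials.
#' @param r_cut cutoff in nm.
#' @export
cut_and_shift <- function(u, r_cut = u$grid$r_cut) {
  i_cut <- as.integer(floor(r_cut / u$grid$dr + 1e-9)) + 1L  # index of r_cut
  for (lab in u$interactions) {
    v <- u$values[, lab]
    v <- v - v[i_cut]
    v[seq_along(v) >= i_cut] <- 0
    u$values[, lab] <- v
  }
  u
}

#' Derivative of the direct correlation w.r.t. the total correlation (k-space)
#'
#' Per wave vector, perturbing the reduced RISM solution gives
#' `dC = U dH W` with `U = Omega^-1 - C rho` and `W = (Omega + rho H)^-1`;
#' by the vectorization identity `vec(U V W) = (W' (x) U) vec(V)` this is the
#' Kronecker-structured linear map of the adapted variables. The site-averaged
#' derivative carries the ratio of multiplicity factors. At zero density (and
#' no bonds) the map is the identity on matched interactions; for a single
#' bead type it is `(1 + rho h_hat)^-2`.
#'
#' @param H `reduced_correlations`.
#' @param omega matching `intramolecular_matrix`.
#' @param comp a [composition()].
#' @return object of class `dcdh_operator` holding per-k `U`, `W` and factors.
#' @export
dcdh_k <- function(H, omega, comp) {
  types <- H$types
  n_t <- length(types)
  n <- H$grid$n_points
  rho <- diag(rho_molecular(omega, comp), n_t)
  U <- array(0, c(n_t, n_t, n), dimnames = list(types, types, NULL))
  W <- U
  # k = 0 handled by extrapolation, as in direct_correlation()
  for (kk in 2:n) {
    Om <- matrix(omega$omega[, , kk], n_t, n_t)
    Hk <- matrix(H$Hhat[, , kk], n_t, n_t)
    Z <- Om + rho %*% Hk
    Wk <- tryCatch(solve(Z), error = function(e)
      stop(sprintf("singular RISM matrix at k = %g nm^-1", H$grid$k[kk]),
           call. = FALSE))
    Ck <- solve(Om, Hk) %*% Wk
    U[, , kk] <- solve(Om) - Ck %*% rho
    W[, , kk] <- Wk
  }
  U[, , 1L] <- 3 * U[, , 2L] - 3 * U[, , 3L] + U[, , 4L]
  W[, , 1L] <- 3 * W[, , 2L] - 3 * W[, , 3L] + W[, , 4L]
  structure(list(U = U, W = W, factors = H$factors, types = types,
                 grid = H$grid),
            class = "dcdh_operator")
}

#' @export
print.dcdh_operator <- function(x, ...) {
  cat(sprintf("dcdh_operator: %d type(s), %d wave vectors\n",
              length(x$types), x$grid$n_points))
  invisible(x)
}

#' Single ordered element of the k-space derivative
#'
#' `d c_hat_{ab} / d h_hat_{ge}` as a vector over the wave-vector grid, for
#' ordered pairs (before orientation merging).
#' @param op a `dcdh_operator`.
#' @param a,b target interaction types (ordered).
#' @param g,e source interaction types (ordered).
#' @export
dcdh_element <- function(op, a, b, g, e) {
  ia <- match(a, op$types); ib <- match(b, op$types)
  ig <- match(g, op$types); ie <- match(e, op$types)
  if (anyNA(c(ia, ib, ig, ie))) stop("unknown bead type")
  (op$factors[ig, ie] / op$factors[ia, ib]) * op$U[ia, ig, ] * op$W[ie, ib, ]
}

# merged (unordered) derivative element over k: rows averaged over the two
# orientations of the target pair, columns summed over the orientations of the
# source pair (a potential perturbation moves both ordered elements).
dcdh_merged_element <- function(op, tgt, src) {
  t2 <- if (tgt[1] == tgt[2]) list(tgt) else list(tgt, rev(tgt))
  s2 <- if (src[1] == src[2]) list(src) else list(src, rev(src))
  acc <- 0
  for (tt in t2) {
    row <- 0
    for (ss in s2) row <- row + dcdh_element(op, tt[1], tt[2], ss[1], ss[2])
    acc <- acc + row
  }
  acc / length(t2)
}

#' Real-space derivative matrix of c with respect to h
#'
#' Conjugates the k-space derivative by the discrete Fourier matrices,
#' giving the dense real-space matrix `d c_ab(r_i) / d h_ge(r_j)` over
#' unordered interactions and interior grid points `i, j = 1 .. n_out`.
#' Orientations are merged (rows averaged, columns summed).
#'
#' When the derivative is precomputed once from target RDFs (the t-variants)
#' the input curves must extend to twice the output range to avoid truncation
#' artifacts; request this check with `require_double = TRUE`.
#'
#' @param op a `dcdh_operator` from [dcdh_k()].
#' @param n_out interior points per interaction in the output (default
#'   `n_res` of the operator grid).
#' @param require_double error (rather than warn) if the operator grid does
#'   not extend to `2 * n_out` points.
#' @return dense matrix of size `(n_i * n_out) x (n_i * n_out)`, with
#'   attribute `"interactions"`.
#' @export
dcdh_real <- function(op, n_out = op$grid$n_res, require_double = FALSE) {
  n <- op$grid$n_points
  if (n - 1L < 2L * n_out) {
    msg <- sprintf(paste0("operator grid (%d interior points) is shorter than ",
                          "twice the output range (%d)"), n - 1L, 2L * n_out)
    if (require_double) stop(msg, "; provide curves of double length")
    warning(msg, "; derivative computed at current length")
  }
  if (n_out > n - 1L) stop("n_out exceeds the operator grid")
  fm <- fourier_matrices(op$grid)
  labels <- interaction_labels(op$types)
  n_i <- length(labels)
  M <- matrix(0, n_i * n_out, n_i * n_out)
  idx <- function(m) ((m - 1L) * n_out + 1L):(m * n_out)
  keep <- seq_len(n_out)
  for (mt in seq_len(n_i)) {
    tgt <- split_pair(labels[mt])
    for (ms in seq_len(n_i)) {
      src <- split_pair(labels[ms])
      d <- dcdh_merged_element(op, tgt, src)[-1L]  # interior wave vectors
      block <- fm$Finv %*% (d * fm$F)
      M[idx(mt), idx(ms)] <- block[keep, keep]
    }
  }
  attr(M, "interactions") <- labels
  attr(M, "n_out") <- n_out
  M
}
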