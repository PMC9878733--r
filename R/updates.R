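# Newton and weighted/constrained Gauss-Newton potential updates,
# thermodynamic property evaluators, and constraint rows.
#
# Residual convention, fixed repository-wide: residual = g_tgt - g_k, and
# a step Delta u satisfies J Delta u ~ residual (J = dg/du). Constraint rows
# use K = -dphi/du with d = phi_k - phi_tgt, so K Delta u = d drives the
# property to its target.

#' Newton potential update
#'
#' `Delta u = J_inv (g_tgt - g_k)` for a square system. With the HNC Jacobian
#' inverse this is the HNCN update; with the diagonal low-density inverse it
#' is the a-Newton update.
#'
#' @param J_inv square `du/dg` matrix.
#' @param residual flat residual vector `g_tgt - g_k` (interior points).
#' @return numeric update vector.
#' @export
newton_step <- function(J_inv, residual) {
  if (nrow(J_inv) != ncol(J_inv)) stop("newton_step needs a square Jacobian")
  if (length(residual) != ncol(J_inv))
    stop("residual length does not match the Jacobian")
  as.numeric(J_inv %*% residual)
}

#' Default residual weights
#'
#' The diagonal weighting `r^2 / (g_tgt + 1e-30)` that emphasises the RDF
#' onset and tail. The RDF in the denominator is floored at `g_floor` so the
#' weighted system stays within double range deep in the onset, where the
#' extrapolated RDF underflows; rows there carry no structural information.
#' @param g_tgt target RDF field.
#' @param n_out interior points per interaction (default `n_res`).
#' @param g_floor RDF floor in the denominator.
#' @export
default_weights <- function(g_tgt, n_out = g_tgt$grid$n_res, g_floor = 1e-8) {
  r <- g_tgt$grid$r[1L + seq_len(n_out)]
  w <- numeric(0)
  for (lab in g_tgt$interactions)
    w <- c(w, r^2 / (pmax(g_tgt$values[1L + seq_len(n_out), lab], g_floor)
                     + 1e-30))
  w
}

#' One linear constraint on the potential update
#'
#' A coefficient row `K` over (interaction, interior grid point up to
#' `n_cut`) plus scalar right-hand side `d`; the constrained step enforces
#' `K Delta u = d`. At satisfaction of the property `d = 0`.
#' @param coefficients numeric coefficient vector.
#' @param rhs scalar right-hand side.
#' @param label one of the property labels (`"pressure"`, `"kbi:<pair>"`,
#'   `"pe"`, ...).
#' @export
constraint_row <- function(coefficients, rhs, label = "constraint") {
  if (any(!is.finite(coefficients)) || !is.finite(rhs))
    stop("constraint coefficients must be finite")
  structure(list(coefficients = as.numeric(coefficients), rhs = rhs,
                 label = label),
            class = "constraint_row")
}

#' @export
print.constraint_row <- function(x, ...) {
  cat(sprintf("constraint_row '%s': %d coefficients, d = %g\n",
              x$label, length(x$coefficients), x$rhs))
  invisible(x)
}

constraints_matrix <- function(constraints, n_col) {
  if (inherits(constraints, "constraint_row")) constraints <- list(constraints)
  K <- do.call(rbind, lapply(constraints, `[[`, "coefficients"))
  if (ncol(K) != n_col) stop("constraint length does not match the system")
  list(K = K, d = vapply(constraints, `[[`, numeric(1), "rhs"),
       labels = vapply(constraints, `[[`, character(1), "label"))
}

# Least-norm least squares with relative singular-value cutoff. The cutoff
# discards directions the weighted data cannot determine: with r^2/g_tgt
# weighting on fine grids the spectrum spans many orders, and directions
# below ~1e-6 only amplify roundoff in the residual.
svd_lsq <- function(A, b, rcond = 1e-6) {
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1L]
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
}

#' Weighted, equality-constrained Gauss-Newton update
#'
#' Minimizes `|| W (J Delta u - residual) ||_2` subject to `K Delta u = d`,
#' by direct elimination: a QR factorization of `K'` splits the update into a
#' particular solution and a null-space component, and the reduced
#' unconstrained problem is solved by SVD least squares (relative cutoff
#' 1e-6; constraint feasibility is enforced exactly by the particular
#' solution regardless of the cutoff). With no constraints, square `J` and unit weights the step equals
#' [newton_step()] with the inverted Jacobian. The final update is multiplied
#' by `scale` (1 by default; 0.67 damps overshooting updates).
#'
#' @param J `dg/du` Jacobian (rows: residual entries, columns: potential
#'   entries).
#' @param W diagonal weight vector over rows (`NULL` for unit weights).
#' @param residual flat `g_tgt - g_k` vector.
#' @param constraints list of [constraint_row()]s (or `NULL`).
#' @param selection optional [selection()]; frozen potentials get zero update.
#' @param scale update scaling factor.
#' @param rcond relative singular-value cutoff of the least-squares solve.
#' @return numeric update vector (full column dimension of `J`).
#' @export
gauss_newton_step <- function(J, W = NULL, residual, constraints = NULL,
                              selection = NULL, scale = 1.0, rcond = 1e-6) {
  interactions <- attr(J, "interactions")
  n_full <- ncol(J)
  col_keep <- seq_len(n_full)
  if (!is.null(selection)) {
    red <- selective_reduce(J, residual, selection)
    col_keep <- red$col_keep
    if (!is.null(W)) W <- W[red$row_keep]
    J <- red$J
    residual <- red$residual
  }
  if (nrow(J) < ncol(J))
    stop("fewer residual rows than active potential columns")
  if (is.null(W)) W <- rep(1, nrow(J))
  if (length(W) != nrow(J)) stop("weight length does not match rows")
  if (any(W < 0) || any(!is.finite(W))) stop("weights must be nonnegative finite")
  A <- W * J
  b <- W * residual
  if (is.null(constraints) || length(constraints) == 0L) {
    du_red <- svd_lsq(A, b, rcond)
  } else {
    cm <- constraints_matrix(constraints, n_full)
    K <- cm$K[, col_keep, drop = FALSE]
    d <- cm$d
    qrK <- qr(t(K))
    if (qrK$rank < nrow(K))
      stop("rank-deficient or infeasible constraints among: ",
           paste(cm$labels, collapse = ", "))
    Q <- qr.Q(qrK, complete = TRUE)
    R <- qr.R(qrK)
    m <- nrow(K)
    # particular solution: K du_p = d
    du_p <- Q[, seq_len(m), drop = FALSE] %*%
      backsolve(t(R)[seq_len(m), seq_len(m), drop = FALSE],
                d[qrK$pivot], upper.tri = FALSE)
    # the pivoting of qr() permutes constraint rows: solve R' y = d[pivot]
    Z <- Q[, -seq_len(m), drop = FALSE]
    z <- svd_lsq(A %*% Z, b - A %*% du_p, rcond)
    du_red <- du_p + Z %*% z
  }
  du <- numeric(n_full)
  du[col_keep] <- as.numeric(du_red)
  scale * du
}

#' Selection of potentials to update and targets to match
#'
#' @param update character vector of interaction labels whose potentials are
#'   updated (columns kept).
#' @param targets character vector of interaction labels whose RDFs are
#'   matched (rows kept). Defaults to `update`.
#' @export
selection <- function(update, targets = update) {
  if (length(update) == 0L || length(targets) == 0L)
    stop("selection must name at least one potential and one target")
  structure(list(update = update, targets = targets), class = "cg_selection")
}

#' Reduce a Jacobian system to a selection
#'
#' Drops the columns of frozen potentials and the rows of ignored target
#' RDFs. For HNC Jacobians the full matrix must be built first and then
#' reduced (the closure couples all interactions); IMC matrices may omit
#' interactions from the start.
#'
#' @param J Jacobian with `interactions`/`n_out` attributes.
#' @param residual flat residual vector (rows of `J`).
#' @param sel a [selection()].
#' @return list with reduced `J`, `residual`, and the kept row/column indices.
#' @export
selective_reduce <- function(J, residual, sel) {
  interactions <- attr(J, "interactions")
  n_out_row <- length(residual) %/% length(interactions)
  n_out_col <- ncol(J) %/% length(interactions)
  if (!all(sel$update %in% interactions) || !all(sel$targets %in% interactions))
    stop("selection names unknown interactions")
  row_keep <- unlist(lapply(match(sel$targets, interactions),
                            function(m) (m - 1L) * n_out_row + seq_len(n_out_row)))
  col_keep <- unlist(lapply(match(sel$update, interactions),
                            function(m) (m - 1L) * n_out_col + seq_len(n_out_col)))
  Jr <- J[row_keep, col_keep, drop = FALSE]
  attr(Jr, "form") <- attr(J, "form")
  list(J = Jr, residual = residual[row_keep],
       row_keep = row_keep, col_keep = col_keep)
}

# ---- thermodynamic property evaluators ------------------------------------

pair_prefactors <- function(comp, interactions) {
  vapply(interactions, function(lab) {
    ab <- split_pair(lab)
    (2 - as.numeric(ab[1] == ab[2])) * comp$rho[[ab[1]]] * comp$rho[[ab[2]]]
  }, numeric(1))
}

#' Virial pressure of a tabulated pair system
#'
#' Ideal term `kT sum_a rho_a` plus the discrete virial sum over half-shifted
#' grid points: forces are centered differences of the tabulated potential at
#' the midpoints, RDF values are midpoint averages, and the unrestricted
#' double species sum contributes the factor `(2 - delta_ab)`.
#'
#' @param g RDF [stacked_field()].
#' @param u potential [stacked_field()] (zero beyond `r_cut`).
#' @param comp a [composition()].
#' @return pressure in bar.
#' @export
virial_pressure <- function(g, u, comp) {
  grid <- g$grid
  n_cut <- grid$n_cut
  rmid <- grid_midpoints(grid, n_cut)
  pre <- pair_prefactors(comp, g$interactions)
  vir <- 0
  for (lab in g$interactions) {
    uv <- u$values[, lab]
    gv <- g$values[, lab]
    i <- seq_len(n_cut)                       # midpoints between i-1 and i
    f_mid <- (uv[i] - uv[i + 1L]) / grid$dr   # force -du/dr at r_(i-1/2)
    g_mid <- (gv[i] + gv[i + 1L]) / 2
    vir <- vir + pre[[lab]] * sum(rmid^3 * f_mid * g_mid) * grid$dr
  }
  p_internal <- comp$kT * sum(comp$rho) + (2 * pi / 3) * vir
  p_internal * .bar_per_kJ_mol_nm3
}

#' Kirkwood-Buff integrals from the RDF
#'
#' Discrete running integral `G_ab = sum_i 4 pi r_i^2 (g_i - 1) dr` up to
#' `r_res`, in nm^3 (multiply by 1000 for Angstrom^3).
#'
#' @param g RDF [stacked_field()].
#' @param n_res integration range in interior points (default grid `n_res`).
#' @return named vector of KBIs per interaction (nm^3).
#' @export
kirkwood_buff <- function(g, n_res = g$grid$n_res) {
  grid <- g$grid
  r <- grid$r[1L + seq_len(n_res)]
  vapply(g$interactions, function(lab) {
    sum(4 * pi * r^2 * (g$values[1L + seq_len(n_res), lab] - 1)) * grid$dr
  }, numeric(1))
}

#' Intermolecular potential energy per bead
#'
#' Discrete pair-energy integral
#' `PE/N = (1/(2 N V)) sum_{a<=b} (2 - delta_ab) N_a N_b sum_i 4 pi r_i^2
#' u_i g_i dr` (kJ/mol per bead; equals the per-molecule value for single-bead
#' molecules). Intramolecular pair potentials are out of scope.
#'
#' @param g RDF [stacked_field()].
#' @param u potential [stacked_field()].
#' @param comp a [composition()].
#' @return energy per count in kJ/mol.
#' @export
intermolecular_pe <- function(g, u, comp) {
  grid <- g$grid
  n_cut <- grid$n_cut
  r <- grid$r[1L + seq_len(n_cut)]
  N <- sum(comp$counts)
  acc <- 0
  for (lab in g$interactions) {
    ab <- split_pair(lab)
    pre <- (2 - as.numeric(ab[1] == ab[2])) *
      comp$counts[[ab[1]]] * comp$counts[[ab[2]]] / comp$volume
    idx <- 1L + seq_len(n_cut)
    acc <- acc + pre * sum(4 * pi * r^2 * u$values[idx, lab] *
                             g$values[idx, lab]) * grid$dr
  }
  acc / (2 * N)
}

# ---- constraint builders ---------------------------------------------------

#' Pressure constraint row
#'
#' Coefficients are the (negated) exact derivative of the discrete virial
#' pressure with respect to each tabulated potential value, holding the RDF
#' fixed (the RDF response term is neglected, a good approximation after the
#' first iterations); `d = p_k - p_tgt`.
#'
#' @param g_k current RDF field.
#' @param u_k current potential field (used only for the current pressure).
#' @param comp a [composition()].
#' @param p_tgt target pressure (bar).
#' @return a [constraint_row()] over (interaction, interior point up to n_cut).
#' @export
pressure_constraint <- function(g_k, u_k, comp, p_tgt) {
  grid <- g_k$grid
  n_cut <- grid$n_cut
  rmid <- grid_midpoints(grid, n_cut)
  pre <- pair_prefactors(comp, g_k$interactions)
  coef <- numeric(0)
  for (lab in g_k$interactions) {
    gv <- g_k$values[, lab]
    i <- seq_len(n_cut)
    g_mid <- (gv[i] + gv[i + 1L]) / 2
    t_mid <- rmid^3 * g_mid                       # per-midpoint virial weight
    # f at midpoint j+1 gains +1/dr from u_j, f at midpoint j gains -1/dr
    dpdu <- (2 * pi / 3) * pre[[lab]] *
      (c(t_mid[-1L], 0) - t_mid) * .bar_per_kJ_mol_nm3
    coef <- c(coef, dpdu)
  }
  p_k <- virial_pressure(g_k, u_k, comp)
  constraint_row(-coef, p_k - p_tgt, label = "pressure")
}

#' Kirkwood-Buff integral constraint rows
#'
#' One row per constrained interaction: the KBI depends on the potential only
#' through the RDF, so the chain rule with the step's own Jacobian gives
#' coefficients `-(dG/dg) J` restricted to that interaction's rows;
#' `d = G_k - G_tgt`.
#'
#' @param g_k,g_tgt current and target RDF fields.
#' @param J `dg/du` Jacobian used in the step (rows over `n_res` interior
#'   points per interaction).
#' @param interactions labels to constrain (default: all).
#' @return list of [constraint_row()]s.
#' @export
kbi_constraint <- function(g_k, g_tgt, J, interactions = g_k$interactions) {
  grid <- g_k$grid
  n_res_rows <- nrow(J) %/% length(g_k$interactions)
  r <- grid$r[1L + seq_len(n_res_rows)]
  dGdg <- 4 * pi * r^2 * grid$dr
  G_k <- kirkwood_buff(g_k, n_res = n_res_rows)
  G_tgt <- kirkwood_buff(g_tgt, n_res = n_res_rows)
  lapply(interactions, function(lab) {
    m <- match(lab, g_k$interactions)
    if (is.na(m)) stop("interaction not in system: ", lab)
    rows <- (m - 1L) * n_res_rows + seq_len(n_res_rows)
    coef <- -as.numeric(dGdg %*% J[rows, , drop = FALSE])
    constraint_row(coef, G_k[[lab]] - G_tgt[[lab]],
                   label = paste0("kbi:", lab))
  })
}

#' Intermolecular potential-energy constraint row
#'
#' Same structure as the pressure constraint: exact derivative of the
#' discrete pair-energy sum with respect to the potential values at fixed
#' RDF, `d = PE_k - PE_tgt` (per bead, kJ/mol).
#'
#' @param g_k current RDF field.
#' @param u_k current potential field.
#' @param comp a [composition()].
#' @param pe_tgt target intermolecular potential energy per count (kJ/mol).
#' @export
pe_constraint <- function(g_k, u_k, comp, pe_tgt) {
  grid <- g_k$grid
  n_cut <- grid$n_cut
  r <- grid$r[1L + seq_len(n_cut)]
  N <- sum(comp$counts)
  coef <- numeric(0)
  for (lab in g_k$interactions) {
    ab <- split_pair(lab)
    pre <- (2 - as.numeric(ab[1] == ab[2])) *
      comp$counts[[ab[1]]] * comp$counts[[ab[2]]] / comp$volume
    coef <- c(coef, pre * 4 * pi * r^2 *
                g_k$values[1L + seq_len(n_cut), lab] * grid$dr / (2 * N))
  }
  pe_k <- intermolecular_pe(g_k, u_k, comp)
  constraint_row(-coef, pe_k - pe_tgt, label = "pe")
}
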