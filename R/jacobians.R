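# Update Jacobians: HNC (with onset-averaged diagonal), the diagonal
# low-density form, the inverse Monte Carlo Jacobian estimated from
# particle-count cross-correlations, and the IBI update.
#
# Index convention: Jacobian rows/columns run over (interaction, interior
# grid point i = 1..n) in interaction_labels() order; the r = 0 bin is
# excluded (its shell volume is zero).

flat_interior <- function(sf, n_out) {
  as.numeric(sf$values[1L + seq_len(n_out), , drop = FALSE])
}

gbar_interior <- function(g_tgt, g_k, n_out) {
  (flat_interior(g_tgt, n_out) + flat_interior(g_k, n_out)) / 2
}

#' Inverse HNC Jacobian (du/dg)
#'
#' Differentiating the HNC closure gives the Jacobian inverse directly:
#' `(J^-1)_{ab i, ge j} = kT [ delta (1 - 1/gbar_i) - dc_ab(r_i)/dh_ge(r_j) ]`,
#' where the diagonal uses `gbar = (g_tgt + g_k)/2`, the average of target and
#' current RDF that stabilizes the onset region (with `g_tgt = g_k` this is
#' the plain closure derivative). Newton uses the returned matrix as-is;
#' Gauss-Newton inverts it to obtain `dg/du`.
#'
#' @param g_tgt,g_k target and current RDF [stacked_field()]s.
#' @param dcdh real-space derivative matrix from [dcdh_real()].
#' @param kT thermal energy (kJ/mol).
#' @return matrix with attribute `form = "dudg"`.
#' @export
jacobian_hnc <- function(g_tgt, g_k, dcdh, kT) {
  n_out <- attr(dcdh, "n_out")
  if (is.null(n_out)) stop("dcdh must come from dcdh_real()")
  gbar <- gbar_interior(g_tgt, g_k, n_out)
  n_cut <- g_tgt$grid$n_cut
  in_cut <- as.logical(outer(seq_len(n_out) <= n_cut,
                             rep(TRUE, length(g_tgt$interactions))))
  if (any(gbar[in_cut] <= 0))
    stop("average RDF is nonpositive inside the cutoff; ",
         "extrapolate the RDF onset first (see extrapolate_onset)")
  J <- kT * (diag(1 - 1 / gbar, length(gbar)) - dcdh)
  attr(J, "form") <- "dudg"
  attr(J, "interactions") <- g_tgt$interactions
  attr(J, "n_out") <- n_out
  J
}

#' Invert a du/dg Jacobian with onset regularization
#'
#' Inverts the HNC Jacobian inverse to the forward form `dg/du`. Rows whose
#' average RDF is below `g_floor` are dominated by the diagonal closure term
#' `-kT/gbar` (magnitudes beyond float range deep in the onset); their inverse
#' rows/columns are therefore set to the decoupled diagonal limit
#' `-g_floor/kT`, which freezes the potential where the RDF is effectively
#' zero, and the well-sampled block is inverted exactly.
#'
#' @param J_inv matrix from [jacobian_hnc()] (`form = "dudg"`).
#' @param g_tgt,g_k target and current RDF fields (for the average RDF).
#' @param kT thermal energy (kJ/mol).
#' @param g_floor RDF value below which a bin is treated as decoupled.
#' @return matrix with attribute `form = "dgdu"`.
#' @export
invert_hnc_jacobian <- function(J_inv, g_tgt, g_k, kT, g_floor = 1e-8) {
  n_out <- attr(J_inv, "n_out")
  gbar <- gbar_interior(g_tgt, g_k, n_out)
  live <- gbar >= g_floor
  J <- matrix(0, nrow(J_inv), ncol(J_inv))
  if (any(live)) J[live, live] <- solve(J_inv[live, live, drop = FALSE])
  if (any(!live)) diag(J)[!live] <- -g_floor / kT
  attr(J, "form") <- "dgdu"
  attr(J, "interactions") <- attr(J_inv, "interactions")
  attr(J, "n_out") <- n_out
  J
}

#' Diagonal low-density Jacobian (dg/du)
#'
#' The low-density relation `u = -kT ln g` gives the diagonal Jacobian
#' `dg/du = -gbar/kT` with `gbar = (g_tgt + g_k)/2` (the a-Newton form, also
#' used to stabilize the IMC Jacobian in the onset region).
#'
#' @param g_tgt,g_k target and current RDF fields.
#' @param kT thermal energy (kJ/mol).
#' @param n_out interior points per interaction (default `n_cut`).
#' @return diagonal matrix with attribute `form = "dgdu"`.
#' @export
jacobian_lowdensity_diag <- function(g_tgt, g_k, kT, n_out = g_tgt$grid$n_cut) {
  gbar <- gbar_interior(g_tgt, g_k, n_out)
  if (any(gbar < 0)) stop("average RDF is negative")
  J <- diag(-gbar / kT, length(gbar))
  attr(J, "form") <- "dgdu"
  attr(J, "interactions") <- g_tgt$interactions
  attr(J, "n_out") <- n_out
  J
}

#' Accumulate particle-count cross-correlation statistics
#'
#' Means and second moments of the pair-count histogram vectors `S` needed for
#' the IMC Jacobian. The estimator is only valid in the NVT ensemble (a
#' barostat rescales distances and biases the cross-correlations); NpT input
#' is a hard error. The t-IMC shortcut is the same computation applied to
#' reference-ensemble samples.
#'
#' @param samples matrix, one row per frame, columns = (interaction, bin) in
#'   [interaction_labels()] order over interior bins.
#' @param interactions character vector of interaction labels.
#' @param ensemble `"NVT"` (anything else errors).
#' @return object of class `imc_stats` with `mean`, `second_moment`, `cov`,
#'   `n_frames`.
#' @export
imc_stats <- function(samples, interactions, ensemble = "NVT") {
  if (!identical(toupper(ensemble), "NVT"))
    stop("IMC statistics must be sampled in the NVT ensemble; got ", ensemble)
  samples <- as.matrix(samples)
  n_f <- nrow(samples)
  if (n_f < 2L) stop("need at least 2 frames")
  m <- colMeans(samples)
  sm <- crossprod(samples) / n_f
  cv <- sm - tcrossprod(m)
  cv <- (cv + t(cv)) / 2
  structure(list(mean = m, second_moment = sm, cov = cv,
                 n_frames = n_f, interactions = interactions,
                 ensemble = "NVT"),
            class = "imc_stats")
}

#' @export
print.imc_stats <- function(x, ...) {
  cat(sprintf("imc_stats: %d frames, %d bins, interactions: %s\n",
              x$n_frames, length(x$mean), paste(x$interactions, collapse = ", ")))
  invisible(x)
}

#' Write / read IMC statistics as a plain-text matrix file
#'
#' Layout: `#` header lines recording interactions, bin count and frame count,
#' then the mean vector on one line, then the dense second-moment matrix row
#' by row. Allows computing the statistics once and reusing them (t-IMC).
#' @param stats an `imc_stats` object.
#' @param path file path.
#' @export
write_imc_stats <- function(stats, path) {
  p <- length(stats$mean)
  hdr <- c(paste("# interactions:", paste(stats$interactions, collapse = " ")),
           paste("# bins:", p %/% length(stats$interactions)),
           paste("# frames:", stats$n_frames))
  body <- c(paste(sprintf("%.17g", stats$mean), collapse = " "),
            apply(stats$second_moment, 1L,
                  function(rw) paste(sprintf("%.17g", rw), collapse = " ")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_imc_stats
#' @export
read_imc_stats <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  inter <- strsplit(sub("# interactions:\\s*", "", hdr[grepl("interactions:", hdr)]),
                    "\\s+")[[1L]]
  n_f <- as.integer(sub("# frames:\\s*", "", hdr[grepl("frames:", hdr)]))
  m <- as.numeric(strsplit(trimws(body[1L]), "\\s+")[[1L]])
  sm <- do.call(rbind, lapply(body[-1L], function(rw)
    as.numeric(strsplit(trimws(rw), "\\s+")[[1L]])))
  cv <- sm - tcrossprod(m)
  structure(list(mean = m, second_moment = sm, cov = (cv + t(cv)) / 2,
                 n_frames = n_f, interactions = inter, ensemble = "NVT"),
            class = "imc_stats")
}

# expected-count conversion S_ab(r_i) = g_ab(r_i) * 4 pi r_i^2 dr N_a N_b /
# (V (1 + delta_ab)) -- the factor avoiding double counting for like pairs.
s_to_g_factor <- function(comp, grid, interactions, n_out) {
  out <- numeric(0)
  r <- grid$r[1L + seq_len(n_out)]
  for (lab in interactions) {
    ab <- split_pair(lab)
    del <- as.numeric(ab[1] == ab[2])
    fac <- 4 * pi * r^2 * grid$dr *
      comp$counts[[ab[1]]] * comp$counts[[ab[2]]] /
      (comp$volume * (1 + del))
    out <- c(out, fac)
  }
  out
}

#' IMC Jacobian from particle-count statistics
#'
#' The canonical-ensemble identity gives the Jacobian in terms of `S` and `u`
#' as `A = -beta Cov(S)`; converting rows to RDF scale via the `S <-> g`
#' normalization yields `dg/du`.
#'
#' @param stats `imc_stats`.
#' @param comp a [composition()].
#' @param grid a [radial_grid()]; bins are its interior points.
#' @return matrix with attribute `form = "dgdu"`.
#' @export
jacobian_imc <- function(stats, comp, grid) {
  p <- length(stats$mean)
  n_i <- length(stats$interactions)
  n_out <- p %/% n_i
  if (n_out * n_i != p) stop("bin count is not a multiple of interactions")
  beta <- 1 / (k_boltzmann * comp$temperature)
  A <- -beta * stats$cov
  fac <- s_to_g_factor(comp, grid, stats$interactions, n_out)
  J <- A / fac   # row-wise division
  attr(J, "form") <- "dgdu"
  attr(J, "interactions") <- stats$interactions
  attr(J, "n_out") <- n_out
  J
}

#' Onset policy for Jacobian stabilization
#'
#' Two RDF thresholds `t1 < t2` delimiting the interpolation region of the
#' onset stabilization; defaults 0.001 and 0.1. The interpolation exponent is
#' fixed to the square root. `reference` chooses which RDF the thresholds
#' compare against; the default `"min"` (elementwise minimum of target and
#' current) triggers stabilization whenever either curve is in the onset.
#' @param t1,t2 RDF value thresholds, `0 < t1 < t2`.
#' @param reference `"min"`, `"target"`, `"current"` or `"mean"`.
#' @export
onset_policy <- function(t1 = 0.001, t2 = 0.1,
                         reference = c("min", "target", "current", "mean")) {
  if (!(t1 > 0 && t1 < t2)) stop("need 0 < t1 < t2")
  structure(list(t1 = t1, t2 = t2, reference = match.arg(reference)),
            class = "onset_policy")
}

policy_reference <- function(policy, g_tgt, g_k, n_out) {
  a <- flat_interior(g_tgt, n_out)
  b <- flat_interior(g_k, n_out)
  switch(policy$reference,
         min = pmin(a, b), target = a, current = b, mean = (a + b) / 2)
}

#' Stabilize an IMC Jacobian in the RDF onset region
#'
#' Row-wise interpolation between the sampled Jacobian and the diagonal
#' low-density form: rows whose reference RDF value is below `t1` are replaced
#' by the `-gbar/kT` diagonal row; rows at or above `t2` are returned bitwise
#' unchanged; in between the row is `w * J_row + (1 - w) * diag_row` with the
#' square-root weight `w = sqrt((g - t1)/(t2 - t1))` (chosen to compensate the
#' rapid growth of the RDF in the onset).
#'
#' @param J IMC Jacobian (`form = "dgdu"`).
#' @param g_tgt,g_k target and current RDF fields.
#' @param policy an [onset_policy()].
#' @param kT thermal energy (kJ/mol).
#' @export
improve_imc <- function(J, g_tgt, g_k, policy, kT) {
  if (!identical(attr(J, "form"), "dgdu")) stop("J must be a dg/du Jacobian")
  n_out <- attr(J, "n_out")
  gref <- policy_reference(policy, g_tgt, g_k, n_out)
  gbar <- gbar_interior(g_tgt, g_k, n_out)
  for (rw in seq_len(nrow(J))) {
    if (gref[rw] >= policy$t2) next
    w <- if (gref[rw] <= policy$t1) 0
         else sqrt((gref[rw] - policy$t1) / (policy$t2 - policy$t1))
    diag_row <- numeric(ncol(J))
    if (rw <= ncol(J)) diag_row[rw] <- -gbar[rw] / kT
    J[rw, ] <- w * J[rw, ] + (1 - w) * diag_row
  }
  J
}

#' Iterative Boltzmann inversion update
#'
#' The one-line update `du = kT ln(g_k / g_tgt)`, applied pointwise; also the
#' generic update for bonded distributions. Under the onset asymptotics
#' `g = exp(-u/kT) q(r)` with fixed `q` a single IBI update matches the target
#' exactly. Values are computed where both RDFs are positive within the
#' cutoff; nonpositive values there are an error (extrapolate the onset
#' first). The \eqn{r = 0} value copies its neighbour; the update is zero at and
#' beyond the cutoff.
#'
#' @param g_tgt,g_k target and current RDF fields.
#' @param kT thermal energy (kJ/mol).
#' @return a [stacked_field()] of potential updates.
#' @export
ibi_update <- function(g_tgt, g_k, kT) {
  if (!same_grid(g_tgt$grid, g_k$grid)) stop("grids differ")
  n_cut <- g_tgt$grid$n_cut
  du <- stacked_field(g_tgt$grid, g_tgt$types, kind = "potential")
  for (lab in g_tgt$interactions) {
    a <- g_tgt$values[, lab]
    b <- g_k$values[, lab]
    idx <- 1L + seq_len(n_cut)
    if (any(a[idx] <= 0) || any(b[idx] <= 0))
      stop("nonpositive RDF values inside the cutoff for ", lab,
           "; extrapolate the RDF onset first")
    v <- numeric(g_tgt$grid$n_points)
    v[idx] <- kT * log(b[idx] / a[idx])
    v[1L] <- v[2L]
    du$values[, lab] <- v
  }
  du
}
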