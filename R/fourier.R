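# Radially symmetric Fourier transforms via a discrete sine transform.
#
# Convention: h_hat(k) = (4 pi / k) int r h(r) sin(kr) dr, the 3D transform of
# a radially symmetric function. On the paired grids (dk = pi/(n dr)) the
# quadrature is the type-I DST, which is exactly invertible on the interior
# points r > 0; the r = 0 (k = 0) values are reconstructed by analytic limits.

.cgiter_cache <- new.env(parent = emptyenv())

sine_matrix <- function(n) {
  key <- paste0("S", n)
  s <- .cgiter_cache[[key]]
  if (is.null(s)) {
    ij <- outer(seq_len(n - 1L), seq_len(n - 1L))
    s <- sin(pi * ij / n)
    .cgiter_cache[[key]] <- s
  }
  s
}

#' Discrete radial Fourier matrices
#'
#' Returns the forward matrix `F` mapping interior real-space values
#' `h(r_1..r_{n-1})` to `h_hat(k_1..k_{n-1})` and its exact inverse `Finv`.
#' These are the "Fourier matrix" used to conjugate k-space operators into
#' real space.
#' @param grid a [radial_grid()].
#' @return list with `F`, `Finv` ((n-1) x (n-1) matrices).
#' @export
fourier_matrices <- function(grid) {
  n <- grid$n_points
  key <- paste0("F", n, "_", format(grid$dr, digits = 17))
  fm <- .cgiter_cache[[key]]
  if (!is.null(fm)) return(fm)
  S <- sine_matrix(n)
  r <- grid$r[-1L]
  k <- grid$k[-1L]
  Fm <- (4 * pi * grid$dr) * (S * rep(r, each = n - 1L)) / k
  Finv <- (grid$dk / (2 * pi^2)) * (S * rep(k, each = n - 1L)) / r
  fm <- list(F = Fm, Finv = Finv)
  .cgiter_cache[[key]] <- fm
  fm
}

ft_values <- function(values, grid) {
  n <- grid$n_points
  r <- grid$r[-1L]
  h <- values[-1L]
  S <- sine_matrix(n)
  hk <- numeric(n)
  hk[-1L] <- (4 * pi * grid$dr) * as.numeric(S %*% (r * h)) / grid$k[-1L]
  hk[1L] <- 4 * pi * grid$dr * sum(r^2 * h)  # analytic k -> 0 limit
  hk
}

ift_values <- function(values, grid) {
  n <- grid$n_points
  k <- grid$k[-1L]
  hk <- values[-1L]
  S <- sine_matrix(n)
  h <- numeric(n)
  h[-1L] <- (grid$dk / (2 * pi^2)) * as.numeric(S %*% (k * hk)) / grid$r[-1L]
  h[1L] <- (grid$dk / (2 * pi^2)) * sum(k^2 * hk)  # analytic r -> 0 limit
  h
}

#' Radial Fourier transform of a curve
#'
#' Computes `h_hat(k) = (4 pi / k) int r h(r) sin(kr) dr` by the sine-transform
#' quadrature; linear in the input. The `k = 0` element is the analytic limit
#' `4 pi int r^2 h dr`. The input should have decayed near the grid end.
#'
#' @param curve a real-space [cg_curve()].
#' @param grid optional grid; must match the curve's grid if given.
#' @return a k-space `cg_curve` on the conjugate grid.
#' @export
radial_ft <- function(curve, grid = curve$grid) {
  stopifnot(inherits(curve, "cg_curve"))
  if (!same_grid(grid, curve$grid)) stop("grid does not match the curve")
  if (curve$space != "r") stop("radial_ft expects a real-space curve")
  cg_curve(grid, ft_values(curve$values, grid), kind = "correlation", space = "k")
}

#' Inverse radial Fourier transform
#'
#' Exact inverse of [radial_ft()] on the interior points \eqn{r > 0}; the value at
#' \eqn{r = 0} is reconstructed from the analytic limit of `sin(kr)/r`.
#' @param curve a k-space [cg_curve()].
#' @param grid optional grid; must match.
#' @export
radial_ift <- function(curve, grid = curve$grid) {
  stopifnot(inherits(curve, "cg_curve"))
  if (!same_grid(grid, curve$grid)) stop("grid does not match the curve")
  if (curve$space != "k") stop("radial_ift expects a k-space curve")
  cg_curve(grid, ift_values(curve$values, grid), kind = "correlation", space = "r")
}
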