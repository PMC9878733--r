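# RDF onset extrapolation and convergence/noise metrics.

#' Fit window for RDF onset extrapolation
#'
#' The onset of an RDF (where it rises from zero) is poorly sampled; the fit
#' region is delimited by two RDF-value thresholds, and values below the
#' extrapolation threshold are replaced by the fitted curve.
#'
#' @param lower,upper RDF-value thresholds of the fit region,
#'   `0 < lower < upper <= 1`; defaults 0.001 and 0.1.
#' @param threshold extrapolation threshold: values below it are replaced
#'   (default `lower`).
#' @export
onset_fit_window <- function(lower = 0.001, upper = 0.1, threshold = lower) {
  if (!(lower > 0 && lower < upper && upper <= 1))
    stop("need 0 < lower < upper <= 1")
  structure(list(lower = lower, upper = upper, threshold = threshold),
            class = "onset_fit_window")
}

fit_onset_pmf <- function(r, y) {
  # fit y = a exp(-b r) + c; starting values from the endpoint slopes,
  # fallback: log-linear fit of log(y) (c = 0)
  lin <- stats::lm(log(y) ~ r)
  a0 <- exp(stats::coef(lin)[[1L]])
  b0 <- max(-stats::coef(lin)[[2L]], 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b * r) + c,
                      start = list(a = a0, b = b0, c = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    function(x) cf[["a"]] * exp(-cf[["b"]] * x) + cf[["c"]]
  } else {
    function(x) a0 * exp(-b0 * x)
  }
}

#' Extrapolate the RDF onset region
#'
#' In the onset the RDF follows Boltzmann asymptotics, so `-log g` (the PMF in
#' kT units) is fitted with `a exp(-b r) + c` over the well-sampled window
#' where `lower <= g <= upper`, and every value below the extrapolation
#' threshold (zeros included) is replaced by `exp(-f)`. Values above are
#' untouched; the result is strictly positive below the window and continuous
#' at the splice to fit accuracy. Idempotent within fit tolerance.
#'
#' @param g an RDF [cg_curve()] or [stacked_field()] (applied per curve).
#' @param window an [onset_fit_window()].
#' @return the extrapolated object, same class as the input.
#' @export
extrapolate_onset <- function(g, window = onset_fit_window()) {
  if (inherits(g, "stacked_field")) {
    for (lab in g$interactions) {
      cv <- extrapolate_onset(cg_curve(g$grid, g$values[, lab], kind = "rdf"),
                              window)
      g$values[, lab] <- cv$values
    }
    return(g)
  }
  stopifnot(inherits(g, "cg_curve"))
  v <- g$values
  r <- g$grid$r
  i_first <- which(v >= window$lower)[1L]
  if (is.na(i_first)) stop("RDF never reaches the fit window")
  above <- which(v > window$upper)
  i_top <- above[above > i_first][1L]
  if (is.na(i_top)) i_top <- length(v) + 1L
  region <- i_first:(i_top - 1L)
  region <- region[v[region] >= window$lower & v[region] <= window$upper]
  if (length(region) < 4L)
    stop("fewer than 4 points in the onset fit window; widen the thresholds")
  f <- fit_onset_pmf(r[region], -log(v[region]))
  replace <- which(v < window$threshold & seq_along(v) < i_top)
  # floor keeps the result strictly positive even where exp(-f) underflows
  if (length(replace)) v[replace] <- pmax(exp(-f(r[replace])), 1e-250)
  out <- cg_curve(g$grid, v, kind = "rdf")
  attr(out, "onset_fit") <- f
  out
}

chi_sum <- function(diff2_matrix, weight_matrix, dr) {
  sum(diff2_matrix * weight_matrix) * dr
}

#' Potential convergence metric
#'
#' Target-RDF-weighted squared potential difference, summed over all
#' interactions and grid points up to the cutoff:
#' `chi(u) = sum_i sum_r g_tgt (u - u_ref)^2 dr`. Zero iff the potentials
#' agree on the weighted support; quadratic in the difference.
#'
#' @param u,u_ref potential [stacked_field()]s on the same grid.
#' @param g_tgt target RDF field (the weighting).
#' @return scalar (kJ^2 mol^-2 nm).
#' @export
chi_u <- function(u, u_ref, g_tgt) {
  if (!same_grid(u$grid, u_ref$grid) || !same_grid(u$grid, g_tgt$grid))
    stop("grid mismatch between potentials and weighting RDF")
  idx <- 1L + seq_len(u$grid$n_cut)
  chi_sum((u$values[idx, , drop = FALSE] - u_ref$values[idx, , drop = FALSE])^2,
          g_tgt$values[idx, , drop = FALSE], u$grid$dr)
}

#' RDF convergence metric
#'
#' Collective squared RDF mismatch over all interactions up to `r_res`:
#' `chi(g) = sum_i sum_r (g - g_tgt)^2 dr`. Zero iff the RDFs match.
#'
#' @param g,g_tgt RDF fields on the same grid.
#' @return scalar (nm).
#' @export
chi_g <- function(g, g_tgt) {
  if (!same_grid(g$grid, g_tgt$grid)) stop("grid mismatch")
  idx <- 1L + seq_len(g$grid$n_res)
  chi_sum((g$values[idx, , drop = FALSE] - g_tgt$values[idx, , drop = FALSE])^2,
          matrix(1, length(idx), length(g$interactions)), g$grid$dr)
}

#' Noise measure of tabulated curves near the cutoff
#'
#' Per interaction: take the last 20 points to the left of the cutoff, fit a
#' third-degree polynomial, and return the square root of the summed squared
#' residuals; the measure is the average over the interactions. Exactly cubic
#' data give zero; i.i.d. noise of amplitude s gives a value proportional to
#' s, shrinking as the inverse square root of the number of averaged frames.
#'
#' @param curves a [stacked_field()] (RDFs or potential updates).
#' @param n_fit number of pre-cutoff points in the fit (20).
#' @return scalar noise measure.
#' @export
noise_sigma <- function(curves, n_fit = 20L) {
  grid <- curves$grid
  if (grid$n_cut < n_fit)
    stop("fewer than ", n_fit, " points to the left of the cutoff")
  idx <- 1L + ((grid$n_cut - n_fit + 1L):grid$n_cut)  # last n_fit before r_cut
  r <- grid$r[idx]
  vals <- vapply(curves$interactions, function(lab) {
    y <- curves$values[idx, lab]
    fit <- stats::lm(y ~ stats::poly(r, 3))
    sqrt(sum(stats::resid(fit)^2))
  }, numeric(1))
  mean(vals)
}
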