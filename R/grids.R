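# Grids, curves, stacked interaction fields, compositions.

#' Boltzmann constant in kJ/(mol K)
#'
#' Internal unit system: nm, kJ/mol, K. `k_B` converts temperature to thermal
#' energy `kT = k_B * T` in kJ/mol.
#' @export
k_boltzmann <- 0.00831446

# bar per kJ mol^-1 nm^-3 (1e3 J / N_A / 1e-27 m^3 / 1e5 Pa)
.bar_per_kJ_mol_nm3 <- 1e3 / (6.02214076e23 * 1e-27) / 1e5

#' Uniform radial grid with conjugate wave-vector grid
#'
#' Real-space points sit at `r_i = i * dr` for `i = 0 .. n_points - 1`
#' (the grid includes \eqn{r = 0}); midpoints at `(i + 1/2) * dr`. The conjugate
#' wave-vector grid has `k_j = j * dk` with `dk = pi / (n_points * dr)`, which
#' makes the radial sine-transform pair exactly unitary on the interior points.
#'
#' `n_cut` and `n_res` count interior points (`r_1 .. r_n`): the potential is
#' tabulated up to `r_cut = n_cut * dr` and the RDF residual is minimized up to
#' `r_res = n_res * dr >= r_cut`.
#'
#' @param n_points number of grid points including \eqn{r = 0}.
#' @param dr grid spacing in nm.
#' @param r_cut potential cutoff in nm (default: last grid point).
#' @param r_res residual cutoff in nm (default: `r_cut`).
#' @return an object of class `radial_grid`.
#' @export
radial_grid <- function(n_points, dr, r_cut = NULL, r_res = NULL) {
  stopifnot(is.numeric(n_points), length(n_points) == 1L, n_points >= 4,
            is.numeric(dr), length(dr) == 1L, dr > 0)
  n_points <- as.integer(n_points)
  if (is.null(r_cut)) r_cut <- (n_points - 1L) * dr
  if (is.null(r_res)) r_res <- r_cut
  n_cut <- as.integer(floor(r_cut / dr + 1e-9))
  n_res <- as.integer(floor(r_res / dr + 1e-9))
  if (n_cut < 2L) stop("n_cut must be at least 2")
  if (n_res < n_cut) stop("r_res must be >= r_cut")
  if (n_res > n_points - 1L) stop("r_res exceeds the grid extent")
  g <- structure(list(
    n_points = n_points, dr = dr,
    r = (seq_len(n_points) - 1) * dr,
    dk = pi / (n_points * dr),
    k = (seq_len(n_points) - 1) * pi / (n_points * dr),
    n_cut = n_cut, n_res = n_res,
    r_cut = n_cut * dr, r_res = n_res * dr
  ), class = "radial_grid")
  g
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("radial_grid: %d points, dr = %g nm, r_max = %g nm\n",
              x$n_points, x$dr, x$r[x$n_points]))
  cat(sprintf("  r_cut = %g nm (n_cut = %d), r_res = %g nm (n_res = %d), dk = %g nm^-1\n",
              x$r_cut, x$n_cut, x$r_res, x$n_res, x$dk))
  invisible(x)
}

#' Midpoint radii of a grid
#'
#' Returns `(i + 1/2) * dr` for `i = 0 .. n - 1`, the half-shifted points at
#' which forces are evaluated in the discrete virial.
#' @param grid a [radial_grid()].
#' @param n number of midpoints (default `n_cut`).
#' @export
grid_midpoints <- function(grid, n = grid$n_cut) {
  (seq_len(n) - 0.5) * grid$dr
}

same_grid <- function(a, b) {
  a$n_points == b$n_points && isTRUE(all.equal(a$dr, b$dr))
}

#' Tabulated radial curve
#'
#' A single tabulated function on a [radial_grid()] (in real or wave-vector
#' space). `kind` records what the values mean; RDF-kind curves must be
#' nonnegative.
#'
#' @param grid a [radial_grid()].
#' @param values numeric vector of length `n_points`.
#' @param kind one of `"rdf"`, `"potential"`, `"correlation"`, `"distribution"`.
#' @param space `"r"` (default) or `"k"`.
#' @export
cg_curve <- function(grid, values,
                     kind = c("correlation", "rdf", "potential", "distribution"),
                     space = c("r", "k")) {
  kind <- match.arg(kind)
  space <- match.arg(space)
  stopifnot(inherits(grid, "radial_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_points)
    stop("values length does not match the grid")
  if (any(!is.finite(values))) stop("curve values must be finite")
  if (kind == "rdf" && any(values < 0)) stop("rdf values must be nonnegative")
  structure(list(grid = grid, values = values, kind = kind, space = space),
            class = "cg_curve")
}

#' @export
print.cg_curve <- function(x, ...) {
  cat(sprintf("cg_curve (%s, %s-space): %d points, range [%g, %g]\n",
              x$kind, x$space, x$grid$n_points, min(x$values), max(x$values)))
  invisible(x)
}

#' Canonical label of an unordered bead-type pair
#'
#' `(alpha, beta)` and `(beta, alpha)` map to the same label.
#' @param a,b bead type names.
#' @export
pair_label <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

split_pair <- function(label) strsplit(label, "-", fixed = TRUE)[[1L]]

#' All interaction labels of a type set
#'
#' For `n_t` types there are `n_t (n_t + 1) / 2` unordered interactions,
#' ordered lexicographically in the sorted type names with like pairs first
#' within a leading type (`A-A`, `A-B`, `B-B`).
#' @param types character vector of bead type names.
#' @export
interaction_labels <- function(types) {
  types <- sort(unique(types))
  n <- length(types)
  out <- character(0)
  for (i in seq_len(n))
    for (j in i:n)
      out <- c(out, paste(types[i], types[j], sep = "-"))
  out
}

#' Stacked per-interaction field
#'
#' The "u"/"g" vector of the update equations: one curve per unordered
#' interaction, stored as a `n_points x n_i` matrix whose columns follow
#' [interaction_labels()] order. [stack_vector()] flattens the curves to a
#' single vector (columns concatenated) and [unstack_vector()] inverts it.
#'
#' @param grid a [radial_grid()].
#' @param types character vector of bead type names.
#' @param values matrix (`n_points` rows, one column per interaction), a single
#'   value to fill with, or `NULL` for zeros.
#' @param kind curve kind, see [cg_curve()].
#' @export
stacked_field <- function(grid, types, values = NULL, kind = "correlation") {
  labels <- interaction_labels(types)
  n_i <- length(labels)
  if (is.null(values)) values <- 0
  if (length(values) == 1L) values <- matrix(values, grid$n_points, n_i)
  values <- as.matrix(values)
  if (nrow(values) != grid$n_points || ncol(values) != n_i)
    stop("values must be n_points x n_i")
  if (any(!is.finite(values))) stop("stacked_field values must be finite")
  colnames(values) <- labels
  structure(list(grid = grid, types = sort(unique(types)),
                 interactions = labels, values = values, kind = kind),
            class = "stacked_field")
}

#' @export
print.stacked_field <- function(x, ...) {
  cat(sprintf("stacked_field (%s): %d interaction(s) [%s] on %d-point grid\n",
              x$kind, length(x$interactions),
              paste(x$interactions, collapse = ", "), x$grid$n_points))
  invisible(x)
}

#' @rdname stacked_field
#' @param sf a `stacked_field`.
#' @export
stack_vector <- function(sf) as.numeric(sf$values)

#' @rdname stacked_field
#' @param vec flat numeric vector of length `n_points * n_i`.
#' @param template a `stacked_field` providing grid/ordering.
#' @export
unstack_vector <- function(vec, template) {
  stopifnot(length(vec) == length(template$values))
  template$values[] <- vec
  template
}

#' Extract or replace one interaction curve of a stacked field
#' @param sf a [stacked_field()].
#' @param a,b bead type names (order irrelevant).
#' @export
sf_curve <- function(sf, a, b = NULL) {
  lab <- if (is.null(b)) a else pair_label(a, b)
  if (!lab %in% sf$interactions) stop("unknown interaction: ", lab)
  cg_curve(sf$grid, sf$values[, lab], kind = sf$kind)
}

#' @rdname sf_curve
#' @param value numeric vector (length `n_points`) or `cg_curve`.
#' @export
`sf_curve<-` <- function(sf, a, b = NULL, value) {
  lab <- if (is.null(b)) a else pair_label(a, b)
  if (!lab %in% sf$interactions) stop("unknown interaction: ", lab)
  if (inherits(value, "cg_curve")) value <- value$values
  sf$values[, lab] <- value
  sf
}

#' System composition
#'
#' Bead counts, box volume and temperature, with derived number densities
#' `rho_a = N_a / V` (nm^-3) and thermal energy `kT` (kJ/mol).
#'
#' @param counts named numeric vector of bead counts per type.
#' @param volume box volume in nm^3.
#' @param temperature temperature in K.
#' @export
composition <- function(counts, volume, temperature) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by bead type")
  if (any(counts <= 0) || volume <= 0 || temperature <= 0)
    stop("counts, volume and temperature must be positive")
  counts <- counts[order(names(counts))]
  structure(list(counts = counts, volume = volume, temperature = temperature,
                 types = names(counts), rho = counts / volume,
                 kT = k_boltzmann * temperature),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("composition: V = %g nm^3, T = %g K (kT = %g kJ/mol)\n",
              x$volume, x$temperature, x$kT))
  for (t in x$types)
    cat(sprintf("  %s: N = %g, rho = %g nm^-3\n", t, x$counts[[t]], x$rho[[t]]))
  invisible(x)
}
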