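# Table file I/O in the GROMACS tabulated-potential style and
# cubic resampling between grids.

#' Read a tabulated curve from a text file
#'
#' Text tables with `#` comment lines and blank lines allowed. Two dialects:
#' `"distribution"` (columns r, value) and `"potential"` (columns r, value,
#' flag). `"auto"` picks by column count. Values are read at full precision;
#' the r column must be uniformly spaced starting at 0.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"distribution"` or `"potential"`.
#' @param kind curve kind passed to [cg_curve()].
#' @return a [cg_curve()]; comment lines are kept in attribute `"comments"`,
#'   flags (potential dialect) in attribute `"flags"`.
#' @export
read_table <- function(path, dialect = c("auto", "distribution", "potential"),
                       kind = "correlation") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  comments <- character(0)
  r <- numeric(0); v <- numeric(0); fl <- character(0)
  ncol_seen <- NA_integer_
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) { comments <- c(comments, lines[[ln]]); next }
    parts <- strsplit(line, "[[:space:]]+")[[1L]]
    if (length(parts) < 2L)
      stop(sprintf("parse error at line %d of %s: need at least 2 columns", ln, path))
    rv <- suppressWarnings(as.numeric(parts[1:2]))
    if (any(is.na(rv)))
      stop(sprintf("parse error at line %d of %s: non-numeric value", ln, path))
    if (is.na(ncol_seen)) ncol_seen <- length(parts)
    r <- c(r, rv[1L]); v <- c(v, rv[2L])
    fl <- c(fl, if (length(parts) >= 3L) parts[3L] else NA_character_)
  }
  if (length(r) < 4L) stop("table in ", path, " has fewer than 4 rows")
  if (any(diff(r) <= 0))
    stop("parse error in ", path, ": r column is not strictly increasing")
  if (dialect == "auto")
    dialect <- if (!is.na(ncol_seen) && ncol_seen >= 3L) "potential" else "distribution"
  dr <- r[2L] - r[1L]
  if (abs(r[1L]) > 1e-12 * max(dr, 1))
    stop("parse error in ", path, ": grid must start at r = 0")
  if (max(abs(diff(r) - dr)) > 1e-9 * dr)
    stop("parse error in ", path, ": grid spacing is not uniform")
  grid <- radial_grid(length(r), dr)
  if (dialect == "potential" && is.null(kind)) kind <- "potential"
  curve <- cg_curve(grid, v, kind = kind)
  attr(curve, "comments") <- comments
  if (dialect == "potential") attr(curve, "flags") <- fl
  curve
}

#' Write a tabulated curve to a text file
#'
#' Lossless at double precision (`%.17g`). The `"potential"` dialect writes a
#' three-column (r, u, flag) table (flag defaults to `"i"`); the `"gromacs"`
#' dialect additionally resamples to the fixed 0.002 nm grid of the MD engine
#' before writing. Comment lines (attribute `"comments"` or the `comments`
#' argument) are preserved at the top.
#'
#' @param curve a [cg_curve()].
#' @param path output path.
#' @param dialect `"distribution"`, `"potential"` or `"gromacs"`.
#' @param comments character vector of `#` comment lines.
#' @export
write_table <- function(curve, path,
                        dialect = c("potential", "distribution", "gromacs"),
                        comments = attr(curve, "comments")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(curve, "cg_curve"))
  if (dialect == "gromacs") {
    md_dr <- 0.002
    n_new <- floor(curve$grid$r[curve$grid$n_points] / md_dr + 1e-9) + 1L
    new_grid <- radial_grid(n_new, md_dr)
    curve <- resample(curve, new_grid)
    dialect <- "potential"
  }
  lines <- character(0)
  if (length(comments)) {
    cm <- ifelse(startsWith(trimws(comments), "#"), comments, paste("#", comments))
    lines <- c(lines, cm)
  }
  r <- curve$grid$r
  v <- curve$values
  if (dialect == "potential") {
    flags <- attr(curve, "flags")
    if (is.null(flags) || anyNA(flags)) flags <- rep("i", length(r))
    lines <- c(lines, sprintf("%.17g %.17g %s", r, v, flags))
  } else {
    lines <- c(lines, sprintf("%.17g %.17g", r, v))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Resample a curve onto a new grid
#'
#' Cubic interpolation by default (exact for cubic polynomials and at shared
#' nodes); linear optionally. Extrapolation beyond the source support is an
#' error unless `allow_extrapolation = TRUE` (constant continuation).
#'
#' @param curve a [cg_curve()].
#' @param new_grid target [radial_grid()].
#' @param method `"cubic"` or `"linear"`.
#' @param allow_extrapolation allow the new grid to extend past the source.
#' @export
resample <- function(curve, new_grid, method = c("cubic", "linear"),
                     allow_extrapolation = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "cg_curve"), inherits(new_grid, "radial_grid"))
  r_old <- curve$grid$r
  r_new <- new_grid$r
  if (!allow_extrapolation && max(r_new) > max(r_old) + 1e-12)
    stop("new grid extends beyond the source support; ",
         "set allow_extrapolation = TRUE to continue with the end value")
  if (method == "cubic") {
    f <- stats::splinefun(r_old, curve$values, method = "fmm")
    v <- f(pmin(r_new, max(r_old)))
  } else {
    v <- stats::approx(r_old, curve$values, xout = pmin(r_new, max(r_old)),
                       rule = 2)$y
  }
  out <- cg_curve(new_grid, v, kind = curve$kind)
  attr(out, "comments") <- attr(curve, "comments")
  out
}
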