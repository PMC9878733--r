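# Iteration loop: method registry, run configuration, initial guesses,
# single-iteration pipeline (forward evaluate -> extrapolate -> Jacobian ->
# constraints -> solve -> scale -> apply -> shift), and the outer loop with
# the alternating bonded/nonbonded schedule.

#' Parse a method name with prefixes
#'
#' Recognized bases: `ibi`, `hncn`, `hncgn`, `imc`, `imcgn`; prefixes: `t-`
#' (one-time Jacobian from the target), `p-`, `pe-`, `kbi-` (constraints,
#' Gauss-Newton bases only).
#' @param name method string, e.g. `"p-t-hncgn"`.
#' @return list with `base`, `t_variant`, `constraints`.
#' @export
parse_method <- function(name) {
  tokens <- strsplit(tolower(name), "-", fixed = TRUE)[[1L]]
  base <- tokens[length(tokens)]
  prefixes <- tokens[-length(tokens)]
  known <- c("p", "pe", "kbi", "t")
  if (!all(prefixes %in% known))
    stop("unknown method prefix in '", name, "'")
  if (!base %in% c("ibi", "hncn", "hncgn", "imc", "imcgn"))
    stop("unknown method base '", base, "'")
  constraints <- setdiff(prefixes, "t")
  if (length(constraints) && !base %in% c("hncgn", "imcgn"))
    stop("constraints require a Gauss-Newton base (hncgn/imcgn)")
  list(base = base, t_variant = "t" %in% prefixes, constraints = constraints)
}

#' Run configuration
#'
#' Collects everything an iteration run needs: the method name, system
#' definition, stabilization thresholds, weighting, constraint targets,
#' update scaling and iteration budget.
#'
#' @param method method name, see [parse_method()].
#' @param comp a [composition()].
#' @param grid a [radial_grid()] (carries `r_cut`, `r_res`).
#' @param omega `intramolecular_matrix` (default: free single beads).
#' @param onset_window [onset_fit_window()] for RDF extrapolation.
#' @param imc_policy [onset_policy()] for IMC Jacobian stabilization.
#' @param weights `"rdf"` for the default diagonal `r^2/(g_tgt + 1e-30)`,
#'   `"unit"`, or a numeric vector.
#' @param p_tgt,pe_tgt target pressure (bar) / potential energy per count.
#' @param kbi_tgt named vector of target Kirkwood-Buff integrals (nm^3) or
#'   `TRUE` to constrain all interactions to the target-RDF KBIs.
#' @param scale update scaling factor (0.67 damps overshooting updates).
#' @param max_iter number of iterations.
#' @param selection optional [selection()].
#' @param alternate_bonded alternate nonbonded/bonded updates (simultaneous
#'   updates are oscillation-prone).
#' @param extrapolate extrapolate the RDF onset each iteration.
#' @param solver [solver_settings()] for the surrogate forward model.
#' @param rcond singular-value cutoff of the Gauss-Newton least-squares
#'   solve; the closed-loop default 1e-4 suppresses noise amplification
#'   through weakly determined directions.
#' @param seed RNG seed for the run.
#' @export
run_config <- function(method, comp, grid, omega = NULL,
                       onset_window = onset_fit_window(),
                       imc_policy = onset_policy(),
                       weights = "rdf",
                       p_tgt = NULL, pe_tgt = NULL, kbi_tgt = NULL,
                       scale = 1.0, max_iter = 10L, selection = NULL,
                       alternate_bonded = TRUE, extrapolate = TRUE,
                       solver = solver_settings(), rcond = 1e-4, seed = 1L) {
  spec <- parse_method(method)
  if ("p" %in% spec$constraints && is.null(p_tgt))
    stop("p- prefix requires p_tgt")
  if ("pe" %in% spec$constraints && is.null(pe_tgt))
    stop("pe- prefix requires pe_tgt")
  if ("kbi" %in% spec$constraints && is.null(kbi_tgt))
    stop("kbi- prefix requires kbi_tgt")
  structure(list(method = method, spec = spec, comp = comp, grid = grid,
                 omega = omega, onset_window = onset_window,
                 imc_policy = imc_policy, weights = weights,
                 p_tgt = p_tgt, pe_tgt = pe_tgt, kbi_tgt = kbi_tgt,
                 scale = scale, max_iter = as.integer(max_iter),
                 selection = selection, alternate_bonded = alternate_bonded,
                 extrapolate = extrapolate, solver = solver,
                 rcond = rcond, seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: method %s, %d iteration(s), scale %g, seed %d\n",
              x$method, x$max_iter, x$scale, x$seed))
  invisible(x)
}

#' Surrogate forward model factory
#'
#' Wraps [solve_structure()] as the pluggable forward map from potentials to
#' RDFs, warm-starting each call from the previous solution.
#' @param config a [run_config()].
#' @return function `(u, state)` returning `list(g = <stacked_field>)`.
#' @export
surrogate_forward_model <- function(config) {
  env <- new.env(parent = emptyenv())
  env$gamma <- NULL
  function(u, state = NULL) {
    g <- solve_structure(u, config$comp, config$omega,
                         settings = config$solver, gamma_init = env$gamma)
    env$gamma <- attr(g, "gamma")
    list(g = g)
  }
}

#' Initial potential guess from a target RDF
#'
#' `"pmf"`: the Boltzmann inversion `u = -kT ln g` (the low-density limit);
#' `"hnc"`: the hypernetted-chain inversion using the full available RDF
#' length (a much better starting point). Both are cut at `r_cut` and shifted
#' to zero beyond. RDFs must be onset-extrapolated first.
#'
#' @param g_tgt target RDF [stacked_field()].
#' @param comp a [composition()].
#' @param omega `intramolecular_matrix` (default: free single beads).
#' @param method `"hnc"` or `"pmf"`.
#' @param r_cut cutoff (default grid `r_cut`).
#' @return potential [stacked_field()].
#' @export
initial_guess <- function(g_tgt, comp, omega = NULL,
                          method = c("hnc", "pmf"), r_cut = g_tgt$grid$r_cut) {
  method <- match.arg(method)
  if (any(g_tgt$values[-1L, ] <= 0))
    stop("target RDF has zero-valued bins; extrapolate the onset first")
  if (is.null(omega))
    omega <- build_omega(lapply(g_tgt$types, molecule_graph), g_tgt$grid)
  if (method == "pmf") {
    u <- stacked_field(g_tgt$grid, g_tgt$types, kind = "potential")
    for (lab in g_tgt$interactions) {
      v <- -comp$kT * log(g_tgt$values[, lab])
      v[1L] <- 2 * v[2L] - v[3L]
      u$values[, lab] <- v
    }
    return(cut_and_shift(u, r_cut))
  }
  h <- stacked_field(g_tgt$grid, g_tgt$types, g_tgt$values - 1)
  red <- reduce_correlations(h, omega, comp)
  c_sf <- direct_correlation(red, omega, comp)
  hnc_guess(g_tgt, c_sf, comp$kT, r_cut = r_cut)
}

#' Average-of-like-potentials guess for a new cross interaction
#'
#' `u_AB = (u_AA + u_BB)/2`, used when adding one mixed interaction to a
#' model whose like potentials are kept fixed.
#' @param u potential [stacked_field()] containing the like interactions.
#' @param a,b the two bead types.
#' @export
avg_cross_guess <- function(u, a, b) {
  out <- u
  out$values[, pair_label(a, b)] <-
    (u$values[, pair_label(a, a)] + u$values[, pair_label(b, b)]) / 2
  out
}

new_iteration_state <- function(u0, g_tgt, config, u_ref = NULL,
                                u_intra = NULL, p_intra_tgt = NULL) {
  list(k = 0L, u = u0, g = NULL, g_tgt = g_tgt, u_ref = u_ref,
       u_intra = u_intra, p_intra_tgt = p_intra_tgt,
       cache = new.env(parent = emptyenv()),
       history = list(), config = config)
}

build_dcdh_cached <- function(state, config, g_for_dcdh, n_out) {
  cache <- state$cache
  if (config$spec$t_variant && !is.null(cache$dcdh)) return(cache$dcdh)
  h <- stacked_field(g_for_dcdh$grid, g_for_dcdh$types, g_for_dcdh$values - 1)
  omega <- config$omega
  if (is.null(omega))
    omega <- build_omega(lapply(g_for_dcdh$types, molecule_graph),
                         g_for_dcdh$grid)
  red <- reduce_correlations(h, omega, config$comp)
  op <- dcdh_k(red, omega, config$comp)
  dcdh <- suppressWarnings(dcdh_real(op, n_out = n_out))
  cache$n_jacobian_builds <- (cache$n_jacobian_builds %||% 0L) + 1L
  if (config$spec$t_variant) cache$dcdh <- dcdh
  dcdh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_constraints <- function(config, g_k, u_k, J = NULL) {
  cons <- list()
  if ("p" %in% config$spec$constraints)
    cons <- c(cons, list(pressure_constraint(g_k, u_k, config$comp,
                                             config$p_tgt)))
  if ("pe" %in% config$spec$constraints)
    cons <- c(cons, list(pe_constraint(g_k, u_k, config$comp, config$pe_tgt)))
  if ("kbi" %in% config$spec$constraints) {
    tgt <- config$kbi_tgt
    labs <- if (isTRUE(tgt)) g_k$interactions else names(tgt)
    rows <- kbi_constraint(g_k, attr(config, "g_tgt_cache"), J,
                           interactions = labs)
    if (!isTRUE(tgt))
      for (i in seq_along(rows))
        rows[[i]]$rhs <- kirkwood_buff(g_k)[[labs[i]]] - tgt[[labs[i]]]
    cons <- c(cons, rows)
  }
  cons
}

embed_update <- function(du_flat, template, n_cut) {
  du <- stacked_field(template$grid, template$types, kind = "potential")
  n_i <- length(template$interactions)
  for (m in seq_len(n_i)) {
    v <- numeric(template$grid$n_points)
    v[1L + seq_len(n_cut)] <- du_flat[(m - 1L) * n_cut + seq_len(n_cut)]
    v[1L] <- v[2L]
    du$values[, template$interactions[m]] <- v
  }
  du
}

#' One pass of the coarse-graining iteration
#'
#' Forward-evaluates the current potentials, extrapolates the RDF onset,
#' builds (or reuses, for t-variants) the Jacobian, assembles constraint
#' rows, solves for the update, scales and applies it, shifts the potential
#' to zero at the cutoff, and logs metrics. When bonded distribution targets
#' are present and the alternating schedule is on, odd iterations instead
#' apply distribution-IBI to the bonded potentials.
#'
#' @param state iteration state from [run_loop()] internals.
#' @param config a [run_config()].
#' @param forward forward model `(u, state) -> list(g = ..., p_intra = ...,
#'   imc_stats = ...)`.
#' @return updated state.
#' @export
run_iteration <- function(state, config, forward) {
  grid <- config$grid
  kT <- config$comp$kT
  g_tgt <- state$g_tgt
  out <- forward(state$u, state)
  if (!is.list(out) || is.null(out$g))
    stop("forward model failed to return an RDF field; state preserved")
  g_k <- out$g
  if (config$extrapolate)
    g_k <- tryCatch(extrapolate_onset(g_k, config$onset_window),
                    error = function(e) g_k)
  state$g <- g_k
  state$k <- state$k + 1L

  bonded_turn <- !is.null(state$p_intra_tgt) && config$alternate_bonded &&
    (state$k %% 2L == 0L)
  feas <- NA_real_
  if (bonded_turn) {
    for (nm in names(state$p_intra_tgt)) {
      pk <- out$p_intra[[nm]]
      ptgt <- state$p_intra_tgt[[nm]]
      ok <- pk$values > 0 & ptgt$values > 0
      dv <- numeric(length(pk$values))
      dv[ok] <- kT * log(pk$values[ok] / ptgt$values[ok])
      state$u_intra[[nm]]$values <- state$u_intra[[nm]]$values +
        config$scale * dv
    }
  } else {
    base <- config$spec$base
    n_cut <- grid$n_cut
    n_res <- grid$n_res
    if (base == "ibi") {
      du_sf <- ibi_update(g_tgt, g_k, kT)
      state$u$values <- state$u$values + config$scale * du_sf$values
    } else {
      n_used <- if (base == "imc") n_cut else n_res
      residual <- flat_interior(g_tgt, n_used) - flat_interior(g_k, n_used)
      if (base %in% c("hncn", "hncgn")) {
        g_for_d <- if (config$spec$t_variant) g_tgt else g_k
        dcdh <- build_dcdh_cached(state, config, g_for_d, n_used)
        J_inv <- jacobian_hnc(g_tgt, g_k, dcdh, kT)
      } else {
        stats <- out$imc_stats %||% state$cache$imc_stats
        if (is.null(stats))
          stop("IMC methods need particle-count statistics from the forward ",
               "model (imc_stats)")
        if (config$spec$t_variant) state$cache$imc_stats <- stats
        J_imc <- jacobian_imc(stats, config$comp, grid)
        J_imc <- improve_imc(J_imc, g_tgt, g_k, config$imc_policy, kT)
      }
      gbar <- (flat_interior(g_tgt, n_used) + flat_interior(g_k, n_used)) / 2
      dead <- gbar < 1e-8      # bins far below any sampled RDF value
      if (base %in% c("hncn", "imc")) {
        # Newton applies the Jacobian inverse as-is; bins without structural
        # information (deep onset) are frozen.
        J_inv_sq <- if (base == "hncn") J_inv else solve(J_imc)
        du_flat <- config$scale * newton_step(J_inv_sq, residual)
        du_flat[dead] <- 0
        du_sf <- embed_update(du_flat, g_tgt, n_used)
      } else {
        J <- if (base == "hncgn") invert_hnc_jacobian(J_inv, g_tgt, g_k, kT)
             else J_imc
        cmsk <- as.logical(outer(seq_len(n_used) <= n_cut,
                                 rep(TRUE, length(g_tgt$interactions))))
        J <- J[, cmsk, drop = FALSE]
        # freeze potential bins with no structural signal (zero columns ->
        # least-norm solution leaves them untouched)
        J[, dead[cmsk]] <- 0
        attr(J, "interactions") <- g_tgt$interactions
        W <- switch(as.character(config$weights[1L]),
                    rdf = default_weights(g_tgt, n_used),
                    unit = rep(1, length(residual)),
                    as.numeric(config$weights))
        # extrapolated onset bins carry no data: zero residual weight there
        gt_flat <- flat_interior(g_tgt, n_used)
        W[gt_flat < config$onset_window$threshold] <- 0
        attr(config, "g_tgt_cache") <- g_tgt
        cons <- build_constraints(config, g_k, state$u, J = J)
        du_flat <- gauss_newton_step(J, W, residual,
                                     constraints = if (length(cons)) cons,
                                     selection = config$selection,
                                     scale = 1.0, rcond = config$rcond)
        if (length(cons)) {
          cm <- constraints_matrix(cons, length(du_flat))
          feas <- max(abs(cm$K %*% du_flat - cm$d))
        }
        du_flat <- config$scale * du_flat
        du_sf <- embed_update(du_flat, g_tgt, n_cut)
      }
      state$u$values <- state$u$values + du_sf$values
    }
    state$u <- cut_and_shift(state$u, grid$r_cut)
  }

  rec <- list(k = state$k,
              chi_g = chi_g(g_k, g_tgt),
              chi_u = if (!is.null(state$u_ref))
                chi_u(state$u, state$u_ref, g_tgt) else NA_real_,
              pressure = virial_pressure(g_k, state$u, config$comp),
              pe = intermolecular_pe(g_k, state$u, config$comp),
              kbi = kirkwood_buff(g_k),
              constraint_feasibility = feas,
              bonded = bonded_turn)
  state$history <- c(state$history, list(rec))
  state
}

#' Run the full iteration loop
#'
#' Starts from `u_init` (or the HNC initial guess), runs `max_iter`
#' iterations of [run_iteration()], and aborts with a suggestion to scale the
#' update if the RDF metric increases three iterations in a row. With
#' `max_iter = 0` the initial guess is returned untouched. Identical
#' config and seed give bitwise-identical metric history.
#'
#' @param config a [run_config()].
#' @param g_tgt target RDF [stacked_field()] (onset-extrapolated).
#' @param forward forward model (default: the built-in surrogate).
#' @param u_init initial potentials (default: HNC guess from `g_tgt`).
#' @param u_ref optional reference potentials for the chi(u) metric.
#' @param u_intra,p_intra_tgt optional bonded potentials and target
#'   distributions (named lists of [cg_curve()]s) for the alternating
#'   schedule.
#' @param log_path optional path; one JSON record per iteration is appended.
#' @return final state: list with `u`, `g`, `history`, `cache`.
#' @export
run_loop <- function(config, g_tgt, forward = NULL, u_init = NULL,
                     u_ref = NULL, u_intra = NULL, p_intra_tgt = NULL,
                     log_path = NULL) {
  set.seed(config$seed)
  if (is.null(forward)) forward <- surrogate_forward_model(config)
  if (is.null(u_init))
    u_init <- initial_guess(g_tgt, config$comp, config$omega, method = "hnc",
                            r_cut = config$grid$r_cut)
  state <- new_iteration_state(u_init, g_tgt, config, u_ref = u_ref,
                               u_intra = u_intra, p_intra_tgt = p_intra_tgt)
  if (config$max_iter == 0L) return(state)
  rising <- 0L
  for (k in seq_len(config$max_iter)) {
    state <- run_iteration(state, config, forward)
    n_h <- length(state$history)
    if (!is.null(log_path)) {
      rec <- state$history[[n_h]]
      rec$kbi <- as.list(rec$kbi)
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = log_path, append = TRUE)
    }
    if (n_h >= 2L) {
      prev <- state$history[[n_h - 1L]]$chi_g
      best <- min(vapply(state$history, `[[`, numeric(1), "chi_g"))
      chi_now <- state$history[[n_h]]$chi_g
      rising <- if (chi_now > prev && chi_now > 10 * best) rising + 1L else 0L
      if (rising >= 3L)
        stop("chi(g) increased three iterations in a row; the update is ",
             "overshooting - consider scaling the update (e.g. scale = 0.67)")
    }
  }
  state
}

#' Thermodynamic and convergence report
#'
#' Evaluates the property set logged per iteration (pressure, potential
#' energy per count, Kirkwood-Buff integrals, chi metrics) for a given
#' potential/RDF pair.
#' @param g RDF field.
#' @param u potential field.
#' @param comp a [composition()].
#' @param g_tgt optional target RDF for chi(g).
#' @param u_ref optional reference potential for chi(u).
#' @return named list.
#' @export
evaluate_thermo <- function(g, u, comp, g_tgt = NULL, u_ref = NULL) {
  out <- list(pressure_bar = virial_pressure(g, u, comp),
              pe_per_count = intermolecular_pe(g, u, comp),
              kbi_nm3 = kirkwood_buff(g))
  if (!is.null(g_tgt)) out$chi_g <- chi_g(g, g_tgt)
  if (!is.null(u_ref) && !is.null(g_tgt)) out$chi_u <- chi_u(u, u_ref, g_tgt)
  out
}
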