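#' Build an axial-conductance knot profile from cut positions
#'
#' The piecewise-linear `K` profile is parameterized by one knot per cut,
#' placed at the blade distances to the tip (so the cut-and-flow data
#' constrain exactly one knot each). With uniform `k`, `Js*` and `Ps`, nine
#' cuts give the maximal 12-parameter problem.
#'
#' @param cut_positions strictly increasing blade distances to tip, m.
#' @param K_values conductances at the knots, m^4 MPa^-1 s^-1 (recycled if
#'   scalar).
#' @return a `K_knots` data.frame for [transport_params()].
#' @export
make_k_profile <- function(cut_positions, K_values) {
  if (anyDuplicated(cut_positions)) {
    stop("duplicate knot abscissae", call. = FALSE)
  }
  if (is.unsorted(cut_positions, strictly = TRUE)) {
    stop("cut_positions must be strictly increasing", call. = FALSE)
  }
  K_values <- rep_len(K_values, length(cut_positions))
  data.frame(dist = cut_positions, K = K_values)
}

#' First-guess step profile for the axial conductance
#'
#' Step function with `K = 1e-12` below the step and `1e-10` m^4 MPa^-1 s^-1
#' above it, the step positioned at around 0.1 m (adjusted to the abscissae
#' of the cut-and-flow data).
#'
#' @param cut_positions knot abscissae, m.
#' @param step_at step position, m.
#' @param K_min,K_max plateau values, m^4 MPa^-1 s^-1.
#' @return a `K_knots` data.frame.
#' @export
first_guess_k_profile <- function(cut_positions, step_at = 0.1,
                                  K_min = 1e-12, K_max = 1e-10) {
  make_k_profile(cut_positions,
                 ifelse(cut_positions < step_at, K_min, K_max))
}

#' Synthetic axial-conductance profile
#'
#' A tip-to-base increasing conductance profile used as ground truth in
#' simulation studies: log-linear ramp between `K_tip` and `K_base` over the
#' knot abscissae, with optional log-normal jitter; monotonicity is restored
#' after jittering (xylem maturation makes conductance non-decreasing away
#' from the tip).
#'
#' @param knot_dist knot abscissae (distance to tip, m).
#' @param K_tip,K_base conductances near the tip and base,
#'   m^4 MPa^-1 s^-1.
#' @param span distance range of the ramp, m (defaults to the knot range).
#' @param jitter_sd standard deviation of the log-normal jitter.
#' @param seed integer seed.
#' @return a `K_knots` data.frame.
#' @export
synthetic_k_profile <- function(knot_dist, K_tip = 2e-12, K_base = 8e-11,
                                span = range(knot_dist), jitter_sd = 0.15,
                                seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  logK <- stats::approx(span, log(c(K_tip, K_base)), xout = knot_dist,
                        rule = 2)$y
  logK <- logK + stats::rnorm(length(knot_dist), 0, jitter_sd)
  make_k_profile(knot_dist, exp(cummax(logK)))
}

#' Fit configuration
#'
#' Settings of the staged inversion workflow. All positive parameters are
#' optimized in log space (positivity by construction). By default the `K`
#' profile is additionally parameterized through positive log-increments, so
#' candidate profiles are non-decreasing from tip to base; this excludes the
#' sawtooth-shaped exact interpolants of the cut-and-flow data that
#' otherwise trap local optimizers.
#'
#' @param k_guess,Js_guess,Ps_guess first guesses (literature orders of
#'   magnitude for maize seedlings).
#' @param K_step_at,K_min,K_max first-guess profile for `K`: a step at
#'   `K_step_at` when `monotone_K = FALSE`, a log-linear ramp between
#'   `K_min` and `K_max` otherwise.
#' @param monotone_K constrain the fitted profile to be non-decreasing with
#'   distance to tip?
#' @param stage1_maxit,stage2_maxit,stage3_maxit Levenberg-Marquardt
#'   iteration caps of the three stages.
#' @param epsfcn relative step used for the finite-difference Jacobian
#'   (kept well above the solver tolerance so derivative estimates are not
#'   dominated by fixed-point truncation).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(k_guess = 1e-7, Js_guess = 1e-7, Ps_guess = 1e-9,
                       K_step_at = 0.1, K_min = 1e-12, K_max = 1e-10,
                       monotone_K = TRUE,
                       stage1_maxit = 40, stage2_maxit = 30,
                       stage3_maxit = 40, epsfcn = 1e-6) {
  structure(list(k_guess = k_guess, Js_guess = Js_guess, Ps_guess = Ps_guess,
                 K_step_at = K_step_at, K_min = K_min, K_max = K_max,
                 monotone_K = monotone_K,
                 stage1_maxit = stage1_maxit, stage2_maxit = stage2_maxit,
                 stage3_maxit = stage3_maxit, epsfcn = epsfcn),
            class = "fit_config")
}

# cut graphs matching a cut-and-flow series (x = remaining primary length);
# built sequentially, most distal cut first
.cut_graphs <- function(g, cutflow_series, lateral_rule = "stretched") {
  L0 <- g$axes$length[g$axes$order == 0L]
  x <- cutflow_series$x
  graphs <- vector("list", length(x))
  g_cur <- g
  for (i in seq_along(x)) {
    blade <- L0 - x[i]
    if (blade > 1e-9) {
      g_cur <- cut_at_distance(g_cur, blade, lateral_rule = lateral_rule)
    }
    graphs[[i]] <- g_cur
  }
  graphs
}

# forward-simulated flows (ul/s) with per-point warm starting kept in `cache`
.forward_jvp <- function(g, params, bath, steps, control, cache = NULL) {
  vapply(seq_along(steps), function(i) {
    bath_i <- bath_solution(Pe = steps[i], Ce = bath$Ce, w_peg = bath$w_peg,
                            T = bath$T)
    init <- if (!is.null(cache) && length(cache$jvp) >= i) cache$jvp[[i]]
    st <- solve_steady_state(g, params, bath_i, control = control,
                             init = init)
    if (!is.null(cache)) cache$jvp[[i]] <- st
    st$Jv_base_ul
  }, numeric(1))
}

.forward_cutflow <- function(graphs, params, bath, op, control, cache = NULL) {
  bath_op <- bath_solution(Pe = op, Ce = bath$Ce, w_peg = bath$w_peg,
                           T = bath$T)
  vapply(seq_along(graphs), function(i) {
    init <- if (!is.null(cache) && length(cache$cut) >= i) cache$cut[[i]]
    st <- solve_steady_state(graphs[[i]], params, bath_op, control = control,
                             init = init)
    if (!is.null(cache)) cache$cut[[i]] <- st
    st$Jv_base_ul
  }, numeric(1))
}

.new_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$jvp <- list()
  e$cut <- list()
  e
}

#' Least-squares objective of the inverse problem
#'
#' Sum of squared flow errors (ul^2 s^-2) pooled over the Jv(P) and
#' cut-and-flow points. Solver failures at any point yield a large penalty
#' with a warning, which keeps derivative-free optimizers alive.
#'
#' @param params a [transport_params].
#' @param g a `rev_graph` (intact root).
#' @param jvp_series,cutflow_series [experiment_series] objects (either may
#'   be NULL).
#' @param control a [solve_control].
#' @param cut_graphs optionally precomputed [cut_at_distance()] graphs for
#'   the cut-and-flow abscissae (recomputed otherwise).
#' @param penalty value returned on solver failure.
#' @param cache optional warm-start cache (an environment from
#'   `rootflow:::.new_cache()`): successive evaluations at nearby parameters
#'   then reuse each point's previous steady state as the initial iterate.
#' @return the objective F, ul^2 s^-2.
#' @export
objective <- function(params, g, jvp_series = NULL, cutflow_series = NULL,
                      control = solve_control(), cut_graphs = NULL,
                      penalty = 1e6, cache = NULL) {
  res <- tryCatch(
    objective_residuals(params, g, jvp_series, cutflow_series, control,
                        cut_graphs, cache),
    error = function(e) {
      warning("objective: solver failure, returning penalty (",
              conditionMessage(e), ")", call. = FALSE)
      NULL
    })
  if (is.null(res)) return(penalty)
  sum(res$residual^2)
}

#' @rdname objective
#' @return `objective_residuals()` returns a data.frame with one row per
#'   point: `kind`, `x`, `observed`, `fitted`, `residual` (ul s^-1).
#' @export
objective_residuals <- function(params, g, jvp_series = NULL,
                                cutflow_series = NULL,
                                control = solve_control(),
                                cut_graphs = NULL, cache = NULL) {
  out <- list()
  withCallingHandlers({
    if (!is.null(jvp_series)) {
      bath <- attr(jvp_series, "bath")
      sim <- .forward_jvp(g, params, bath, jvp_series$x, control, cache)
      out$jvp <- data.frame(kind = "jvp", x = jvp_series$x,
                            observed = jvp_series$Jv, fitted = sim,
                            residual = jvp_series$Jv - sim)
    }
    if (!is.null(cutflow_series)) {
      bath <- attr(cutflow_series, "bath")
      op <- attr(cutflow_series, "operating_pressure")
      if (is.null(cut_graphs)) cut_graphs <- .cut_graphs(g, cutflow_series)
      sim <- .forward_cutflow(cut_graphs, params, bath, op, control, cache)
      out$cut <- data.frame(kind = "cutflow", x = cutflow_series$x,
                            observed = cutflow_series$Jv, fitted = sim,
                            residual = cutflow_series$Jv - sim)
    }
  }, warning = function(w) invokeRestart("muffleWarning"))
  do.call(rbind, out)
}

# K-profile parameter transform ---------------------------------------------
# monotone: theta = (log K1, log dlogK_2, ..., log dlogK_n); plain: log K.

.K_to_theta <- function(K, monotone) {
  if (!monotone) return(log(K))
  lk <- log(K)
  d <- diff(lk)
  if (any(d <= 0)) {
    # project onto the strictly increasing cone before transforming
    lk <- cummax(lk + seq_along(lk) * 1e-6)
    d <- diff(lk)
  }
  c(lk[1], log(d))
}

.theta_to_K <- function(theta, monotone) {
  if (!monotone) return(exp(theta))
  if (length(theta) == 1L) return(exp(theta))
  exp(theta[1] + c(0, cumsum(exp(theta[-1]))))
}

# osmotic offset of a hydraulic-only fit, from the pressure intercept of the
# linear (high-pressure) part of the Jv(P) data
.estimate_p0 <- function(jvp_series, threshold = 0.1) {
  if (is.null(jvp_series)) return(0)
  sel <- jvp_series$x >= threshold
  if (sum(sel) < 2) sel <- rep(TRUE, nrow(jvp_series))
  co <- stats::coef(stats::lm(Jv ~ x, data = jvp_series[sel, ]))
  if (!is.finite(co[2]) || co[2] == 0) return(0)
  unname(-co[1] / co[2])
}

# first-guess conductance values at the knot abscissae
.initial_K <- function(knot_dist, config) {
  if (length(knot_dist) == 1L) {
    return(sqrt(config$K_min * config$K_max))
  }
  if (config$monotone_K) {
    # log-linear ramp: the monotone analogue of the step first guess
    exp(stats::approx(range(knot_dist), log(c(config$K_min, config$K_max)),
                      xout = knot_dist)$y)
  } else {
    first_guess_k_profile(knot_dist, config$K_step_at,
                          config$K_min, config$K_max)$K
  }
}

# residual-function wrapper that keeps Levenberg-Marquardt alive across
# solver failures
.lm_safe <- function(rfun, n_res, penalty = 1e3) {
  function(theta) {
    r <- tryCatch(rfun(theta), error = function(e) NULL)
    if (is.null(r) || !all(is.finite(r))) rep(penalty, n_res) else r
  }
}

.run_lm <- function(rfun, theta0, n_res, maxiter, epsfcn) {
  f <- .lm_safe(rfun, n_res)
  opt <- withCallingHandlers(
    minpack.lm::nls.lm(theta0, fn = f,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, epsfcn = epsfcn,
                         ftol = 1e-12, ptol = 1e-10)),
    warning = function(w) invokeRestart("muffleWarning"))
  F0 <- sum(f(theta0)^2)
  if (!is.finite(opt$deviance) || opt$deviance > F0) {
    list(par = theta0, F = F0, niter = opt$niter, improved = FALSE)
  } else {
    list(par = opt$par, F = opt$deviance, niter = opt$niter, improved = TRUE)
  }
}

#' Staged inverse estimation of the transport parameters
#'
#' Three-stage weighted least-squares workflow on paired Jv(P) and
#' cut-and-flow series:
#' \enumerate{
#'   \item adjust the `K` profile and `k` on the cut-and-flow data with
#'     solute transport disabled and the osmotic term frozen to a constant
#'     offset estimated from the Jv(P) pressure intercept;
#'   \item keep `K`, adjust `k`, `Js*` and `Ps` on the Jv(P) data with the
#'     full water-solute model;
#'   \item jointly refine all parameters on both series.
#' }
#' Each stage minimizes its sum of squared flow errors by
#' Levenberg-Marquardt on log-transformed parameters (positivity by
#' construction; the `K` profile is non-decreasing tip-to-base by default,
#' see [fit_config()]). A stage that fails or ends above its starting
#' objective is discarded and the previous parameters are kept.
#'
#' @param g a `rev_graph` of the intact root.
#' @param jvp_series,cutflow_series [experiment_series] objects. The normal
#'   mode uses both; a single series is accepted with a warning (degraded
#'   identifiability).
#' @param config a [fit_config].
#' @param control a [solve_control].
#' @return an object of class `fit_result`: fitted [transport_params], the
#'   objective `F` (ul^2 s^-2), pooled `R2`, per-point `residuals`, and a
#'   `stage_trace` data.frame (stage objective and joint objective after
#'   each stage).
#' @export
fit <- function(g, jvp_series = NULL, cutflow_series = NULL,
                config = fit_config(), control = solve_control()) {
  if (is.null(jvp_series) && is.null(cutflow_series)) {
    stop("at least one experiment series is required", call. = FALSE)
  }
  if (is.null(jvp_series) || is.null(cutflow_series)) {
    warning("single-series fit: parameters are only weakly identifiable",
            call. = FALSE)
  }
  L0 <- g$axes$length[g$axes$order == 0L]
  cut_graphs <- if (!is.null(cutflow_series)) .cut_graphs(g, cutflow_series)
  knot_dist <- if (!is.null(cutflow_series)) {
    blades <- L0 - cutflow_series$x
    sort(blades[blades > 1e-9])
  } else {
    c(0.05, 0.15)
  }
  K_start <- .initial_K(knot_dist, config)
  params <- transport_params(k = config$k_guess,
                             K_knots = make_k_profile(knot_dist, K_start),
                             Js_star = config$Js_guess, Ps = config$Ps_guess)
  nk <- length(knot_dist)
  mono <- config$monotone_K
  cache_joint <- .new_cache()
  joint_F <- function(p) {
    objective(p, g, jvp_series, cutflow_series, control, cut_graphs,
              cache = cache_joint)
  }
  trace <- data.frame(stage = character(0), F_stage = numeric(0),
                      F_joint = numeric(0))

  # --- stage 1: K profile and k on cut-and-flow, no solute transport -------
  if (!is.null(cutflow_series)) {
    ctrl1 <- control
    ctrl1$hydraulic_only <- TRUE
    ctrl1$P0 <- .estimate_p0(jvp_series)
    cache1 <- .new_cache()
    r1 <- function(theta) {
      p <- params
      p$k <- exp(theta[1])
      p$K_knots$K <- .theta_to_K(theta[-1], mono)
      p$Js_star <- 0
      p$Ps <- 0
      objective_residuals(p, g, NULL, cutflow_series, ctrl1, cut_graphs,
                          cache1)$residual
    }
    o1 <- .run_lm(r1, c(log(params$k), .K_to_theta(params$K_knots$K, mono)),
                  nrow(cutflow_series), config$stage1_maxit, config$epsfcn)
    params$k <- exp(o1$par[1])
    params$K_knots$K <- .theta_to_K(o1$par[-1], mono)
    trace <- rbind(trace, data.frame(stage = "1: K,k on cut-and-flow",
                                     F_stage = o1$F,
                                     F_joint = joint_F(params)))
  }

  # --- stage 2: k, Js*, Ps on Jv(P), K fixed -------------------------------
  if (!is.null(jvp_series)) {
    cache2 <- .new_cache()
    r2 <- function(theta) {
      p <- params
      p$k <- exp(theta[1])
      p$Js_star <- exp(theta[2])
      p$Ps <- exp(theta[3])
      objective_residuals(p, g, jvp_series, NULL, control, NULL,
                          cache2)$residual
    }
    o2 <- .run_lm(r2, c(log(params$k), log(params$Js_star), log(params$Ps)),
                  nrow(jvp_series), config$stage2_maxit, config$epsfcn)
    params$k <- exp(o2$par[1])
    params$Js_star <- exp(o2$par[2])
    params$Ps <- exp(o2$par[3])
    trace <- rbind(trace, data.frame(stage = "2: k,Js*,Ps on Jv(P)",
                                     F_stage = o2$F,
                                     F_joint = joint_F(params)))
  }

  # --- stage 3: joint refinement of all parameters -------------------------
  n_res <- (if (is.null(jvp_series)) 0 else nrow(jvp_series)) +
    (if (is.null(cutflow_series)) 0 else nrow(cutflow_series))
  cache3 <- .new_cache()
  with_solute <- !is.null(jvp_series)
  r3 <- function(theta) {
    p <- params
    p$k <- exp(theta[1])
    p$K_knots$K <- .theta_to_K(theta[1 + seq_len(nk)], mono)
    if (with_solute) {
      p$Js_star <- exp(theta[nk + 2])
      p$Ps <- exp(theta[nk + 3])
    }
    objective_residuals(p, g, jvp_series, cutflow_series, control,
                        cut_graphs, cache3)$residual
  }
  th0 <- c(log(params$k), .K_to_theta(params$K_knots$K, mono),
           if (with_solute) c(log(params$Js_star), log(params$Ps)))
  o3 <- .run_lm(r3, th0, n_res, config$stage3_maxit, config$epsfcn)
  params$k <- exp(o3$par[1])
  params$K_knots$K <- .theta_to_K(o3$par[1 + seq_len(nk)], mono)
  if (with_solute) {
    params$Js_star <- exp(o3$par[nk + 2])
    params$Ps <- exp(o3$par[nk + 3])
  }
  F_final <- joint_F(params)
  trace <- rbind(trace, data.frame(stage = "3: joint refinement",
                                   F_stage = o3$F, F_joint = F_final))

  quiet <- function(expr) withCallingHandlers(
    expr, warning = function(w) invokeRestart("muffleWarning"))
  res <- quiet(objective_residuals(params, g, jvp_series, cutflow_series,
                                   control, cut_graphs))
  obs <- res$observed
  R2 <- 1 - sum(res$residual^2) / sum((obs - mean(obs))^2)
  structure(list(params = params, F = F_final, R2 = R2, residuals = res,
                 stage_trace = trace),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result: F = %.4g ul^2 s^-2, R2 = %.4f\n", x$F, x$R2))
  print(x$params)
  cat("Stage trace (stage objective / joint objective):\n")
  for (i in seq_len(nrow(x$stage_trace))) {
    cat(sprintf("  %-28s F = %.4g / %.4g\n", x$stage_trace$stage[i],
                x$stage_trace$F_stage[i], x$stage_trace$F_joint[i]))
  }
  invisible(x)
}

#' Pure-hydraulic fit with a constant osmotic offset
#'
#' The simplification used by classical pressure-chamber analyses: the
#' osmotic term is frozen to a constant `P0`, giving the radial law
#' `j = k (P - P0) S`, and `K`, `k`, `P0` are fitted on the linear
#' (high-pressure) part of the Jv(P) data plus the cut-and-flow data. On
#' data produced by the full water-solute model this estimator is biased
#' (notably, `k` is biased low); the function exposes that comparison.
#'
#' @param g a `rev_graph`.
#' @param jvp_series,cutflow_series [experiment_series] objects.
#' @param linear_threshold pressures at or above this (MPa) are treated as
#'   the linear part of the sweep.
#' @param config a [fit_config].
#' @param control a [solve_control].
#' @return a `fit_result` whose element `P0` holds the fitted offset (MPa);
#'   `params` has `Js_star = Ps = 0`.
#' @export
fit_pure_hydraulic <- function(g, jvp_series = NULL, cutflow_series = NULL,
                               linear_threshold = 0.1,
                               config = fit_config(),
                               control = solve_control()) {
  jvp_lin <- if (!is.null(jvp_series)) {
    sel <- jvp_series$x >= linear_threshold
    if (sum(sel) < 2) {
      warning("fewer than 2 points above the linear threshold; using all",
              call. = FALSE)
      jvp_series
    } else {
      experiment_series("jvp", jvp_series$x[sel], jvp_series$Jv[sel],
                        bath = attr(jvp_series, "bath"))
    }
  }
  L0 <- g$axes$length[g$axes$order == 0L]
  cut_graphs <- if (!is.null(cutflow_series)) .cut_graphs(g, cutflow_series)
  knot_dist <- if (!is.null(cutflow_series)) {
    blades <- L0 - cutflow_series$x
    sort(blades[blades > 1e-9])
  } else {
    c(0.05, 0.15)
  }
  K_start <- .initial_K(knot_dist, config)
  params <- transport_params(k = config$k_guess,
                             K_knots = make_k_profile(knot_dist, K_start),
                             Js_star = 0, Ps = 0)
  nk <- length(knot_dist)
  mono <- config$monotone_K
  cache <- .new_cache()
  make_ctrl <- function(P0) {
    ctrl <- control
    ctrl$hydraulic_only <- TRUE
    ctrl$P0 <- P0
    ctrl
  }
  n_res <- (if (is.null(jvp_lin)) 0 else nrow(jvp_lin)) +
    (if (is.null(cutflow_series)) 0 else nrow(cutflow_series))
  rfun <- function(theta) {
    p <- params
    p$k <- exp(theta[1])
    p$K_knots$K <- .theta_to_K(theta[1 + seq_len(nk)], mono)
    objective_residuals(p, g, jvp_lin, cutflow_series,
                        make_ctrl(theta[nk + 2]), cut_graphs,
                        cache)$residual
  }
  th0 <- c(log(params$k), .K_to_theta(params$K_knots$K, mono),
           .estimate_p0(jvp_series, linear_threshold))
  o <- .run_lm(rfun, th0, n_res, config$stage3_maxit, config$epsfcn)
  params$k <- exp(o$par[1])
  params$K_knots$K <- .theta_to_K(o$par[1 + seq_len(nk)], mono)
  P0 <- o$par[nk + 2]
  quiet <- function(expr) withCallingHandlers(
    expr, warning = function(w) invokeRestart("muffleWarning"))
  res <- quiet(objective_residuals(params, g, jvp_lin, cutflow_series,
                                   make_ctrl(P0), cut_graphs))
  R2 <- 1 - sum(res$residual^2) / sum((res$observed - mean(res$observed))^2)
  structure(list(params = params, P0 = P0, F = sum(res$residual^2), R2 = R2,
                 residuals = res,
                 stage_trace = data.frame(stage = "pure hydraulic",
                                          F_stage = sum(res$residual^2),
                                          F_joint = sum(res$residual^2))),
            class = "fit_result")
}

#' Sensitivity of the fitted radial conductivity to the solute parameters
#'
#' Re-fits `k` alone on the Jv(P) data over a grid of `Js*` and `Ps`
#' multipliers around the best fit, and reports the multiplicative range of
#' each solute parameter that keeps `k` within 10% of its best-fit value.
#' Optionally repeats the `k` re-fit for alternative reflection
#' coefficients.
#'
#' @param g a `rev_graph`.
#' @param jvp_series an [experiment_series] of kind `"jvp"`.
#' @param params_best best-fit [transport_params].
#' @param js_factors,ps_factors multiplicative grids (applied one at a time,
#'   the other parameter held at its best-fit value).
#' @param sigmas optional reflection coefficients to re-fit `k` under.
#' @param control a [solve_control].
#' @return list with `scan` (data.frame: parameter, factor, k, F),
#'   `band_js`, `band_ps` (factor ranges keeping `k` within 10%), and
#'   optionally `sigma_refits`.
#' @export
sensitivity_scan <- function(g, jvp_series, params_best,
                             js_factors = 10^seq(-2, 1, by = 0.5),
                             ps_factors = 10^seq(-2, 1, by = 0.5),
                             sigmas = NULL, control = solve_control()) {
  cache_s <- .new_cache()
  refit_k <- function(p) {
    f <- function(lk) {
      p$k <- exp(lk)
      objective(p, g, jvp_series, NULL, control, cache = cache_s)
    }
    opt <- stats::optimize(f, interval = log(params_best$k) + c(-4, 4))
    c(k = exp(opt$minimum), F = opt$objective)
  }
  rows <- list()
  for (fac in js_factors) {
    p <- params_best; p$Js_star <- params_best$Js_star * fac
    r <- refit_k(p)
    rows[[length(rows) + 1L]] <- data.frame(parameter = "Js_star",
                                            factor = fac, k = r[["k"]],
                                            F = r[["F"]])
  }
  for (fac in ps_factors) {
    p <- params_best; p$Ps <- params_best$Ps * fac
    r <- refit_k(p)
    rows[[length(rows) + 1L]] <- data.frame(parameter = "Ps", factor = fac,
                                            k = r[["k"]], F = r[["F"]])
  }
  scan <- do.call(rbind, rows)
  k0 <- refit_k(params_best)[["k"]]
  in_band <- function(par) {
    s <- scan[scan$parameter == par, ]
    ok <- abs(s$k / k0 - 1) <= 0.1
    if (!any(ok)) return(c(NA_real_, NA_real_))
    range(s$factor[ok])
  }
  out <- list(scan = scan, k0 = k0, band_js = in_band("Js_star"),
              band_ps = in_band("Ps"))
  if (!is.null(sigmas)) {
    out$sigma_refits <- do.call(rbind, lapply(sigmas, function(s) {
      p <- params_best; p$sigma <- s
      r <- refit_k(p)
      data.frame(sigma = s, k = r[["k"]], F = r[["F"]])
    }))
  }
  out
}
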