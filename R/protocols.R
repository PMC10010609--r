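#' Pressure-chamber experiment series
#'
#' A measured or simulated protocol curve: either a pressure sweep (`jvp`,
#' `x` = applied relative pressure in MPa) or a cut-and-flow series
#' (`cutflow`, `x` = remaining primary length in m, first point = intact
#' root). Flows are in ul s^-1, as recorded by the flowmeter.
#'
#' @param kind `"jvp"` or `"cutflow"`.
#' @param x abscissae (MPa or m).
#' @param Jv sap flows, ul s^-1.
#' @param bath the [bath_solution] of the experiment.
#' @param operating_pressure constant chamber pressure of a cut-and-flow
#'   series, MPa.
#' @return a data.frame of class `experiment_series` with columns `x`, `Jv`
#'   and attributes `kind`, `bath`, `operating_pressure`.
#' @export
experiment_series <- function(kind = c("jvp", "cutflow"), x, Jv, bath = NULL,
                              operating_pressure = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(Jv))
  if (kind == "jvp" && any(x < 0)) {
    stop("jvp pressures must be >= 0 (relative)", call. = FALSE)
  }
  out <- data.frame(x = x, Jv = Jv)
  attr(out, "kind") <- kind
  attr(out, "bath") <- bath
  attr(out, "operating_pressure") <- operating_pressure
  class(out) <- c("experiment_series", "data.frame")
  out
}

#' Typical pressure-step sequence of a Jv(P) measurement
#'
#' The successive relative pressures (MPa) applied in a standard sweep,
#' alternating up and down to probe hysteresis.
#'
#' @return numeric vector of pressures, MPa.
#' @export
default_pressure_steps <- function() {
  c(0.00, 0.05, 0.15, 0.10, 0.25, 0.20, 0.35, 0.30, 0.45, 0.50, 0.25, 0.00)
}

#' Simulate a Jv(P) pressure sweep
#'
#' One steady-state solve per pressure step (flows are assumed stable at
#' each step, as observed experimentally). The first solve starts cold;
#' subsequent steps are warm-started from the previous state.
#'
#' @param g a `rev_graph`.
#' @param params a [transport_params].
#' @param bath a [bath_solution] (its `Pe` is overridden by each step).
#' @param pressure_steps applied relative pressures, MPa (at least 4, the
#'   minimum usable protocol).
#' @param control a [solve_control].
#' @return an [experiment_series] of kind `"jvp"`.
#' @export
simulate_jvp <- function(g, params, bath,
                         pressure_steps = default_pressure_steps(),
                         control = solve_control()) {
  if (length(pressure_steps) < 4) {
    stop("a usable Jv(P) protocol has at least 4 pressure steps", call. = FALSE)
  }
  state <- NULL
  Jv <- numeric(length(pressure_steps))
  for (i in seq_along(pressure_steps)) {
    bath_i <- bath_solution(Pe = pressure_steps[i], Ce = bath$Ce,
                            w_peg = bath$w_peg, T = bath$T)
    state <- solve_steady_state(g, params, bath_i, control = control,
                                init = state)
    Jv[i] <- state$Jv_base_ul
  }
  experiment_series("jvp", x = pressure_steps, Jv = Jv, bath = bath)
}

#' Simulate a cut-and-flow experiment
#'
#' The flow of the intact root is recorded at the operating pressure, then
#' the root is cut at successive blade positions (distances to the original
#' primary tip) and the steady flow re-recorded after each cut, with the
#' open-cut-face boundary condition active. In a PEG bath, PEG intrusion
#' through the cut faces and the resulting local viscosity increase are
#' fully coupled.
#'
#' @param g a `rev_graph` (the intact root).
#' @param params a [transport_params].
#' @param bath a [bath_solution].
#' @param cut_positions strictly increasing blade distances to the original
#'   primary tip, m (default: [default_cut_schedule()]).
#' @param operating_pressure constant chamber pressure, MPa. Defaults to the
#'   experimental protocol: 0.3 MPa in a PEG bath, 0.2 MPa otherwise.
#' @param control a [solve_control].
#' @param lateral_rule passed to [cut_at_distance()].
#' @return an [experiment_series] of kind `"cutflow"` whose `x` column is
#'   the remaining primary length (m); the first point is the intact root.
#' @export
simulate_cut_and_flow <- function(g, params, bath, cut_positions = NULL,
                                  operating_pressure = NULL,
                                  control = solve_control(),
                                  lateral_rule = "stretched") {
  L0 <- g$axes$length[g$axes$order == 0L]
  if (is.null(cut_positions)) cut_positions <- default_cut_schedule(L0)
  if (is.unsorted(cut_positions, strictly = TRUE)) {
    stop("cut_positions must be strictly increasing blade distances to tip",
         call. = FALSE)
  }
  if (is.null(operating_pressure)) {
    operating_pressure <- if (bath$w_peg > 0) 0.3 else 0.2
  }
  bath_op <- bath_solution(Pe = operating_pressure, Ce = bath$Ce,
                           w_peg = bath$w_peg, T = bath$T)
  n_pt <- length(cut_positions) + 1L
  Jv <- numeric(n_pt)
  x <- c(L0, L0 - cut_positions)
  st <- solve_steady_state(g, params, bath_op, control = control)
  Jv[1] <- st$Jv_base_ul
  g_cur <- g
  for (i in seq_along(cut_positions)) {
    g_cur <- cut_at_distance(g_cur, cut_positions[i],
                             lateral_rule = lateral_rule)
    st <- solve_steady_state(g_cur, params, bath_op, control = control)
    Jv[i + 1L] <- st$Jv_base_ul
  }
  experiment_series("cutflow", x = x, Jv = Jv, bath = bath,
                    operating_pressure = operating_pressure)
}

#' Gap to linearity of a pressure-flow curve
#'
#' Pressures and flows are min-max normalized to \[0, 1\] (so roots with
#' very different absolute flows can be compared) and the gap is the maximal
#' residual between the normalized curve and the bisector. 0 for an exactly
#' linear series; invariant under affine rescaling of either axis.
#'
#' @param series an [experiment_series] (or any data.frame with `x`, `Jv`).
#' @return the gap, dimensionless in \[0, 1\].
#' @export
linearity_gap <- function(series) {
  x <- series$x
  Jv <- series$Jv
  if (length(unique(x)) < 3) {
    stop("linearity gap needs at least 3 distinct abscissae", call. = FALSE)
  }
  if (diff(range(Jv)) == 0) {
    stop("linearity gap undefined for a constant flow series", call. = FALSE)
  }
  xn <- (x - min(x)) / diff(range(x))
  yn <- (Jv - min(Jv)) / diff(range(Jv))
  max(abs(yn - xn))
}

#' Add reproducible measurement noise to a series
#'
#' Gaussian perturbation of the flows, absolute (ul s^-1) or multiplicative.
#'
#' @param series an [experiment_series].
#' @param noise_sd standard deviation: ul s^-1 if `relative = FALSE`, a
#'   fraction of each flow otherwise.
#' @param relative multiplicative noise?
#' @param seed integer seed (the caller's RNG state is left untouched).
#' @return the perturbed series.
#' @export
add_measurement_noise <- function(series, noise_sd, relative = FALSE,
                                  seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  eps <- stats::rnorm(nrow(series))
  series$Jv <- if (relative) {
    series$Jv * (1 + noise_sd * eps)
  } else {
    series$Jv + noise_sd * eps
  }
  series
}
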