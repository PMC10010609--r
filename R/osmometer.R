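#' Two-compartment osmometer model of a root
#'
#' The classical representation of the whole root as one semi-permeable
#' barrier of area `S_tot` separating the bath from a well-mixed xylem
#' compartment at relative pressure 0. It closes the same radial water and
#' solute fluxes as the architecture model, so its exact solution serves as
#' an oracle for the tree solver and as the reference for quantifying the
#' bias of ignoring architecture.
#'
#' @param S_tot total exchange surface, m^2.
#' @param params a [transport_params] (the `K_knots` profile is ignored:
#'   the compartment model has no axial resistance).
#' @param bath a [bath_solution]. PEG appears only through the external
#'   osmotic term: a compartment model has no cut faces for PEG to enter.
#' @return an object of class `osmometer_model`.
#' @export
osmometer_model <- function(S_tot, params, bath) {
  stopifnot(S_tot > 0, inherits(params, "transport_params"),
            inherits(bath, "bath_solution"))
  structure(list(S_tot = S_tot, params = params, bath = bath),
            class = "osmometer_model")
}

#' Closed-form steady state of the osmometer
#'
#' Solves the coupled pair
#' `Jv = k S (Pe - pi_peg_ext - sigma R T (Ce - C))` and
#' `Jv C = S (Js* - Ps (C - Ce))`
#' for the homogeneous interior concentration `C` and the sap outflow `Jv`.
#' Eliminating `Jv` yields a quadratic in `C` whose coefficients have a
#' single sign change, so exactly one root is non-negative; that root is
#' selected, making `Jv(Pe)` continuous and non-decreasing.
#'
#' At the zero-flow point `C - Ce = Js*/Ps` and the pressure offset is
#' `Pe = pi_peg_ext - sigma R T Js*/Ps`; at large `Pe` the interior solute is
#' fully diluted and the slope approaches `k S`.
#'
#' @param m an [osmometer_model].
#' @param Pe applied relative pressure(s), MPa (overrides the bath value).
#' @return data.frame with columns `Pe` (MPa), `Jv_ul` (ul s^-1), `Jv`
#'   (m^3 s^-1) and `C` (mol m^-3).
#' @export
osmometer_steady_state <- function(m, Pe = m$bath$Pe) {
  p <- m$params
  S <- m$S_tot
  RT <- rt_mpa(p$T)
  out <- vapply(Pe, function(pe) {
    A <- pe - m$bath$pi_peg - p$sigma * RT * m$bath$Ce
    src <- p$Js_star + p$Ps * m$bath$Ce
    if (p$sigma > 0) {
      a <- p$k * p$sigma * RT
      bq <- p$k * A + p$Ps
      disc <- bq^2 + 4 * a * src
      C <- (-bq + sqrt(disc)) / (2 * a)
    } else {
      den <- p$k * A + p$Ps
      if (den <= 0 && src > 0) {
        stop("osmometer has no non-negative steady concentration", call. = FALSE)
      }
      C <- if (src == 0) 0 else src / den
    }
    if (C < 0) C <- 0
    Jv <- p$k * S * (A + p$sigma * RT * C)
    c(Jv, C)
  }, numeric(2))
  data.frame(Pe = Pe, Jv_ul = out[1, ] * 1e9, Jv = out[1, ], C = out[2, ])
}

#' Compare the architecture solution with its osmometer reduction
#'
#' Simulates a pressure sweep on the full architecture, fits the osmometer
#' (same total surface, same `sigma` and temperature) to those flows by
#' least squares on `(k, Js*, Ps)` in log space, and reports the relative
#' deviation of each fitted parameter from the architecture's true value,
#' together with the base-to-tip solute concentration gradient of the
#' architecture solution (per meter of primary axis), the homogeneity
#' metric that explains when the reduction is biased.
#'
#' @param g a `rev_graph`.
#' @param params a [transport_params] (truth for the architecture model).
#' @param bath a [bath_solution].
#' @param pressure_grid applied pressures, MPa.
#' @param control a [solve_control].
#' @return list with `fit` (fitted osmometer parameters), `deviation`
#'   (named relative deviations, e.g. `(k_fit - k)/k`), `gradient_C`
#'   (mol m^-4), and the two `Jv` curves.
#' @export
compare_with_rsa <- function(g, params, bath,
                             pressure_grid = seq(0, 0.5, by = 0.1),
                             control = solve_control()) {
  S_tot <- sum(g$nodes$surface)
  series <- simulate_jvp(g, params, bath, pressure_steps = pressure_grid,
                         control = control)
  Jv_rsa <- series$Jv

  obj <- function(theta) {
    p2 <- params
    p2$k <- exp(theta[1]); p2$Js_star <- exp(theta[2]); p2$Ps <- exp(theta[3])
    m <- osmometer_model(S_tot, p2, bath)
    sum((osmometer_steady_state(m, pressure_grid)$Jv_ul - Jv_rsa)^2)
  }
  start <- log(c(params$k, params$Js_star, params$Ps))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  fit <- c(k = exp(opt$par[1]), Js_star = exp(opt$par[2]),
           Ps = exp(opt$par[3]))
  truth <- c(k = params$k, Js_star = params$Js_star, Ps = params$Ps)
  deviation <- (fit - truth) / truth

  # homogeneity metric at the middle of the pressure grid
  bath_mid <- bath_solution(Pe = stats::median(pressure_grid), Ce = bath$Ce,
                            w_peg = bath$w_peg, T = bath$T)
  st <- solve_steady_state(g, params, bath_mid, control = control)
  prim <- g$nodes$order == 0L
  base_row <- which(prim)[which.max(g$nodes$dist_tip[which(prim)])]
  tip_row <- which(prim)[which.min(g$nodes$dist_tip[which(prim)])]
  Lp <- g$axes$length[g$axes$order == 0L]
  # sap flow dilutes the xylem toward the base, so the tip is the
  # concentrated end; report the tip-to-base drop per meter of primary
  gradient_C <- (st$C[tip_row] - st$C[base_row]) / Lp

  list(fit = fit, deviation = deviation, F = opt$value,
       gradient_C = gradient_C,
       Jv_rsa = Jv_rsa,
       Jv_osmometer = osmometer_steady_state(
         osmometer_model(S_tot, {
           p2 <- params; p2$k <- fit[["k"]]; p2$Js_star <- fit[["Js_star"]]
           p2$Ps <- fit[["Ps"]]; p2
         }, bath), pressure_grid)$Jv_ul,
       pressure_grid = pressure_grid)
}
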