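#' Physical constants
#'
#' Gas constant and the derived osmotic conversion factor used throughout the
#' package. Internally all pressures are in MPa and concentrations in
#' mol m^-3, so `RT` is expressed in MPa per (mol m^-3).
#'
#' @param T temperature in K (default 298).
#' @return `rt_mpa()` returns R*T*1e-6, i.e. MPa per mol m^-3.
#' @examples
#' rt_mpa(298)  # 2.4776e-3
#' @export
rt_mpa <- function(T = 298) {
  GAS_CONSTANT * T * 1e-6
}

#' @rdname rt_mpa
#' @format Gas constant, 8.314 J mol^-1 K^-1.
#' @export
GAS_CONSTANT <- 8.314

#' Bathing-solution state
#'
#' The external medium seen by the root in the pressure chamber: relative
#' hydrostatic pressure, lumped nutrient solute concentration, PEG 8000 mass
#' concentration and temperature. The default solute concentration (13.72
#' mol m^-3) reproduces, through the Van't Hoff term at 298 K, the measured
#' osmotic potential of the control hydroponic solution (-0.034 MPa).
#'
#' @param Pe relative hydrostatic pressure of the bath, MPa (0 = atmospheric).
#' @param Ce lumped solute concentration, mol m^-3.
#' @param w_peg PEG mass concentration, kg l^-1 (0.150 for the water-deficit
#'   medium).
#' @param T temperature, K.
#' @return an object of class `bath_solution`.
#' @examples
#' bath_solution()                    # control medium, atmospheric pressure
#' bath_solution(Pe = 0.3, w_peg = 0.15)  # pressurized PEG medium
#' @export
bath_solution <- function(Pe = 0, Ce = 13.72, w_peg = 0, T = 298) {
  stopifnot(is.numeric(Pe), length(Pe) == 1L, is.finite(Pe))
  if (Ce < 0) stop("Ce must be >= 0", call. = FALSE)
  if (w_peg < 0) stop("w_peg must be >= 0", call. = FALSE)
  if (T <= 0) stop("T must be positive (K)", call. = FALSE)
  structure(
    list(Pe = Pe, Ce = Ce, w_peg = w_peg, T = T,
         pi_peg = -peg_water_potential(w_peg, T)),
    class = "bath_solution"
  )
}

#' @export
print.bath_solution <- function(x, ...) {
  cat("Bathing solution:\n")
  cat(sprintf("  Pe     = %g MPa (relative)\n", x$Pe))
  cat(sprintf("  Ce     = %g mol m^-3\n", x$Ce))
  cat(sprintf("  w_peg  = %g kg l^-1 (pi_peg = %.4f MPa)\n", x$w_peg, x$pi_peg))
  cat(sprintf("  T      = %g K\n", x$T))
  invisible(x)
}

#' Dynamic viscosity of a PEG 8000 solution
#'
#' Exponential law fitted on published viscosimetry of PEG 8000 solutions
#' between 100 and 200 g l^-1, anchored at pure water (1 mPa s):
#' `mu(w) = -17.4 + 18.4 * exp(w / 0.279)` with `w` in kg l^-1.
#' A 150 g l^-1 solution is 14 times more viscous than water, which is why
#' PEG intrusion into cut xylem vessels must be tracked during cut-and-flow
#' simulations.
#'
#' @param w_peg PEG mass concentration, kg l^-1. The fit is valid on
#'   \[0, 0.25\]; larger values extrapolate with a warning.
#' @return dynamic viscosity in mPa s.
#' @examples
#' peg_viscosity(0)      # 1.0
#' peg_viscosity(0.150)  # 14.1
#' @export
peg_viscosity <- function(w_peg) {
  if (any(w_peg < 0)) stop("w_peg must be >= 0", call. = FALSE)
  if (any(w_peg > 0.25)) {
    warning("peg_viscosity: extrapolating beyond fitted range (w_peg > 0.25 kg/l)",
            call. = FALSE)
  }
  .peg_viscosity(w_peg)
}

# internal, no range policing: used inside solver iterations
.peg_viscosity <- function(w_peg) {
  -17.4 + 18.4 * exp(w_peg / 0.279)
}

#' Water potential of a PEG 8000 solution
#'
#' PEG solutions do not follow Van't Hoff's law; their water potential is
#' described by an empirical calibration quadratic in concentration and
#' linear in temperature,
#' `Psi_MPa = 0.1 * (1.29 w^2 Tc - 140 w^2 - 4.0 w)`,
#' with `Tc` the temperature in degrees Celsius and `w` the PEG mass per mass
#' of water (numerically identified with the kg l^-1 concentration at these
#' dilutions). At 150 g l^-1 and 25 C this gives -0.302 MPa; added to the
#' control-solution potential of -0.034 MPa it yields the -0.336 MPa
#' water-deficit medium.
#'
#' @param w_peg PEG mass concentration, kg l^-1 (>= 0).
#' @param T temperature, K.
#' @return water potential Psi_peg in MPa (<= 0). The osmotic pressure is
#'   `pi_peg = -Psi_peg`.
#' @examples
#' peg_water_potential(0)              # 0
#' peg_water_potential(0.150, 298.15)  # -0.302
#' @export
peg_water_potential <- function(w_peg, T = 298) {
  if (any(w_peg < 0)) stop("w_peg must be >= 0", call. = FALSE)
  Tc <- T - 273.15
  # bar -> MPa factor 0.1
  0.1 * (1.29 * w_peg^2 * Tc - 140 * w_peg^2 - 4.0 * w_peg)
}

#' Van't Hoff osmotic pressure term
#'
#' Osmotic driving pressure `sigma * R * T * C_diff` for the lumped permeant
#' solute, in MPa.
#'
#' @param C_diff concentration difference, mol m^-3.
#' @param sigma effective reflection coefficient in \[0, 1\].
#' @param T temperature, K.
#' @return pressure in MPa.
#' @examples
#' vant_hoff_term(40, sigma = 0.85)  # 0.08424
#' @export
vant_hoff_term <- function(C_diff, sigma = 0.85, T = 298) {
  if (sigma < 0 || sigma > 1) stop("sigma must lie in [0, 1]", call. = FALSE)
  sigma * rt_mpa(T) * C_diff
}

#' Hagen-Poiseuille conductance of a cylindrical capillary
#'
#' Reference axial conductance `K = pi r^4 / (8 mu)` expressed in
#' m^4 MPa^-1 s^-1 so that `mu` enters in mPa s (reference sap viscosity 1).
#' Conductance scales with the fourth power of the radius and inversely with
#' viscosity: a capillary filled with 150 g l^-1 PEG solution conducts 14
#' times less than the same capillary filled with water.
#'
#' @param r capillary radius, m.
#' @param mu dynamic viscosity, mPa s.
#' @return conductance, m^4 MPa^-1 s^-1.
#' @examples
#' capillary_conductance(1e-5)  # 3.93e-12
#' @export
capillary_conductance <- function(r, mu = 1) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  pi * r^4 * 1e9 / (8 * mu)
}
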