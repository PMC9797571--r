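# Closed-form fracture-mechanics estimates for enamel cracks: stress
# concentration at an elliptical flaw, theoretical strength, critical
# stress from the fracture-toughness criterion (linear and elliptical
# crack fronts), the Griffith energy form, and the bite-pressure ratio.
# SI units (Pa, m, J/m^2) are used internally; fracture toughness is
# accepted in MPa*sqrt(m) at the interface and converted.

#' Reference material constants for dental enamel
#'
#' Fracture toughness of enamel is anisotropic: K_Ic = 1.24 MPa*sqrt(m)
#' perpendicular to the hydroxyapatite crystallites and 0.70 MPa*sqrt(m)
#' in-plane. Young's modulus, surface energy and the intra-atomic plane
#' distance have no universally agreed enamel values and stay user inputs.
#'
#' @param K_Ic_perp_MPa_sqrt_m Perpendicular fracture toughness.
#' @param K_Ic_par_MPa_sqrt_m In-plane fracture toughness.
#' @param E_Pa Young's modulus (Pa).
#' @param gamma_J_m2 Surface energy per area (J/m^2).
#' @param a0_m Intra-atomic plane distance (m).
#' @return List of class `material_constants`.
#' @export
material_constants <- function(K_Ic_perp_MPa_sqrt_m = 1.24,
                               K_Ic_par_MPa_sqrt_m = 0.70,
                               E_Pa = 100e9,
                               gamma_J_m2 = 1,
                               a0_m = 3e-10) {
  vals <- c(K_Ic_perp_MPa_sqrt_m, K_Ic_par_MPa_sqrt_m, E_Pa, gamma_J_m2, a0_m)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("material_constants: all constants must be positive")
  structure(list(K_Ic_perp_MPa_sqrt_m = K_Ic_perp_MPa_sqrt_m,
                 K_Ic_par_MPa_sqrt_m = K_Ic_par_MPa_sqrt_m,
                 E_Pa = E_Pa, gamma_J_m2 = gamma_J_m2, a0_m = a0_m),
            class = "material_constants")
}

check_pos <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("fracture mechanics inputs must be positive and finite")
  invisible(v)
}

#' Stress concentration at a pre-existing elliptical crack
#'
#' `sigma_max = 2 * sigma * sqrt(l_c / l_rho)` for a pre-existing crack of
#' half-length `l_c` and tip curvature `l_rho` under applied stress `sigma`.
#'
#' @param sigma Applied stress (Pa).
#' @param l_c Crack half-length (m).
#' @param l_rho Tip curvature radius (m).
#' @return Maximum stress at the tip (Pa).
#' @export
#' @examples
#' stress_concentration(1, 4, 1) # 2 * sqrt(4) = 4
stress_concentration <- function(sigma, l_c, l_rho) {
  check_pos(sigma, l_c, l_rho)
  2 * sigma * sqrt(l_c / l_rho)
}

#' Theoretical strength of a flawless solid
#'
#' `sigma_th = sqrt(gamma * E / a0)`.
#'
#' @param gamma Surface energy per area (J/m^2).
#' @param E Young's modulus (Pa).
#' @param a0 Intra-atomic plane distance (m).
#' @return Theoretical strength (Pa).
#' @export
theoretical_strength <- function(gamma, E, a0) {
  check_pos(gamma, E, a0)
  sqrt(gamma * E / a0)
}

#' Order-of-magnitude theoretical strength, `E / (2 * pi)`
#' @param E Young's modulus (Pa).
#' @return Approximate theoretical strength (Pa).
#' @export
approx_theoretical_strength <- function(E) {
  check_pos(E)
  E / (2 * pi)
}

mpa_sqrt_m_to_si <- function(K) K * 1e6

#' Critical stress for a linear crack front
#'
#' Inverts the brittle-fracture criterion `K_Ic = sigma_c * sqrt(pi * l)`:
#' `sigma_c = K_Ic / sqrt(pi * l)`.
#'
#' @param K_Ic Fracture toughness in MPa*sqrt(m).
#' @param l Crack length (m).
#' @return Critical stress (Pa).
#' @export
critical_stress_linear <- function(K_Ic, l) {
  check_pos(K_Ic, l)
  mpa_sqrt_m_to_si(K_Ic) / sqrt(pi * l)
}

#' Critical stress for an elliptical crack front
#'
#' The elliptical-front stress-intensity factor is smaller by `2 / pi`
#' (`K_Ic = (2 / pi) * sigma_c * sqrt(pi * l)`), so the inverted critical
#' stress is `pi / 2` times the linear-front value.
#'
#' @inheritParams critical_stress_linear
#' @return Critical stress (Pa).
#' @export
critical_stress_elliptical <- function(K_Ic, l) {
  (pi / 2) * critical_stress_linear(K_Ic, l)
}

#' Griffith critical stress for an elliptical crack
#'
#' `sigma_c = sqrt(2 * gamma * E / (pi * l))`.
#'
#' @param gamma Surface energy per area (J/m^2).
#' @param E Young's modulus (Pa).
#' @param l Crack length (m).
#' @return Critical stress (Pa).
#' @export
griffith_elliptical <- function(gamma, E, l) {
  check_pos(gamma, E, l)
  sqrt(2 * gamma * E / (pi * l))
}

#' Bite pressure over a contact area
#'
#' `pressure = mass * g / area`. The default `g = 10` m/s^2 follows the
#' order-of-magnitude convention of the 100 kg / 1 cm^2 -> 1e7 Pa estimate;
#' pass `g = 9.81` for the physical value.
#'
#' @param mass_kg Bite force expressed as an equivalent mass (kg).
#' @param area_m2 Contact area (m^2).
#' @param g Gravitational acceleration (m/s^2).
#' @return Pressure (Pa).
#' @export
#' @examples
#' bite_pressure(100, 1e-4) # 1e7 Pa
bite_pressure <- function(mass_kg, area_m2, g = 10) {
  check_pos(mass_kg, area_m2, g)
  mass_kg * g / area_m2
}

#' Ratio of an applied pressure to a critical stress, in percent
#'
#' @param pressure Applied pressure (Pa).
#' @param sigma_c Critical stress (Pa).
#' @return `100 * pressure / sigma_c` (percent).
#' @export
#' @examples
#' stress_ratio(1e7, 4.9e9) # ~0.2 percent
stress_ratio <- function(pressure, sigma_c) {
  check_pos(pressure, sigma_c)
  100 * pressure / sigma_c
}
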