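#' Blood rheological properties
#'
#' Blood is modeled as an incompressible Newtonian fluid. Defaults are the
#' standard literature values for whole blood: dynamic viscosity
#' 0.004 kg m^-1 s^-1 and density 1060 kg m^-3.
#'
#' @param viscosity dynamic viscosity, kg m^-1 s^-1
#' @param density density, kg m^-3
#' @return an object of class `blood_properties`
#' @export
blood_properties <- function(viscosity = 0.004, density = 1060) {
  if (!is.numeric(viscosity) || length(viscosity) != 1L || !is.finite(viscosity) ||
      viscosity <= 0) {
    cf_stop("cf_invalid_blood", "viscosity must be a single positive number")
  }
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    cf_stop("cf_invalid_blood", "density must be a single positive number")
  }
  structure(list(viscosity = viscosity, density = density),
            class = "blood_properties")
}

#' Poiseuille resistance of a cylindrical segment
#'
#' R = 8 mu L / (pi r^4). A zero-length segment has zero resistance
#' (used for ideal junction connectors).
#'
#' @param length segment length, m (>= 0)
#' @param radius lumen radius, m (> 0)
#' @param blood a [blood_properties()] object
#' @return resistance, Pa s m^-3
#' @export
segment_resistance <- function(length, radius, blood = blood_properties()) {
  if (!is.finite(length) || length < 0 || !is.finite(radius) || radius <= 0) {
    cf_stop("cf_invalid_geometry",
            "invalid segment geometry: length=%g radius=%g", length, radius)
  }
  8 * blood$viscosity * length / (pi * radius^4)
}

#' Fluid inertance of a cylindrical segment
#'
#' L = rho l / (pi r^2), the lumped inertial coefficient relating
#' dQ/dt to the accelerating pressure difference.
#'
#' @inheritParams segment_resistance
#' @return inertance, Pa s^2 m^-3
#' @export
segment_inertance <- function(length, radius, blood = blood_properties()) {
  if (!is.finite(length) || length < 0 || !is.finite(radius) || radius <= 0) {
    cf_stop("cf_invalid_geometry",
            "invalid segment geometry: length=%g radius=%g", length, radius)
  }
  blood$density * length / (pi * radius^2)
}

#' Lumped stenosis element
#'
#' A reduced-order surrogate for the pressure loss across a focal stenosis:
#' a viscous (Poiseuille-like) coefficient on the minimal lumen plus a
#' turbulent/expansion momentum-loss coefficient, giving
#' dP(Q) = k_linear * Q + k_turb * Q * |Q| (odd in Q).
#'
#' @param k_linear viscous coefficient, Pa s m^-3 (>= 0)
#' @param k_turb momentum-loss coefficient, Pa s^2 m^-6 (>= 0)
#' @param min_diameter minimal lumen diameter, m
#' @param reference_diameter healthy reference diameter, m (> min_diameter)
#' @return an object of class `stenosis_element`
#' @export
stenosis_element <- function(k_linear, k_turb, min_diameter, reference_diameter) {
  if (!is.finite(k_linear) || k_linear < 0 || !is.finite(k_turb) || k_turb < 0) {
    cf_stop("cf_invalid_stenosis", "stenosis coefficients must be >= 0")
  }
  if (!is.finite(min_diameter) || !is.finite(reference_diameter) ||
      min_diameter <= 0 || min_diameter >= reference_diameter) {
    cf_stop("cf_invalid_stenosis",
            "min_diameter must be positive and smaller than reference_diameter")
  }
  structure(list(k_linear = k_linear, k_turb = k_turb,
                 min_diameter = min_diameter,
                 reference_diameter = reference_diameter),
            class = "stenosis_element")
}

#' Build a stenosis element from geometry
#'
#' The viscous coefficient is Poiseuille resistance of the stenotic throat at
#' the minimal lumen; the turbulent coefficient follows a sudden-expansion
#' (Borda-Carnot) closure, K_t = rho/2 * (1/A_min - 1/A_ref)^2, scaled by an
#' empirical factor close to 1.
#'
#' @param length stenotic throat length, m
#' @param min_diameter minimal lumen diameter, m
#' @param reference_diameter healthy diameter, m
#' @param blood a [blood_properties()] object
#' @param expansion_factor empirical multiplier on the expansion loss (default 1)
#' @return a [stenosis_element()]
#' @export
stenosis_from_geometry <- function(length, min_diameter, reference_diameter,
                                   blood = blood_properties(),
                                   expansion_factor = 1) {
  a_min <- pi * (min_diameter / 2)^2
  a_ref <- pi * (reference_diameter / 2)^2
  k_lin <- segment_resistance(length, min_diameter / 2, blood)
  k_turb <- expansion_factor * blood$density / 2 * (1 / a_min - 1 / a_ref)^2
  stenosis_element(k_lin, k_turb, min_diameter, reference_diameter)
}

#' Pressure drop across a stenosis element
#'
#' dP = k_linear * Q + k_turb * Q |Q|; sign-preserving (odd in Q).
#'
#' @param q flow, m^3/s (vectorized)
#' @param element a [stenosis_element()]
#' @return pressure drop, Pa
#' @export
stenosis_pressure_drop <- function(q, element) {
  stopifnot(inherits(element, "stenosis_element"))
  element$k_linear * q + element$k_turb * q * abs(q)
}
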