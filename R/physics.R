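# Closed-form Cherenkov emission physics: relativistic kinematics, emission
# angle and threshold, Frank-Tamm photon yield, and the geometry of the
# emitted photon's linear polarization vector.

# electron rest-mass energy, keV (CODATA); the rounded 511 keV is accepted
# everywhere m0c2 is a parameter
ELECTRON_REST_MASS_KEV <- 510.99895
FINE_STRUCTURE <- 1 / 137.035999084

#' Particle speed from kinetic energy
#'
#' Computes beta = v/c from the relativistic kinetic energy via
#' gamma = 1 + E_kin / m0c^2 and beta = sqrt(1 - 1/gamma^2).
#'
#' @param kinetic_energy kinetic energy in keV (vectorised).
#' @param m0c2 rest-mass energy in keV; defaults to the electron value.
#' @return beta in `[0, 1)`.
#' @examples
#' beta_from_kinetic_energy(511, 511)  # gamma = 2 -> sqrt(3)/2
#' @export
beta_from_kinetic_energy <- function(kinetic_energy,
                                     m0c2 = ELECTRON_REST_MASS_KEV) {
  if (any(!is.finite(kinetic_energy)) || any(kinetic_energy < 0))
    stop("kinetic_energy must be finite and >= 0")
  if (any(m0c2 <= 0)) stop("m0c2 must be > 0")
  gamma <- 1 + kinetic_energy / m0c2
  sqrt(pmax(0, 1 - 1 / gamma^2))
}

#' Cherenkov emission angle
#'
#' The emission cone half-angle from cos(theta) = 1 / (beta * n).
#'
#' @param beta particle speed as a fraction of c (vectorised).
#' @param n refractive index of the medium.
#' @return Angle in degrees; 0 at threshold, approaching acos(1/n) as
#'   beta -> 1 (41 degrees in water).
#' @examples
#' cherenkov_angle(1, 1.33)  # 41.25 deg
#' @export
cherenkov_angle <- function(beta, n) {
  cosang <- 1 / (beta * n)
  if (any(cosang > 1 + 1e-15))
    stop("below threshold: beta * n < 1, no Cherenkov emission")
  acos(pmin(1, cosang)) * 180 / pi
}

#' Cherenkov production threshold energy
#'
#' Minimum relativistic kinetic energy for Cherenkov emission,
#' E_min = m0c^2 * ((1 - 1/n^2)^(-1/2) - 1). In water (n = 1.33) this is
#' 264 keV for electrons; in polyvinyl toluene (n = 1.58), 149 keV.
#'
#' @inheritParams cherenkov_angle
#' @inheritParams beta_from_kinetic_energy
#' @return Threshold kinetic energy in keV.
#' @examples
#' round(cherenkov_threshold_energy(1.33, 511))  # 264
#' @export
cherenkov_threshold_energy <- function(n, m0c2 = ELECTRON_REST_MASS_KEV) {
  if (any(n <= 1)) stop("no Cherenkov emission possible in a medium with n <= 1")
  m0c2 * (1 / sqrt(1 - 1 / n^2) - 1)
}

#' Expected Cherenkov photon yield over a step
#'
#' Frank-Tamm photon count for a unit-charge particle over a straight path
#' of length `step_length` in the wavelength band
#' `[lambda_min, lambda_max]`:
#' N = 2 pi alpha * step * (1 - 1/(beta^2 n^2)) * (1/lambda_min - 1/lambda_max).
#' Below threshold the yield is 0 (not an error): emission simply stops.
#'
#' @inheritParams cherenkov_angle
#' @param lambda_min,lambda_max wavelength band edges in nm.
#' @param step_length path length in cm.
#' @return Expected photon count (vectorised over beta).
#' @examples
#' cherenkov_photon_yield(1, 1.33, 400, 800, 1)  # ~249 photons/cm
#' @export
cherenkov_photon_yield <- function(beta, n, lambda_min = 400,
                                   lambda_max = 800, step_length = 1) {
  if (lambda_min >= lambda_max) stop("lambda_min must be < lambda_max")
  sin2 <- pmax(0, 1 - 1 / (beta^2 * n^2))
  band <- (1 / (lambda_min * 1e-7) - 1 / (lambda_max * 1e-7))  # cm^-1
  2 * pi * FINE_STRUCTURE * step_length * sin2 * band
}

#' Linear polarization vector of a Cherenkov photon
#'
#' The electric-field direction of Cherenkov light lies in the plane spanned
#' by the particle direction and the photon direction, perpendicular to the
#' photon direction, and points away from the particle's path (outward from
#' the emission cone axis). With unit vectors u (particle) and k (photon)
#' this is the normalization of (u . k) k - u.
#'
#' @param particle_direction unit 3-vector (particle path).
#' @param photon_direction unit 3-vector (photon propagation), separated from
#'   the particle direction by the Cherenkov angle.
#' @return Unit 3-vector; orthogonal to `photon_direction`.
#' @examples
#' u <- c(0, 0, 1)
#' k <- c(sin(41 * pi / 180), 0, cos(41 * pi / 180))
#' photon_polarization_vector(u, k)
#' @export
photon_polarization_vector <- function(particle_direction, photon_direction) {
  u <- particle_direction; k <- photon_direction
  w <- k * sum(u * k) - u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12)
    stop("degenerate geometry: particle and photon directions are collinear")
  w / nw
}

# Vectorised polarization for n x 3 direction matrices (internal; same
# formula as photon_polarization_vector).
polarization_matrix <- function(u_mat, k_mat) {
  dots <- rowSums(u_mat * k_mat)
  w <- k_mat * dots - u_mat
  nw <- sqrt(rowSums(w^2))
  w / pmax(nw, 1e-300)
}
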