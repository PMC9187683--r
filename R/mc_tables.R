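# Embedded interaction-data tables for liquid water, log-interpolated.
# Collision stopping powers follow the NIST ESTAR tabulation (MeV cm^2/g);
# photon attenuation coefficients (without coherent scattering) follow the
# NIST XCOM tabulation (cm^2/g). Both are coarse grids adequate for the
# condensed-history transport used here.

.WATER_STOPPING <- data.frame(
  energy_kev = c(100, 200, 300, 400, 500, 600, 800, 1000, 1500, 2000,
                 3000, 4000, 5000, 6000, 8000, 10000, 15000, 20000, 30000),
  # collision stopping power, MeV cm^2 / g
  s_col = c(4.115, 2.793, 2.355, 2.148, 2.034, 1.963, 1.886, 1.849,
            1.822, 1.824, 1.846, 1.870, 1.892, 1.911, 1.943, 1.968,
            2.014, 2.046, 2.089))

.WATER_MU <- data.frame(
  energy_kev = c(500, 1000, 1500, 2000, 3000, 4000, 5000, 6000, 8000, 10000),
  # attenuation coefficient without coherent scattering, cm^2 / g
  mu_rho = c(0.0966, 0.0707, 0.0575, 0.0494, 0.0397, 0.0340, 0.0303,
             0.0277, 0.0243, 0.0222))

log_interp <- function(x, xs, ys) {
  x <- pmin(pmax(x, min(xs)), max(xs))
  exp(approx(log(xs), log(ys), xout = log(x), rule = 2)$y)
}

#' Electron collision stopping power in water
#'
#' Log-log interpolation of an embedded coarse tabulation (valid 100 keV to
#' 30 MeV; clamped outside).
#'
#' @param energy_kev electron kinetic energy in keV (vectorised).
#' @return Collision stopping power in MeV cm^2/g.
#' @export
water_stopping_power <- function(energy_kev) {
  log_interp(energy_kev, .WATER_STOPPING$energy_kev, .WATER_STOPPING$s_col)
}

#' Photon attenuation coefficient in water
#'
#' Log-log interpolation of an embedded coarse tabulation (incoherent +
#' photoelectric + pair; coherent scattering excluded), valid 0.5-10 MeV.
#'
#' @param energy_kev photon energy in keV (vectorised).
#' @return Linear attenuation coefficient in cm^-1 (unit-density water).
#' @export
water_attenuation <- function(energy_kev) {
  log_interp(energy_kev, .WATER_MU$energy_kev, .WATER_MU$mu_rho)
}

# Highland multiple-scattering angle (plane-projected RMS, radians) for a
# unit-charge particle traversing thickness step_gcm2 (g/cm^2) of material
# with radiation length X0 (g/cm^2).
highland_theta0 <- function(energy_kev, step_gcm2, X0,
                            m0c2 = ELECTRON_REST_MASS_KEV) {
  pc <- sqrt(energy_kev * (energy_kev + 2 * m0c2))       # keV
  beta <- beta_from_kinetic_energy(energy_kev, m0c2)
  t <- pmax(step_gcm2 / X0, 1e-12)
  13.6e3 / (beta * pc) * sqrt(t) * (1 + 0.038 * log(t))
}
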