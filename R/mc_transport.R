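# Simplified condensed-history Monte Carlo of electron (and first-collision
# photon) transport in a water tank, tallying the position, direction,
# polarization and generation energy of every Cherenkov photon produced.
#
# Tank frame: z = depth along the beam axis (surface at z = 0), y = toward
# the camera, x = lateral. The default tank is 15 x 15 cm^2 in cross-section
# (x, y in [-7.5, 7.5]) and 20 cm deep.

#' Beam specification
#'
#' @param particle `"electron"` or `"photon"`.
#' @param energy_kev kinetic energy (electrons) or effective photon energy
#'   in keV. Megavoltage photon beams are approximated as monoenergetic:
#'   the presets map 6 MV -> 2 MeV and 18 MV -> 5 MeV effective energy.
#' @param field_size side length (cm) of the square field at the surface.
#' @param ssd source-to-surface distance in cm (recorded; the beam is
#'   modelled as parallel).
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(particle = c("electron", "photon"), energy_kev,
                      field_size = 6, ssd = 100) {
  particle <- match.arg(particle)
  if (energy_kev <= 0) stop("energy must be > 0")
  structure(list(particle = particle, energy_kev = energy_kev,
                 field_size = field_size, ssd = ssd), class = "beam_spec")
}

#' Preset clinical beams
#'
#' The four study beams: 6 and 18 MV photons (5 x 5 cm^2 field, effective
#' energies 2 and 5 MeV), 6 and 18 MeV electrons (6 x 6 cm^2 field).
#'
#' @param name one of `"6MV"`, `"18MV"`, `"6MeV"`, `"18MeV"`.
#' @return A [beam_spec()].
#' @export
beam_preset <- function(name = c("6MV", "18MV", "6MeV", "18MeV")) {
  name <- match.arg(name)
  switch(name,
    "6MV"   = beam_spec("photon", 2000, field_size = 5),
    "18MV"  = beam_spec("photon", 5000, field_size = 5),
    "6MeV"  = beam_spec("electron", 6000, field_size = 6),
    "18MeV" = beam_spec("electron", 18000, field_size = 6))
}

default_tank <- function() c(15, 15, 20)   # x, y extent and depth, cm

inside_tank <- function(pos, tank) {
  abs(pos[1]) <= tank[1] / 2 && abs(pos[2]) <= tank[2] / 2 &&
    pos[3] >= 0 && pos[3] <= tank[3]
}

# photon directions on a cone of half-angle theta (radians) around axis d,
# at azimuths psi (radians); returns length(psi) x 3 matrix
cone_directions <- function(axis, theta, psi) {
  # orthonormal frame around the axis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - axis * sum(ref * axis)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  st <- sin(theta); ct <- cos(theta)
  outer(rep(ct, length(psi)), axis) +
    st * (outer(cos(psi), e1) + outer(sin(psi), e2))
}

# deflect direction d by plane-projected Gaussian angles of RMS theta0
scatter_direction <- function(d, theta0) {
  tx <- rnorm(1, 0, theta0); ty <- rnorm(1, 0, theta0)
  ang <- sqrt(tx^2 + ty^2)
  if (ang < 1e-12) return(d)
  psi <- atan2(ty, tx)
  as.vector(cone_directions(d, ang, psi))
}

empty_photons <- function() {
  list(position = matrix(numeric(0), 0, 3),
       direction = matrix(numeric(0), 0, 3),
       polarization = matrix(numeric(0), 0, 3),
       energy_kev = numeric(0))
}

bind_photons <- function(lst) {
  lst <- Filter(function(p) nrow(p$position) > 0, lst)
  if (length(lst) == 0L) return(structure(empty_photons(),
                                          class = "cherenkov_photons"))
  structure(list(
    position = do.call(rbind, lapply(lst, `[[`, "position")),
    direction = do.call(rbind, lapply(lst, `[[`, "direction")),
    polarization = do.call(rbind, lapply(lst, `[[`, "polarization")),
    energy_kev = unlist(lapply(lst, `[[`, "energy_kev"), use.names = FALSE)),
    class = "cherenkov_photons")
}

#' @export
print.cherenkov_photons <- function(x, ...) {
  cat(sprintf("<cherenkov_photons> %d photons\n", nrow(x$position)))
  invisible(x)
}

#' Transport a single electron, emitting Cherenkov photons
#'
#' Condensed-history stepping: per step of length `step_cm`, the electron
#' (a) loses energy according to the tabulated collision stopping power,
#' (b) emits Poisson-distributed Cherenkov photons at the current emission
#' angle around its current direction with uniform cone azimuth, each
#' carrying the polarization vector from [photon_polarization_vector()],
#' and (c) is deflected by a Gaussian multiple-scattering angle (Highland
#' formula). Transport stops when the energy drops below the Cherenkov
#' threshold or the electron leaves the tank.
#'
#' @param energy_kev initial kinetic energy, keV.
#' @param position start position `c(x, y, z)` in tank coordinates (cm).
#' @param direction initial unit direction (default along the beam, +z).
#' @param med a [medium()] (default water).
#' @param step_cm condensed-history step length (default 0.1 cm).
#' @param band wavelength band `c(min, max)` in nm for the photon yield.
#' @param tank tank dimensions `c(x, y, depth)` in cm.
#' @param scattering logical; disable to keep the direction fixed (the
#'   degenerate limit in which every photon sits exactly on the analytic
#'   Cherenkov cone for its generation energy).
#' @param seed optional integer seed for reproducibility (left alone by
#'   default so that callers manage the RNG stream).
#' @return A `cherenkov_photons` record list: `position` (n x 3 cm),
#'   `direction`, `polarization` (n x 3 unit vectors) and `energy_kev`, the
#'   electron kinetic energy at generation.
#' @export
transport_electron <- function(energy_kev, position = c(0, 0, 0),
                               direction = c(0, 0, 1), med = water_medium(),
                               step_cm = 0.1, band = c(400, 800),
                               tank = default_tank(), scattering = TRUE,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- med$refractive_index
  E_thr <- cherenkov_threshold_energy(n)
  E <- energy_kev
  pos <- position
  dir <- direction / sqrt(sum(direction^2))
  out <- vector("list", 64L); nout <- 0L

  while (E > E_thr && inside_tank(pos, tank)) {
    beta <- beta_from_kinetic_energy(E)
    if (beta * n > 1) {
      nph <- rpois(1, cherenkov_photon_yield(beta, n, band[1], band[2],
                                             step_cm))
      if (nph > 0) {
        theta_c <- cherenkov_angle(beta, n) * pi / 180
        psi <- runif(nph, 0, 2 * pi)
        dirs <- cone_directions(dir, theta_c, psi)
        u <- matrix(dir, nph, 3, byrow = TRUE)
        pols <- polarization_matrix(u, dirs)
        frac <- runif(nph)
        ppos <- matrix(pos, nph, 3, byrow = TRUE) +
          outer(frac * step_cm, dir)
        nout <- nout + 1L
        if (nout > length(out)) out <- c(out, vector("list", length(out)))
        out[[nout]] <- list(position = ppos, direction = dirs,
                            polarization = pols,
                            energy_kev = rep(E, nph))
      }
    }
    # energy loss over the step (keV)
    E <- E - water_stopping_power(E) * med$density * step_cm * 1000
    if (scattering && E > 0) {
      t0 <- highland_theta0(E, step_cm * med$density, med$radiation_length)
      if (is.finite(t0) && t0 > 0) dir <- scatter_direction(dir, t0)
    }
    pos <- pos + dir * step_cm
  }
  bind_photons(out[seq_len(nout)])
}

# Kahn rejection sampling of the Klein-Nishina scattered-photon energy.
# Returns x = E / E' >= 1 for incident photon of alpha = E / m0c2.
sample_kahn <- function(alpha) {
  repeat {
    r <- runif(3)
    if (r[1] <= (1 + 2 * alpha) / (9 + 2 * alpha)) {
      x <- 1 + 2 * alpha * r[2]
      if (r[3] <= 4 * (1 / x - 1 / x^2)) return(x)
    } else {
      x <- (1 + 2 * alpha) / (1 + 2 * alpha * r[2])
      cost <- 1 - (x - 1) / alpha
      if (r[3] <= 0.5 * (cost^2 + 1 / x)) return(x)
    }
  }
}

#' Transport a primary photon via its first Compton interaction
#'
#' Samples an interaction depth from exponential attenuation (tabulated
#' attenuation coefficient for water), samples a Compton electron from the
#' Klein-Nishina distribution (energy and emission angle from Compton
#' kinematics), and hands the electron to [transport_electron()]. The
#' scattered photon is not followed further (single-scatter approximation);
#' pair production and bremsstrahlung are ignored.
#'
#' @inheritParams transport_electron
#' @param energy_kev photon energy in keV.
#' @param position entry position at the surface, `c(x, y, 0)`.
#' @return A `cherenkov_photons` record (possibly empty when the photon
#'   traverses the tank without interacting).
#' @export
transport_photon_primary <- function(energy_kev, position = c(0, 0, 0),
                                     med = water_medium(), step_cm = 0.1,
                                     band = c(400, 800),
                                     tank = default_tank(),
                                     scattering = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- water_attenuation(energy_kev) * med$density
  depth <- -log(runif(1)) / mu
  if (depth + position[3] > tank[3])
    return(bind_photons(list()))
  alpha <- energy_kev / ELECTRON_REST_MASS_KEV
  x <- sample_kahn(alpha)
  Escat <- energy_kev / x
  T_e <- energy_kev - Escat
  # electron polar angle from Compton kinematics, azimuth uniform
  cost_g <- 1 - (x - 1) / alpha
  tan_half <- sqrt(max(0, (1 - cost_g) / (1 + cost_g)))
  theta_e <- atan2(1, (1 + alpha) * tan_half)
  phi <- runif(1, 0, 2 * pi)
  dir_e <- c(sin(theta_e) * cos(phi), sin(theta_e) * sin(phi), cos(theta_e))
  transport_electron(T_e, position = position + c(0, 0, depth),
                     direction = dir_e, med = med, step_cm = step_cm,
                     band = band, tank = tank, scattering = scattering)
}

#' Simulate a beam and collect Cherenkov photons
#'
#' Runs `n_primaries` primaries of the given beam, entry positions uniform
#' over the field at the surface, directions along the beam axis, and
#' concatenates all Cherenkov photon records.
#'
#' @param beam a [beam_spec()] or preset name accepted by [beam_preset()].
#' @param n_primaries number of primary particles.
#' @param seed integer seed (reproducible streams).
#' @inheritParams transport_electron
#' @return A `cherenkov_photons` record.
#' @export
simulate_beam <- function(beam, n_primaries, seed = 1,
                          med = water_medium(), step_cm = 0.1,
                          band = c(400, 800), tank = default_tank(),
                          scattering = TRUE) {
  if (is.character(beam)) beam <- beam_preset(beam)
  stopifnot(inherits(beam, "beam_spec"))
  set.seed(seed)
  half <- beam$field_size / 2
  res <- vector("list", n_primaries)
  for (k in seq_len(n_primaries)) {
    entry <- c(runif(1, -half, half), runif(1, -half, half), 0)
    res[[k]] <- if (beam$particle == "electron") {
      transport_electron(beam$energy_kev, position = entry, med = med,
                         step_cm = step_cm, band = band, tank = tank,
                         scattering = scattering)
    } else {
      transport_photon_primary(beam$energy_kev, position = entry, med = med,
                               step_cm = step_cm, band = band, tank = tank,
                               scattering = scattering)
    }
  }
  bind_photons(res)
}
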