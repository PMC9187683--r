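# Forward simulator: renders four-angle polarizer stacks (plus background
# and flat frames) from a known ground-truth projected dose, DoLP/AoLP
# fields and an angular-emission weighting, so the whole analysis chain can
# be exercised against a known answer.

#' Synthetic acquisition scenario
#'
#' Bundles the beam preset, imaging geometry, polarization ground truth and
#' noise model for the forward simulator. DoLP presets follow the measured
#' beam-energy dependence (6 MeV 42%, 18 MeV 47%, 6 MV 29%, 18 MV 33%;
#' `"unpolarized"` emulates the scintillator experiment with DoLP 0). AoLP
#' is 0 on the beam axis and ramps linearly across the penumbra to 35
#' degrees.
#'
#' @param beam `"6MV"`, `"18MV"`, `"6MeV"`, `"18MeV"` or `"unpolarized"`.
#' @param image_size `c(nrow, ncol)` pixels.
#' @param pixel_scale mm/pixel (a coarse default keeps simulated images
#'   small while covering the full tank).
#' @param dolp mean DoLP in percent (default from the beam preset).
#' @param aolp_max AoLP reached in the penumbra, degrees.
#' @param counts_scale expected counts/pixel at the dose maximum.
#' @param background mean background level, counts.
#' @param read_noise Gaussian read noise SD, counts.
#' @param spike_rate per-pixel probability of a transient radiation spike
#'   per frame.
#' @param n_frames frames per polarizer angle.
#' @param vignette_f cos^4 vignette scale parameter, pixels.
#' @param exposure integration time per frame, seconds.
#' @return Object of class `scenario`.
#' @export
scenario <- function(beam = c("6MeV", "18MeV", "6MV", "18MV", "unpolarized"),
                     image_size = c(110, 84), pixel_scale = 2,
                     dolp = NULL, aolp_max = 35,
                     counts_scale = 2e4, background = 100,
                     read_noise = 5, spike_rate = 1e-4, n_frames = 10,
                     vignette_f = 2.5 * max(image_size), exposure = 30) {
  beam <- match.arg(beam)
  if (is.null(dolp))
    dolp <- switch(beam, "6MeV" = 42, "18MeV" = 47, "6MV" = 29,
                   "18MV" = 33, "unpolarized" = 0)
  if (dolp < 0 || dolp > 100) stop("dolp must be in [0, 100]")
  structure(list(beam = beam, image_size = image_size,
                 pixel_scale = pixel_scale, dolp = dolp,
                 aolp_max = aolp_max, counts_scale = counts_scale,
                 background = background, read_noise = read_noise,
                 spike_rate = spike_rate, n_frames = n_frames,
                 vignette_f = vignette_f, exposure = exposure),
            class = "scenario")
}

# depth-dose shape parameters per beam: photons have a build-up +
# exponential-decay model with d_max pinned at the measured positions
# (1.2 cm at 6 MV, 3.05 cm at 18 MV); electrons a plateau + sigmoid falloff
# with typical clinical d_max / R50
beam_depth_model <- function(beam) {
  photon_curve <- function(dmax, b) {
    # solve the build-up rate so the maximum of (1 - e^(-a z)) e^(-b z)
    # falls exactly at dmax: ln((a + b) / b) / a = dmax
    a <- uniroot(function(a) log((a + b) / b) / a - dmax,
                 c(1e-3, 50))$root
    function(z) ifelse(z < 0, 0, (1 - exp(-a * z)) * exp(-b * z))
  }
  electron_curve <- function(R50, w, slope, buildup) {
    function(z) ifelse(z < 0, 0,
      (1 - buildup * exp(-(z / 0.8)^2)) * (1 + slope * z) /
        (1 + exp((z - R50) / w)) + 0.01)
  }
  switch(beam,
    "6MV"  = list(fun = photon_curve(1.20, 0.040), field = 5),
    "18MV" = list(fun = photon_curve(3.05, 0.025), field = 5),
    "6MeV" = list(fun = electron_curve(2.4, 0.35, 0.05, 0.25), field = 6),
    "18MeV" = list(fun = electron_curve(7.5, 1.0, 0.02, 0.20), field = 6),
    "unpolarized" = list(fun = function(z) rep(1, length(z)), field = 6))
}

#' Ground truth for a synthetic scenario
#'
#' Builds the ground-truth projected dose image (separable depth-dose x
#' lateral-profile model), the DoLP field (constant at the scenario DoLP)
#' and the AoLP field (0 on-axis, linear ramp across the penumbra capped at
#' `aolp_max`, antisymmetric in the off-axis coordinate).
#'
#' @param scn a [scenario()].
#' @return List with `dose` (a [projected_dose_image()], max 1),
#'   `dolp_field`, `aolp_field` (matrices) and `geometry`
#'   (a [camera_geometry()]).
#' @export
generate_ground_truth <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  geom <- camera_geometry(scn$image_size, pixel_scale = scn$pixel_scale)
  g <- pixel_grid(geom)
  mod <- beam_depth_model(scn$beam)
  depth_curve <- mod$fun(g$depth)
  depth_curve[!(g$depth >= 0 & g$depth <= geom$tank[3])] <- 0
  W <- mod$field; p <- 0.25
  erf <- function(t) 2 * stats::pnorm(t * sqrt(2)) - 1
  profile <- 0.5 * (erf((g$lateral + W / 2) / (sqrt(2) * p)) -
                      erf((g$lateral - W / 2) / (sqrt(2) * p)))
  dose <- outer(depth_curve, profile)
  dose <- dose / max(dose)
  # AoLP ramp: 0 where the profile is above 80% of the central value,
  # aolp_max below 20%, linear in the normalized profile level in between
  rel <- profile / max(profile)
  t_pen <- pmin(pmax((0.8 - rel) / 0.6, 0), 1)
  aolp_cols <- sign(g$lateral) * scn$aolp_max * t_pen
  list(dose = projected_dose_image(dose, geom),
       dolp_field = matrix(scn$dolp, scn$image_size[1], scn$image_size[2]),
       aolp_field = matrix(aolp_cols, scn$image_size[1], scn$image_size[2],
                           byrow = TRUE),
       geometry = geom)
}

#' Render a four-angle polarizer acquisition from ground truth
#'
#' Inverse of the analysis chain. Per pixel the total Cherenkov intensity
#' is the ground-truth dose times the emission-anisotropy weight (the
#' reciprocal of the correction the pipeline computes from the same
#' angular distributions) scaled to `counts_scale`; it is split into
#' polarized and unpolarized parts by the DoLP field, turned into the four
#' polarizer frames by the Malus model, vignetted, offset by background,
#' and corrupted with Poisson counting noise, Gaussian read noise and
#' random transient spikes. A flat-field frame (uniform emitter seen
#' through the same vignette) and background frames are rendered too.
#'
#' @param truth result of [generate_ground_truth()].
#' @param scn the [scenario()].
#' @param dists optional list of [angular_distribution()] objects; when
#'   given, the rendered anisotropy is the reciprocal of
#'   [build_correction_maps()] on these distributions (`NULL` = isotropic).
#' @param seed integer seed.
#' @param noise logical; `FALSE` renders the noiseless expectation
#'   (and skips spikes and background).
#' @return List with `frames` (list over angles `"0"`, `"45"`, `"90"`,
#'   `"135"`, each a list of `n_frames` matrices), `background_frames`,
#'   `flat_frame`, `vignette` (the generating [vignette_model()]),
#'   `weight` (the anisotropy weight image) and the scenario.
#' @export
render_stack <- function(truth, scn, dists = NULL, seed = 1, noise = TRUE) {
  stopifnot(inherits(scn, "scenario"))
  set.seed(seed)
  nr <- scn$image_size[1]; nc <- scn$image_size[2]
  angles <- c(0, 45, 90, 135)
  beam_kind <- if (scn$beam %in% c("6MV", "18MV")) "photon" else "electron"

  weight <- matrix(1, nr, nc)
  if (!is.null(dists)) {
    cm <- build_correction_maps(dists, truth$geometry, beam_kind)
    weight <- 1 / (cm$C_theta * cm$C_phi)
  }
  total <- truth$dose$dose * weight
  total <- total / max(total) * scn$counts_scale
  dfrac <- truth$dolp_field / 100
  I_pol <- total * dfrac
  I_unpol <- total * (1 - dfrac)

  vig <- vignette_model(center = c((nr + 1) / 2, (nc + 1) / 2),
                        f = scn$vignette_f, amplitude = 1)
  vs <- vignette_surface(vig, nr, nc)

  render_one <- function(expected) {
    if (!noise) return(expected)
    img <- matrix(rpois(length(expected), lambda = expected), nr, nc) +
      matrix(rnorm(length(expected), 0, scn$read_noise), nr, nc)
    spikes <- matrix(runif(length(expected)) < scn$spike_rate, nr, nc)
    img[spikes] <- img[spikes] +
      runif(sum(spikes), 2, 10) * scn$counts_scale
    pmax(img, 0)
  }

  frames <- lapply(angles, function(a0) {
    clean <- (I_pol * cos((a0 - truth$aolp_field) * pi / 180)^2 + I_unpol) *
      vs + if (noise) scn$background else 0
    lapply(seq_len(scn$n_frames), function(k) render_one(clean))
  })
  names(frames) <- as.character(angles)

  bg <- lapply(seq_len(scn$n_frames), function(k)
    render_one(matrix(if (noise) scn$background else 0, nr, nc)))
  flat <- render_one(0.8 * scn$counts_scale * vs)

  list(frames = frames, background_frames = bg, flat_frame = flat,
       vignette = vig, weight = weight, scenario = scn)
}

#' Preprocess a rendered acquisition into a polarized stack
#'
#' Applies the standard preprocessing chain (temporal median over the
#' repeated frames, background subtraction, cos^4 flat-field from the
#' rendered flat frame) to each polarizer angle and assembles a
#' [polarized_stack()].
#'
#' @param rendered result of [render_stack()].
#' @param fit_flat logical; `FALSE` skips the flat-field step (e.g. for
#'   noiseless renders without vignetting).
#' @return A [polarized_stack()].
#' @export
measure_stack <- function(rendered, fit_flat = TRUE) {
  scn <- rendered$scenario
  vig <- if (fit_flat) fit_vignette(rendered$flat_frame) else NULL
  frames <- lapply(rendered$frames, function(fl)
    preprocess_frames(fl, background_frames = rendered$background_frames,
                      vignette = vig))
  polarized_stack(frames, pixel_scale = scn$pixel_scale,
                  exposure = scn$exposure)
}
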