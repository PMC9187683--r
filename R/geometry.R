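# Camera-tank geometry, viewing angles per pixel, and the anisotropy
# correction maps C_theta / C_phi applied to the polarized image.

#' Camera and tank geometry
#'
#' Describes the imaging geometry: a camera at distance `L` from the tank
#' mid-plane, optical axis aimed at the tank center, imaging the tank
#' through a pixel grid. Image rows run along depth (row 1 nearest the
#' surface), columns along the lateral axis.
#'
#' @param image_size `c(nrow, ncol)` in pixels.
#' @param pixel_scale pixel size in mm/pixel in the tank mid-plane.
#' @param L lens-to-mid-plane distance in cm (default 50).
#' @param tank tank dimensions `c(x, y, depth)` in cm
#'   (default 15 x 15 x 20).
#' @return Object of class `camera_geometry`.
#' @export
camera_geometry <- function(image_size, pixel_scale = 0.26, L = 50,
                            tank = default_tank()) {
  if (pixel_scale <= 0) stop("pixel_scale must be > 0")
  if (L <= tank[2] / 2) stop("camera distance must exceed tank half-thickness")
  structure(list(image_size = image_size, pixel_scale = pixel_scale,
                 L = L, tank = tank, depth_center = tank[3] / 2),
            class = "camera_geometry")
}

# tank-plane coordinates of every pixel: depth (cm, per row) and lateral
# (cm, per column), plus the in-tank mask
pixel_grid <- function(geometry) {
  nr <- geometry$image_size[1]; nc <- geometry$image_size[2]
  s <- geometry$pixel_scale / 10                      # cm per pixel
  depth <- (seq_len(nr) - (nr + 1) / 2) * s + geometry$depth_center
  lateral <- (seq_len(nc) - (nc + 1) / 2) * s
  mask <- outer(depth >= 0 & depth <= geometry$tank[3],
                abs(lateral) <= geometry$tank[1] / 2, `&`)
  list(depth = depth, lateral = lateral, mask = mask)
}

#' Viewing angles of a pixel
#'
#' Maps a pixel to the polar and azimuthal angles under which the camera
#' observes the corresponding mid-plane point: theta_cam = 90 deg +
#' arctan((depth - depth_center) / L), phi_cam = arctan(lateral / L). A
#' camera at 50 cm viewing depths 0-17 cm in a 20 cm tank samples polar
#' angles from about 79 to 98 degrees.
#'
#' @param i,j pixel row/column indices (vectorised, equal length).
#' @param geometry a [camera_geometry()].
#' @return Data frame with `theta_cam`, `phi_cam` (degrees), `depth`,
#'   `lateral` (cm) and logical `inside`; pixels mapping outside the tank
#'   are masked (`inside = FALSE`).
#' @export
pixel_to_viewing_angles <- function(i, j, geometry) {
  g <- pixel_grid(geometry)
  if (any(i < 1 | i > geometry$image_size[1] |
          j < 1 | j > geometry$image_size[2]))
    stop("pixel outside image")
  depth <- g$depth[i]; lateral <- g$lateral[j]
  data.frame(
    theta_cam = 90 + atan((depth - geometry$depth_center) / geometry$L) *
      180 / pi,
    phi_cam = atan(lateral / geometry$L) * 180 / pi,
    depth = depth, lateral = lateral,
    inside = g$mask[cbind(i, j)])
}

#' Build anisotropy correction maps from angular distributions
#'
#' For each pixel the camera samples the Cherenkov angular distribution at
#' its viewing angles; the corrections are the reciprocal relative
#' densities C_theta = Pbar_theta / P_theta(theta_cam) and
#' C_phi = Pbar_phi / P_phi(phi_cam), where P are the normalized polar and
#' azimuthal densities of the relevant scoring region and Pbar their mean
#' over the angles actually sampled across the image — so the corrections
#' average to 1 over the field and leave corrected and raw images on
#' comparable scales.
#'
#' Photon beams use a single on-axis distribution (the one scored nearest
#' the tank center); electron beams interpolate the polar density linearly
#' between scored depths. The azimuthal correction uses the scoring region
#' nearest in off-axis distance (counts pooled over depths at the same
#' off-axis position). Densities below `1/cap` of the mean are capped and
#' flagged.
#'
#' @param dists list of [angular_distribution()] objects covering the image.
#' @param geometry a [camera_geometry()].
#' @param beam_kind `"electron"` (depth-dependent polar correction) or
#'   `"photon"` (single polar distribution).
#' @param cap maximum correction factor (default 10).
#' @return Object of class `correction_maps` with matrices `C_theta`,
#'   `C_phi`, logical `mask` (pixels inside the tank), `qa_capped`, and a
#'   `normalization` tag.
#' @export
build_correction_maps <- function(dists, geometry,
                                  beam_kind = c("electron", "photon"),
                                  cap = 10) {
  beam_kind <- match.arg(beam_kind)
  stopifnot(all(vapply(dists, inherits, logical(1), "angular_distribution")))
  g <- pixel_grid(geometry)
  nr <- geometry$image_size[1]; nc <- geometry$image_size[2]
  theta_cam <- 90 + atan((g$depth - geometry$depth_center) / geometry$L) *
    180 / pi                                            # per row
  phi_cam <- atan(g$lateral / geometry$L) * 180 / pi    # per column

  ## polar correction (per row, broadcast over columns)
  onax <- dists[vapply(dists, function(d) d$region$off_axis == 0, logical(1))]
  if (length(onax) == 0L) onax <- dists
  depths <- vapply(onax, function(d) d$region$depth, numeric(1))
  ord <- order(depths); onax <- onax[ord]; depths <- depths[ord]
  dens_at <- function(d, ang) {
    pd <- polar_density(d)
    approx(pd$centers, pd$density, xout = ang, rule = 2)$y
  }
  P_rows <- if (beam_kind == "photon" || length(onax) == 1L) {
    central <- onax[[which.min(abs(depths - geometry$depth_center))]]
    dens_at(central, theta_cam)
  } else {
    # evaluate every scored depth's density at each row's viewing angle,
    # then interpolate linearly in depth (nearest outside the scored span)
    evals <- vapply(onax, dens_at, numeric(nr), ang = theta_cam)
    vapply(seq_len(nr), function(r) {
      z <- g$depth[r]
      approx(depths, evals[r, ], xout = min(max(z, depths[1]),
                                            depths[length(depths)]))$y
    }, numeric(1))
  }

  ## azimuthal correction (per column)
  offs <- vapply(dists, function(d) d$region$off_axis, numeric(1))
  uoff <- sort(unique(offs))
  adens <- lapply(uoff, function(o) {
    grp <- dists[offs == o]
    pooled <- grp[[1]]
    if (length(grp) > 1L)
      pooled$azimuth_counts <- Reduce(`+`, lapply(grp, `[[`, "azimuth_counts"))
    azimuth_density(pooled)
  })
  nearest <- vapply(g$lateral, function(x) which.min(abs(uoff - x)),
                    integer(1))
  P_cols <- vapply(seq_len(nc), function(cidx) {
    ad <- adens[[nearest[cidx]]]
    approx(ad$centers, ad$density, xout = phi_cam[cidx], rule = 2)$y
  }, numeric(1))

  in_rows <- g$depth >= 0 & g$depth <= geometry$tank[3]
  in_cols <- abs(g$lateral) <= geometry$tank[1] / 2
  Pbar_t <- mean(P_rows[in_rows]); Pbar_p <- mean(P_cols[in_cols])
  floor_t <- Pbar_t / cap; floor_p <- Pbar_p / cap
  qa_rows <- P_rows < floor_t; qa_cols <- P_cols < floor_p
  C_t_rows <- Pbar_t / pmax(P_rows, floor_t)
  C_p_cols <- Pbar_p / pmax(P_cols, floor_p)

  structure(list(
    C_theta = matrix(C_t_rows, nr, nc),
    C_phi = matrix(C_p_cols, nr, nc, byrow = TRUE),
    mask = g$mask,
    qa_capped = outer(qa_rows, rep(TRUE, nc)) |
      outer(rep(TRUE, nr), qa_cols),
    normalization = "mean-over-field = 1"),
    class = "correction_maps")
}

#' @export
print.correction_maps <- function(x, ...) {
  cat(sprintf(
    "<correction_maps> %d x %d px; C_theta in [%.2f, %.2f]; C_phi in [%.2f, %.2f]\n",
    nrow(x$C_theta), ncol(x$C_theta), min(x$C_theta), max(x$C_theta),
    min(x$C_phi), max(x$C_phi)))
  invisible(x)
}

#' Projected dose image
#'
#' A 2D image proportional to the dose summed along the camera optical
#' axis, with its tank-coordinate axes: `depth_cm` per row and `lateral_cm`
#' per column.
#'
#' @param dose non-negative matrix (relative dose units).
#' @param geometry the [camera_geometry()] defining the axes.
#' @return Object of class `projected_dose_image`.
#' @export
projected_dose_image <- function(dose, geometry) {
  g <- pixel_grid(geometry)
  stopifnot(nrow(dose) == geometry$image_size[1],
            ncol(dose) == geometry$image_size[2])
  if (any(dose < 0, na.rm = TRUE)) stop("dose must be non-negative")
  structure(list(dose = dose, depth_cm = g$depth, lateral_cm = g$lateral,
                 pixel_scale = geometry$pixel_scale, geometry = geometry),
            class = "projected_dose_image")
}

#' @export
print.projected_dose_image <- function(x, ...) {
  cat(sprintf(
    "<projected_dose_image> %d x %d px; depth %.1f-%.1f cm, lateral %.1f-%.1f cm\n",
    nrow(x$dose), ncol(x$dose), min(x$depth_cm), max(x$depth_cm),
    min(x$lateral_cm), max(x$lateral_cm)))
  invisible(x)
}

#' Apply the anisotropy correction to a polarized image
#'
#' Pixelwise D(x, y) proportional to C_theta * C_phi * I_pol: the corrected
#' polarized image is the projected-dose estimate. Pixels outside the tank
#' are masked to `NA`.
#'
#' @param I_pol polarized-intensity image (from [solve_four_angles()]).
#' @param maps a [build_correction_maps()] result, or `NULL` for the
#'   identity (raw polarized signal as dose).
#' @param geometry the [camera_geometry()].
#' @return A [projected_dose_image()].
#' @export
apply_correction <- function(I_pol, maps, geometry) {
  if (is.null(maps)) {
    dose <- I_pol
    g <- pixel_grid(geometry)
    dose[!g$mask] <- NA_real_
    return(projected_dose_image(dose, geometry))
  }
  stopifnot(inherits(maps, "correction_maps"),
            identical(dim(I_pol), dim(maps$C_theta)))
  dose <- I_pol * maps$C_theta * maps$C_phi
  dose[!maps$mask] <- NA_real_
  projected_dose_image(dose, geometry)
}
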