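# Binning of Cherenkov photon directions into polar/azimuthal angular
# distributions per scoring region.

#' Angular distribution of Cherenkov photon directions
#'
#' Histograms of the polar angle (measured from the beam axis, 0-180 deg)
#' and azimuth (measured around the beam axis, (-180, 180] deg with 0
#' toward the camera) of photons generated inside one scoring voxel.
#'
#' @param polar_counts counts per polar bin.
#' @param azimuth_counts counts per azimuth bin.
#' @param region list with `depth`, `off_axis` (cm) and `voxel` (cm).
#' @param polar_breaks,azimuth_breaks bin edges in degrees (uniform).
#' @return Object of class `angular_distribution` with `n_photons` equal to
#'   the polar histogram total.
#' @export
angular_distribution <- function(polar_counts, azimuth_counts, region,
                                 polar_breaks = seq(0, 180, by = 1),
                                 azimuth_breaks = seq(-180, 180, by = 5)) {
  stopifnot(length(polar_counts) == length(polar_breaks) - 1L,
            length(azimuth_counts) == length(azimuth_breaks) - 1L)
  structure(list(polar_counts = polar_counts,
                 azimuth_counts = azimuth_counts,
                 polar_breaks = polar_breaks,
                 azimuth_breaks = azimuth_breaks,
                 region = region, n_photons = sum(polar_counts)),
            class = "angular_distribution")
}

#' @export
print.angular_distribution <- function(x, ...) {
  cat(sprintf(
    "<angular_distribution> depth %.1f cm, off-axis %.1f cm: %d photons\n",
    x$region$depth, x$region$off_axis, x$n_photons))
  invisible(x)
}

# normalized density over polar bin centers (per degree); integrates to 1
polar_density <- function(dist) {
  w <- diff(dist$polar_breaks)
  centers <- dist$polar_breaks[-length(dist$polar_breaks)] + w / 2
  total <- sum(dist$polar_counts * w)
  dens <- if (total > 0) dist$polar_counts / total else
    rep(1 / sum(w), length(w))
  list(centers = centers, density = dens)
}

azimuth_density <- function(dist) {
  w <- diff(dist$azimuth_breaks)
  centers <- dist$azimuth_breaks[-length(dist$azimuth_breaks)] + w / 2
  total <- sum(dist$azimuth_counts * w)
  dens <- if (total > 0) dist$azimuth_counts / total else
    rep(1 / sum(w), length(w))
  list(centers = centers, density = dens)
}

#' Score photon directions into per-region angular distributions
#'
#' Bins the polar angle (vs the beam axis, +z) and azimuth (vs the camera
#' axis, +y; phi = 0 toward the camera) of all photons generated inside
#' each requested scoring voxel. With `camera_side_filter`, only photons
#' whose direction has a positive component toward the camera are kept — a
#' collection-efficiency filter for a camera on one side of the tank.
#'
#' @param photons a `cherenkov_photons` record.
#' @param regions list of scoring regions, each a list with `depth` and
#'   `off_axis` in cm (lateral x); or a numeric vector of depths (all
#'   on-axis).
#' @param voxel_cm cubic scoring voxel side (default 1 cm).
#' @param polar_bin,azimuth_bin bin widths in degrees.
#' @param camera_side_filter keep only camera-hemisphere photons
#'   (default TRUE).
#' @return List of [angular_distribution()] objects. Empty regions give
#'   zero histograms with attribute `"empty" = TRUE`.
#' @export
score_distributions <- function(photons, regions, voxel_cm = 1,
                                polar_bin = 1, azimuth_bin = 5,
                                camera_side_filter = TRUE) {
  if (is.numeric(regions))
    regions <- lapply(regions, function(d) list(depth = d, off_axis = 0))
  pb <- seq(0, 180, by = polar_bin)
  ab <- seq(-180, 180, by = azimuth_bin)
  pos <- photons$position; dir <- photons$direction
  keep0 <- if (camera_side_filter && nrow(dir) > 0) dir[, 2] > 0 else
    rep(TRUE, nrow(pos))
  lapply(regions, function(rg) {
    half <- voxel_cm / 2
    sel <- keep0 &
      abs(pos[, 3] - rg$depth) <= half &
      abs(pos[, 1] - rg$off_axis) <= half &
      abs(pos[, 2]) <= half
    d <- dir[sel, , drop = FALSE]
    if (nrow(d) == 0L) {
      ad <- angular_distribution(numeric(length(pb) - 1L),
                                 numeric(length(ab) - 1L),
                                 region = list(depth = rg$depth,
                                               off_axis = rg$off_axis,
                                               voxel = voxel_cm),
                                 polar_breaks = pb, azimuth_breaks = ab)
      attr(ad, "empty") <- TRUE
      return(ad)
    }
    polar <- acos(pmin(1, pmax(-1, d[, 3]))) * 180 / pi
    azim <- atan2(d[, 1], d[, 2]) * 180 / pi
    azim[azim <= -180] <- 180
    pidx <- pmin(pmax(findInterval(polar, pb, rightmost.closed = TRUE), 1L),
                 length(pb) - 1L)
    aidx <- pmin(pmax(findInterval(azim, ab, rightmost.closed = TRUE), 1L),
                 length(ab) - 1L)
    pc <- tabulate(pidx, nbins = length(pb) - 1L)
    ac <- tabulate(aidx, nbins = length(ab) - 1L)
    angular_distribution(pc, ac,
                         region = list(depth = rg$depth,
                                       off_axis = rg$off_axis,
                                       voxel = voxel_cm),
                         polar_breaks = pb, azimuth_breaks = ab)
  })
}

#' Mode of the polar histogram
#'
#' Lower edge (degrees) of the maximal polar-angle bin — the headline
#' summary of an angular distribution (about 41 deg for all therapy beams
#' at shallow depth in water).
#'
#' @param dist an [angular_distribution()].
#' @return Lower bin edge in degrees.
#' @export
polar_mode <- function(dist) {
  stopifnot(inherits(dist, "angular_distribution"))
  i <- which.max(dist$polar_counts)
  dist$polar_breaks[i]
}
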