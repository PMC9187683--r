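# Curve extraction and comparison: projected percent depth dose (PPDD),
# lateral profiles at d_max, FWHM field size, and difference statistics.

#' Dose curve
#'
#' A 1D normalized dose curve: a PPDD (values normalized to 100 at the
#' maximum, positions = depth) or a lateral profile (normalized to 100 on
#' the central axis, positions = off-axis distance).
#'
#' @param positions strictly increasing positions in cm.
#' @param values dose values in percent.
#' @param kind `"ppdd"` or `"profile"`.
#' @param anchor normalization anchor (e.g. d_max depth or `0` for the
#'   central axis).
#' @return Object of class `dose_curve` (also a data frame).
#' @export
dose_curve <- function(positions, values, kind = c("ppdd", "profile"),
                       anchor = NA_real_) {
  kind <- match.arg(kind)
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  structure(data.frame(position = positions, value = values),
            kind = kind, anchor = anchor,
            class = c("dose_curve", "data.frame"))
}

#' @export
print.dose_curve <- function(x, ...) {
  cat(sprintf("<dose_curve> %s, %d points, %.2f-%.2f cm (anchor %.2f)\n",
              attr(x, "kind"), nrow(x), min(x$position), max(x$position),
              attr(x, "anchor")))
  invisible(x)
}

#' Projected percent depth dose
#'
#' Sums the dose laterally over a window centred on the beam axis for each
#' depth row, then normalizes to 100 at the maximum. The depth of maximum
#' dose (d_max) is stored as the curve's anchor.
#'
#' @param dose a [projected_dose_image()].
#' @param lateral_window full lateral summation width in cm (default: the
#'   whole image width — dose summed along the beam width).
#' @return A [dose_curve()] of kind `"ppdd"`.
#' @export
extract_ppdd <- function(dose, lateral_window = NULL) {
  stopifnot(inherits(dose, "projected_dose_image"))
  lat <- dose$lateral_cm
  keep <- if (is.null(lateral_window)) rep(TRUE, length(lat)) else
    abs(lat) <= lateral_window / 2
  if (!any(keep)) stop("empty lateral window")
  rows_ok <- rowSums(is.finite(dose$dose[, keep, drop = FALSE])) > 0
  if (!any(rows_ok)) stop("no valid depth rows")
  vals <- rowSums(dose$dose[rows_ok, keep, drop = FALSE], na.rm = TRUE)
  pos <- dose$depth_cm[rows_ok]
  vals <- 100 * vals / max(vals)
  dose_curve(pos, vals, kind = "ppdd", anchor = pos[which.max(vals)])
}

#' Depth of maximum dose
#'
#' @param curve a PPDD [dose_curve()].
#' @return d_max in cm.
#' @export
d_max <- function(curve) {
  stopifnot(inherits(curve, "dose_curve"))
  curve$position[which.max(curve$value)]
}

#' Lateral profile at a given depth
#'
#' Averages dose rows within a depth window centred on `depth`, then
#' normalizes to 100 on the central axis (lateral position nearest zero).
#'
#' @param dose a [projected_dose_image()].
#' @param depth profile depth in cm (typically d_max).
#' @param averaging_window full depth-averaging width in cm (default: one
#'   pixel row).
#' @return A [dose_curve()] of kind `"profile"`.
#' @export
extract_profile <- function(dose, depth, averaging_window = NULL) {
  stopifnot(inherits(dose, "projected_dose_image"))
  z <- dose$depth_cm
  if (depth < min(z) || depth > max(z)) stop("depth outside image")
  keep <- if (is.null(averaging_window)) {
    seq_along(z) == which.min(abs(z - depth))
  } else abs(z - depth) <= averaging_window / 2
  vals <- colMeans(dose$dose[keep, , drop = FALSE], na.rm = TRUE)
  ok <- is.finite(vals)
  lat <- dose$lateral_cm[ok]; vals <- vals[ok]
  cax <- vals[which.min(abs(lat))]
  if (cax <= 0) stop("no signal on the central axis at this depth")
  dose_curve(lat, 100 * vals / cax, kind = "profile", anchor = 0)
}

#' Field size as full width at half maximum
#'
#' Linear-interpolated width of a profile at 50% of its central-axis value.
#'
#' @param profile a profile [dose_curve()].
#' @return Field size in cm.
#' @export
fwhm_field_size <- function(profile) {
  stopifnot(inherits(profile, "dose_curve"))
  x <- profile$position; y <- profile$value
  half <- y[which.min(abs(x))] / 2
  icax <- which.min(abs(x))
  cross_left <- which(y[seq_len(icax - 1)] < half & y[seq_len(icax - 1) + 1] >= half)
  cross_right <- which(y[icax:(length(y) - 1)] >= half &
                         y[(icax + 1):length(y)] < half) + icax - 1
  if (length(cross_left) == 0L || length(cross_right) == 0L)
    stop("profile does not cross 50% on both sides")
  li <- max(cross_left); ri <- min(cross_right)
  xl <- x[li] + (half - y[li]) / (y[li + 1] - y[li]) * (x[li + 1] - x[li])
  xr <- x[ri] + (half - y[ri]) / (y[ri + 1] - y[ri]) * (x[ri + 1] - x[ri])
  xr - xl
}

#' Difference statistics between a measured and a reference curve
#'
#' Resamples the measured curve onto the reference positions by linear
#' interpolation and reports mean and standard deviation of
#' measured - reference, in percentage points of the normalized dose.
#' Optionally restricted to a position region.
#'
#' @param measured,reference [dose_curve()] objects of the same kind.
#' @param region optional `c(min, max)` positions in cm.
#' @return Named vector `c(mean = , sd = )` in percentage points.
#' @export
difference_stats <- function(measured, reference, region = NULL) {
  stopifnot(inherits(measured, "dose_curve"), inherits(reference, "dose_curve"))
  lo <- max(min(measured$position), min(reference$position))
  hi <- min(max(measured$position), max(reference$position))
  if (lo >= hi) stop("curves have disjoint supports")
  pos <- reference$position[reference$position >= lo &
                              reference$position <= hi]
  if (!is.null(region)) pos <- pos[pos >= region[1] & pos <= region[2]]
  if (length(pos) == 0L) stop("empty comparison region")
  m <- approx(measured$position, measured$value, xout = pos)$y
  r <- approx(reference$position, reference$value, xout = pos)$y
  diff <- m - r
  c(mean = mean(diff), sd = if (length(diff) > 1L) sd(diff) else 0)
}
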