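# Raw-frame preprocessing: temporal median filtering, background
# subtraction, cos^4 vignetting (flat-field) fit and correction.
# Pipeline order is median -> background -> flat-field.

#' Pixelwise temporal median of a frame sequence
#'
#' The temporal median across repeated exposures removes transient spikes
#' (stray-radiation hits on the sensor) that affect isolated pixels in
#' individual frames.
#'
#' @param frames list of numeric matrices with identical shape.
#' @return A single matrix of per-pixel medians.
#' @export
temporal_median <- function(frames) {
  if (!is.list(frames) || length(frames) < 1L) stop("need >= 1 frame")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("frame shape mismatch")
  if (length(frames) == 1L) return(frames[[1]])
  arr <- array(unlist(frames), dim = c(d, length(frames)))
  apply(arr, c(1, 2), median)
}

#' Background subtraction
#'
#' Averages the background frames and subtracts them from the signal image,
#' clamping negative results to zero. If exposures differ the background is
#' scaled by the exposure ratio first (with a warning).
#'
#' @param signal signal image (matrix).
#' @param background_frames list of background frames (or a single matrix).
#' @param signal_exposure,background_exposure integration times in seconds.
#' @return The background-subtracted image with attribute
#'   `"negative_fraction"`: the fraction of pixels clamped at zero.
#' @export
subtract_background <- function(signal, background_frames,
                                signal_exposure = NULL,
                                background_exposure = NULL) {
  if (is.matrix(background_frames)) background_frames <- list(background_frames)
  d <- dim(signal)
  if (!all(vapply(background_frames, function(f) identical(dim(f), d),
                  logical(1))))
    stop("background shape mismatch")
  bg <- Reduce(`+`, background_frames) / length(background_frames)
  if (!is.null(signal_exposure) && !is.null(background_exposure) &&
      signal_exposure != background_exposure) {
    warning("exposure mismatch: scaling background by exposure ratio")
    bg <- bg * signal_exposure / background_exposure
  }
  out <- signal - bg
  negfrac <- mean(out < 0)
  out[out < 0] <- 0
  attr(out, "negative_fraction") <- negfrac
  out
}

#' cos^4 vignetting model
#'
#' Radially symmetric sensitivity fall-off of a lens-sensor system:
#' response = A cos^4(theta_ij) with theta_ij = arctan(r_ij / f), where
#' r_ij is the pixel distance to the optical center and f an effective
#' focal-length scale in pixels. Equivalently A / (1 + (r/f)^2)^2.
#'
#' @param center optical center `(i, j)` in pixel coordinates.
#' @param f scale parameter in pixels (> 0).
#' @param amplitude response at the optical center, counts.
#' @return An object of class `vignette_model`.
#' @export
vignette_model <- function(center, f, amplitude = 1) {
  if (f <= 0) stop("f must be > 0")
  structure(list(center = center, f = f, amplitude = amplitude),
            class = "vignette_model")
}

# model surface on an nr x nc grid
vignette_surface <- function(model, nr, nc) {
  r2 <- outer((seq_len(nr) - model$center[1])^2,
              (seq_len(nc) - model$center[2])^2, `+`)
  model$amplitude / (1 + r2 / model$f^2)^2
}

#' Fit the cos^4 vignetting model to a flat-field image
#'
#' Least-squares fit of A cos^4(arctan(r/f)) to an image of a uniform
#' emitter. The optical center is a fitted parameter, initialised at the
#' image center.
#'
#' @param flat_image flat-field image (matrix) from a uniform emitter.
#' @return A [vignette_model()] with attribute `"rms_residual"`.
#' @export
fit_vignette <- function(flat_image) {
  nr <- nrow(flat_image); nc <- ncol(flat_image)
  df <- data.frame(i = rep(seq_len(nr), nc),
                   j = rep(seq_len(nc), each = nr),
                   y = as.vector(flat_image))
  start <- list(ci = (nr + 1) / 2, cj = (nc + 1) / 2,
                f = max(nr, nc), A = max(flat_image))
  fit <- try(minpack.lm::nlsLM(
    y ~ A / (1 + ((i - ci)^2 + (j - cj)^2) / f^2)^2, data = df,
    start = start, lower = c(-Inf, -Inf, 1e-6, 0),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("vignette fit failed to converge: ", attr(fit, "condition")$message)
  cf <- coef(fit)
  m <- vignette_model(center = c(unname(cf["ci"]), unname(cf["cj"])),
                      f = unname(cf["f"]), amplitude = unname(cf["A"]))
  attr(m, "rms_residual") <- sqrt(mean(resid(fit)^2))
  m
}

#' Apply a flat-field correction
#'
#' Divides the image by the vignetting model normalized to 1 at the optical
#' center, so the center value is unchanged and off-center pixels are
#' boosted.
#'
#' @param image image to correct.
#' @param model a [vignette_model()], typically from [fit_vignette()].
#' @return Corrected image.
#' @export
apply_flat <- function(image, model) {
  stopifnot(inherits(model, "vignette_model"))
  norm <- vignette_surface(model, nrow(image), ncol(image)) / model$amplitude
  image / norm
}

#' Preprocess a raw acquisition into a clean intensity image
#'
#' Fixed-order pipeline: temporal median over signal frames, background
#' subtraction (averaged background frames), then cos^4 flat-field
#' correction from the supplied flat frame. Idempotent on already-clean
#' images (a single clean frame, zero background, uniform flat).
#'
#' @param signal_frames list of raw signal frames.
#' @param background_frames list of background frames (optional).
#' @param flat_image flat-field frame from a uniform emitter (optional);
#'   alternatively pass a prefit model via `vignette`.
#' @param vignette a [vignette_model()] to use instead of fitting
#'   `flat_image`.
#' @return Clean intensity image (matrix).
#' @export
preprocess_frames <- function(signal_frames, background_frames = NULL,
                              flat_image = NULL, vignette = NULL) {
  img <- temporal_median(signal_frames)
  if (!is.null(background_frames))
    img <- subtract_background(img, background_frames)
  if (is.null(vignette) && !is.null(flat_image))
    vignette <- fit_vignette(flat_image)
  if (!is.null(vignette)) img <- apply_flat(img, vignette)
  img
}
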