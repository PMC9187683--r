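# Per-pixel Malus-law decomposition of four-angle polarizer stacks into
# polarized amplitude, unpolarized offset, DoLP and AoLP.

#' Four-angle polarized image stack
#'
#' Container for co-registered intensity images acquired through a rotating
#' linear polarizer, one image per polarizer angle (two orthogonal pairs
#' 0/90 and 45/135 degrees by default).
#'
#' @param frames named list of non-negative numeric matrices, all the same
#'   shape; names are the polarizer angles in degrees (e.g. `"0"`, `"45"`,
#'   `"90"`, `"135"`).
#' @param pixel_scale pixel size in mm/pixel.
#' @param exposure integration time in seconds per frame.
#' @return An object of class `polarized_stack`.
#' @export
polarized_stack <- function(frames, pixel_scale = 0.26, exposure = 30) {
  stopifnot(is.list(frames), !is.null(names(frames)))
  angles <- as.numeric(names(frames))
  if (anyNA(angles)) stop("frame names must be polarizer angles in degrees")
  if (length(unique(angles %% 180)) < 3L)
    stop("need at least 3 distinct polarizer angles (mod 180)")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same shape")
  if (any(vapply(frames, function(f) any(f < 0, na.rm = TRUE), logical(1))))
    stop("intensities must be non-negative after preprocessing")
  structure(list(frames = frames, angles = angles,
                 pixel_scale = pixel_scale, exposure = exposure),
            class = "polarized_stack")
}

#' @export
print.polarized_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<polarized_stack> %d x %d px, angles [%s] deg, %.2f mm/px\n",
              d[1], d[2], paste(x$angles, collapse = ", "), x$pixel_scale))
  invisible(x)
}

#' Malus-law forward model with unpolarized offset
#'
#' Transmitted intensity through an ideal linear polarizer at angle
#' `alpha0` for light with polarized component `I_pol` at polarization
#' angle `alpha` plus an unpolarized (DC) component:
#' I = I_pol cos^2(alpha0 - alpha) + I_unpol.
#'
#' @param I_pol,I_unpol polarized and unpolarized intensities (counts, >= 0).
#' @param alpha0 polarizer transmission-axis angle, degrees.
#' @param alpha angle of linear polarization of the light, degrees.
#' @return Intensity in counts; periodic with period 180 deg in
#'   `alpha0 - alpha`.
#' @examples
#' malus_intensity(2, 1, 45, 0)  # 2
#' @export
malus_intensity <- function(I_pol, I_unpol, alpha0, alpha) {
  if (any(I_pol < 0) || any(I_unpol < 0)) stop("intensities must be >= 0")
  I_pol * cos((alpha0 - alpha) * pi / 180)^2 + I_unpol
}

#' Closed-form Malus decomposition of a four-angle stack
#'
#' For polarizer angles \{0, 45, 90, 135\} the Malus model has the exact
#' per-pixel solution
#' Q = I(0) - I(90), U = I(45) - I(135), I_pol = sqrt(Q^2 + U^2),
#' AoLP = atan2(U, Q) / 2, I_unpol = (I(0) + I(90) - I_pol) / 2,
#' with DoLP = 100 I_pol / (I_pol + I_unpol). The model-consistency defect
#' |(I(0) + I(90)) - (I(45) + I(135))|, which is identically zero for data
#' generated by the model, is returned as a per-pixel residual.
#'
#' The fitted DC term is taken as the unpolarized contribution: the physical
#' factor-1/2 transmission of unpolarized light through the polarizer is
#' absorbed into it, matching the DoLP = I_pol / I_tot x 100 convention with
#' I_tot = I_pol + I_unpol.
#'
#' Noise can drive the DC term negative; such pixels are clamped to 0 and
#' flagged in the QA mask. All-zero pixels have DoLP 0 and masked AoLP.
#' Stacks whose angles are not exactly \{0, 45, 90, 135\} fall back to
#' per-pixel nonlinear fitting with [fit_general()].
#'
#' @param stack a [polarized_stack()].
#' @return An object of class `polarimetry_maps` with matrices `I_pol`,
#'   `I_unpol`, `dolp` (percent), `aolp` (degrees in (-90, 90]),
#'   `fit_residual`, and a logical `qa_mask` of flagged pixels.
#' @examples
#' f <- lapply(c(0, 45, 90, 135), function(a)
#'   matrix(malus_intensity(2, 1, a, 0), 2, 2))
#' names(f) <- c("0", "45", "90", "135")
#' m <- solve_four_angles(polarized_stack(f))
#' m$dolp[1, 1]  # 66.7 %
#' @export
solve_four_angles <- function(stack) {
  stopifnot(inherits(stack, "polarized_stack"))
  std <- c(0, 45, 90, 135)
  if (!setequal(stack$angles %% 180, std) || length(stack$angles) != 4L)
    return(solve_stack_general(stack))
  fr <- stack$frames[order(match(stack$angles %% 180, std))]
  I0 <- fr[[1]]; I45 <- fr[[2]]; I90 <- fr[[3]]; I135 <- fr[[4]]

  Q <- I0 - I90
  U <- I45 - I135
  I_pol <- sqrt(Q^2 + U^2)
  aolp <- atan2(U, Q) * 90 / pi            # half-angle, (-90, 90]
  I_unpol_raw <- (I0 + I90 - I_pol) / 2
  qa_mask <- I_unpol_raw < 0
  I_unpol <- pmax(I_unpol_raw, 0)
  tot <- I_pol + I_unpol
  dolp <- ifelse(tot > 0, 100 * I_pol / tot, 0)
  aolp[I_pol == 0] <- NA_real_             # AoLP undefined without signal
  residual <- abs((I0 + I90) - (I45 + I135))

  polarimetry_maps(I_pol, I_unpol, dolp, aolp, residual, qa_mask,
                   pixel_scale = stack$pixel_scale)
}

polarimetry_maps <- function(I_pol, I_unpol, dolp, aolp, fit_residual,
                             qa_mask, pixel_scale = NA_real_) {
  structure(list(I_pol = I_pol, I_unpol = I_unpol, dolp = dolp, aolp = aolp,
                 fit_residual = fit_residual, qa_mask = qa_mask,
                 pixel_scale = pixel_scale),
            class = "polarimetry_maps")
}

#' @export
print.polarimetry_maps <- function(x, ...) {
  cat(sprintf(
    "<polarimetry_maps> %d x %d px; DoLP mean %.1f%%; %d flagged pixel(s)\n",
    nrow(x$dolp), ncol(x$dolp), mean(x$dolp, na.rm = TRUE), sum(x$qa_mask)))
  invisible(x)
}

#' General Malus fit for arbitrary polarizer angles
#'
#' Bounded nonlinear least squares of the Malus model
#' I(alpha0) = I_pol cos^2(alpha0 - alpha) + I_unpol for a single pixel
#' measured at three or more distinct polarizer angles. On exact four-angle
#' model data this agrees with the closed form of [solve_four_angles()].
#'
#' @param alpha0 polarizer angles in degrees.
#' @param values measured intensities at those angles.
#' @param start optional named list with starting values `I_pol`, `I_unpol`,
#'   `alpha`; a closed-form-style initialisation is used by default.
#' @return List with `I_pol`, `I_unpol`, `alpha` (degrees, (-90, 90]; `NA`
#'   when the polarized amplitude is zero) and the residual sum of squares.
#' @export
fit_general <- function(alpha0, values, start = NULL) {
  keep <- is.finite(values)
  alpha0 <- alpha0[keep]; values <- values[keep]
  if (length(unique(alpha0 %% 180)) < 3L)
    stop("underdetermined: need >= 3 distinct polarizer angles (mod 180)")
  # linear reformulation: I = a + b cos(2 alpha0) + c sin(2 alpha0), with
  # I_pol = 2 sqrt(b^2 + c^2), I_unpol = a - I_pol / 2, alpha = atan2(c, b)/2
  X <- cbind(1, cos(2 * alpha0 * pi / 180), sin(2 * alpha0 * pi / 180))
  beta <- tryCatch(qr.solve(X, values), error = function(e)
    stop("degenerate angle design: ", conditionMessage(e)))
  a <- beta[1]; b <- beta[2]; cc <- beta[3]
  I_pol <- 2 * sqrt(b^2 + cc^2)
  alpha <- atan2(cc, b) * 90 / pi
  I_unpol <- a - I_pol / 2
  if (I_unpol < 0 || I_pol < 0) {
    # refit on the bounded nonlinear form
    st <- start
    if (is.null(st))
      st <- list(I_pol = max(I_pol, 1e-9), I_unpol = max(I_unpol, 0),
                 alpha = ifelse(is.finite(alpha), alpha, 0))
    df <- data.frame(a0 = alpha0, y = values)
    fit <- try(minpack.lm::nlsLM(
      y ~ Ip * cos((a0 - al) * pi / 180)^2 + Iu, data = df,
      start = list(Ip = st$I_pol, Iu = st$I_unpol, al = st$alpha),
      lower = c(0, 0, -360), upper = c(Inf, Inf, 360),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- coef(fit)
      I_pol <- unname(cf["Ip"]); I_unpol <- unname(cf["Iu"])
      alpha <- ((unname(cf["al"]) + 90) %% 180) - 90
    } else {
      I_pol <- max(I_pol, 0); I_unpol <- max(I_unpol, 0)
    }
  }
  pred <- I_pol * cos((alpha0 - alpha) * pi / 180)^2 + I_unpol
  if (I_pol < 1e-12 * max(1, I_unpol)) alpha <- NA_real_
  list(I_pol = I_pol, I_unpol = I_unpol, alpha = alpha,
       residual = sum((values - pred)^2))
}

# Per-pixel general fit over a whole stack (fallback for non-standard
# angle sets; O(npixels) nonlinear fits, intended for small images).
solve_stack_general <- function(stack) {
  d <- dim(stack$frames[[1]])
  arr <- vapply(stack$frames, identity, matrix(0, d[1], d[2]))
  I_pol <- I_unpol <- aolp <- res <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    f <- fit_general(stack$angles, arr[i, j, ])
    I_pol[i, j] <- f$I_pol; I_unpol[i, j] <- f$I_unpol
    aolp[i, j] <- if (is.na(f$alpha)) NA_real_ else f$alpha
    res[i, j] <- sqrt(f$residual)
  }
  tot <- I_pol + I_unpol
  dolp <- ifelse(tot > 0, 100 * I_pol / tot, 0)
  polarimetry_maps(I_pol, I_unpol, dolp, aolp, res,
                   qa_mask = matrix(FALSE, d[1], d[2]),
                   pixel_scale = stack$pixel_scale)
}

#' Extract DoLP / AoLP maps
#'
#' Accessors returning the degree of linear polarization
#' (DoLP = I_pol / (I_pol + I_unpol) x 100, percent in `[0, 100]`) and the
#' angle of linear polarization (degrees in (-90, 90], 0 = first polarizer
#' axis) from a [solve_four_angles()] result. Pixels without signal carry
#' DoLP 0 and a masked (`NA`) AoLP.
#'
#' @param maps a `polarimetry_maps` object.
#' @return A numeric matrix.
#' @export
dolp_map <- function(maps) {
  stopifnot(inherits(maps, "polarimetry_maps"))
  maps$dolp
}

#' @rdname dolp_map
#' @export
aolp_map <- function(maps) {
  stopifnot(inherits(maps, "polarimetry_maps"))
  maps$aolp
}

#' DoLP statistics over a region of interest
#'
#' Mean and standard deviation of the DoLP over an ROI, the statistic used
#' to characterise Cherenkov versus scintillation polarization (reported as
#' mean +/- STD in percent over a 1 x 1 cm^2 region).
#'
#' @param maps a `polarimetry_maps` object.
#' @param roi either a logical matrix the size of the image, or a list with
#'   integer vectors `rows` and `cols` selecting a rectangle.
#' @return Named numeric vector `c(mean = , sd = )` in percent.
#' @export
region_dolp_stats <- function(maps, roi) {
  stopifnot(inherits(maps, "polarimetry_maps"))
  d <- dolp_map(maps)
  if (is.matrix(roi)) {
    if (!identical(dim(roi), dim(d))) stop("roi mask shape mismatch")
    vals <- d[roi]
  } else {
    if (any(roi$rows < 1 | roi$rows > nrow(d)) ||
        any(roi$cols < 1 | roi$cols > ncol(d)))
      stop("roi outside image")
    vals <- d[roi$rows, roi$cols]
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("empty roi")
  c(mean = mean(vals), sd = if (length(vals) > 1L) sd(vals) else 0)
}
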