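# On-disk layout for acquisitions: one multi-page 32-bit float TIFF per
# polarizer angle plus background/flat TIFFs, with a YAML sidecar carrying
# the angles, pixel scale, exposure and the count scaling (TIFF float
# samples are stored in [0, 1]; counts_max in the sidecar restores counts).

write_tiff_pages <- function(frames, path, counts_max) {
  if (is.matrix(frames)) frames <- list(frames)
  scaled <- lapply(frames, function(f) pmin(pmax(f / counts_max, 0), 1))
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  invisible(path)
}

read_tiff_pages <- function(path, counts_max) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(p) p * counts_max)
}

#' Write a rendered acquisition to a directory
#'
#' Writes one multi-page TIFF per polarizer angle (`angle_000.tiff`, ...),
#' `background.tiff`, `flat.tiff` and a `stack.yaml` sidecar with the
#' acquisition metadata.
#'
#' @param rendered result of [render_stack()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_acquisition <- function(rendered, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scn <- rendered$scenario
  counts_max <- max(vapply(rendered$frames,
                           function(fl) max(vapply(fl, max, numeric(1))),
                           numeric(1)),
                    max(rendered$flat_frame)) * 1.05
  files <- list()
  for (a in names(rendered$frames)) {
    fn <- sprintf("angle_%03d.tiff", as.integer(a))
    write_tiff_pages(rendered$frames[[a]], file.path(dir, fn), counts_max)
    files[[a]] <- fn
  }
  write_tiff_pages(rendered$background_frames,
                   file.path(dir, "background.tiff"), counts_max)
  write_tiff_pages(rendered$flat_frame, file.path(dir, "flat.tiff"),
                   counts_max)
  meta <- list(angles = as.numeric(names(rendered$frames)),
               files = files, background = "background.tiff",
               flat = "flat.tiff", counts_max = counts_max,
               pixel_scale_mm = scn$pixel_scale, exposure_s = scn$exposure,
               beam = scn$beam)
  yaml::write_yaml(meta, file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' Read an acquisition directory
#'
#' Reads the layout written by [write_acquisition()].
#'
#' @param dir acquisition directory containing `stack.yaml`.
#' @return List with `frames` (per-angle lists of matrices),
#'   `background_frames`, `flat_frame`, and the sidecar metadata.
#' @export
read_acquisition <- function(dir) {
  meta_path <- file.path(dir, "stack.yaml")
  if (!file.exists(meta_path)) stop("missing sidecar: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  cm <- meta$counts_max
  frames <- lapply(meta$files, function(fn)
    read_tiff_pages(file.path(dir, fn), cm))
  names(frames) <- as.character(meta$angles)
  list(frames = frames,
       background_frames = read_tiff_pages(file.path(dir, meta$background),
                                           cm),
       flat_frame = read_tiff_pages(file.path(dir, meta$flat), cm)[[1]],
       meta = meta)
}
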