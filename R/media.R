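#' Optical medium for Cherenkov emission
#'
#' A medium is described by its refractive index (the only quantity entering
#' the Cherenkov emission condition), its mass density and its radiation
#' length (used by the multiple-scattering model during electron transport).
#'
#' @param name character label.
#' @param refractive_index phase refractive index n; must exceed 1 for
#'   Cherenkov emission to be possible.
#' @param density mass density in g/cm^3.
#' @param radiation_length radiation length in g/cm^2.
#' @return An object of class `medium`.
#' @examples
#' medium("water", 1.33, 1.0, 36.08)
#' @export
medium <- function(name, refractive_index, density, radiation_length) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(refractive_index) || refractive_index <= 1)
    stop("refractive_index must be > 1 for Cherenkov emission to be possible")
  if (!is.finite(density) || density <= 0) stop("density must be > 0")
  if (!is.finite(radiation_length) || radiation_length <= 0)
    stop("radiation_length must be > 0")
  structure(
    list(name = name, refractive_index = refractive_index,
         density = density, radiation_length = radiation_length),
    class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %s: n = %.3f, rho = %.3f g/cm^3, X0 = %.2f g/cm^2\n",
              x$name, x$refractive_index, x$density, x$radiation_length))
  invisible(x)
}

#' Built-in media table
#'
#' Reads the small constants table shipped with the package (water and
#' polyvinyl toluene, the plastic-scintillator base).
#'
#' @param name optional medium name; if omitted, the full table is returned
#'   as a data frame.
#' @return A `medium` object, or a data frame listing all media.
#' @examples
#' cherenkov_media("water")
#' @export
cherenkov_media <- function(name = NULL) {
  path <- system.file("extdata", "media.csv", package = "cherenkovpol",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(name)) return(tab)
  row <- tab[tab$name == name, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown medium '", name, "'; known: ",
         paste(tab$name, collapse = ", "))
  medium(row$name, row$refractive_index, row$density, row$radiation_length)
}

#' @rdname cherenkov_media
#' @export
water_medium <- function() cherenkov_media("water")
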