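#' Screen and viewing geometry
#'
#' Bundles the screen resolution, its physical size and the viewing distance.
#' All pixel-to-visual-angle conversions in the package go through this
#' object, so the geometry is stated once per recording.
#'
#' The default corresponds to a 22-inch 16:10 monitor (1680 x 1050 px,
#' 47.4 x 29.6 cm) viewed from 50 cm, the typical toddler set-up for a
#' remote eye tracker mounted under the screen.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_cm,height_cm Physical screen size in centimetres.
#' @param viewing_distance_cm Eye-to-screen distance in centimetres.
#'
#' @return An object of class `screen_geometry` (a named list).
#' @examples
#' geom <- screen_geometry()
#' px_to_deg(31, geom) # about one degree of visual angle
#' @export
screen_geometry <- function(width_px = 1680, height_px = 1050,
                            width_cm = 47.4, height_cm = 29.6,
                            viewing_distance_cm = 50) {
  vals <- c(width_px, height_px, width_cm, height_cm, viewing_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be positive and finite", call. = FALSE)
  }
  structure(
    list(
      width_px = width_px, height_px = height_px,
      width_cm = width_cm, height_cm = height_cm,
      viewing_distance_cm = viewing_distance_cm
    ),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %d x %d px, %.1f x %.1f cm, viewed at %.1f cm\n",
    x$width_px, x$height_px, x$width_cm, x$height_cm, x$viewing_distance_cm
  ))
  invisible(x)
}

#' Convert a pixel extent to visual angle
#'
#' Uses the full subtended angle `2 * atan(size_cm / 2 / distance_cm)`.
#' Horizontal pixel pitch is assumed; for the near-square pixels of common
#' panels the horizontal/vertical difference is negligible and a single
#' pitch keeps the conversion invertible.
#'
#' @param px Extent in pixels (vector allowed).
#' @param geometry A [screen_geometry()].
#' @return Visual angle in degrees.
#' @export
px_to_deg <- function(px, geometry) {
  cm <- px * geometry$width_cm / geometry$width_px
  2 * atan2(cm / 2, geometry$viewing_distance_cm) * 180 / pi
}

#' Convert a visual angle to a pixel extent
#'
#' Inverse of [px_to_deg()].
#' @inheritParams px_to_deg
#' @param deg Visual angle in degrees.
#' @export
deg_to_px <- function(deg, geometry) {
  cm <- 2 * geometry$viewing_distance_cm * tan(deg / 2 * pi / 180)
  cm * geometry$width_px / geometry$width_cm
}
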