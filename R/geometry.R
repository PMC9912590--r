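#' Screen geometry of the eye-tracking setup
#'
#' Describes the physical display and viewing configuration needed to convert
#' between screen pixels, millimetres on the display surface, and degrees of
#' visual angle. Defaults correspond to a remote-eye-tracker setup with a
#' fixed display area of 345 x 259 mm viewed from 650 mm.
#'
#' @param display_width_mm,display_height_mm Physical display area in mm.
#' @param width_px,height_px Display resolution in pixels. The pixel aspect
#'   ratio must agree with the mm aspect ratio within 1% (square pixels).
#' @param viewing_distance_mm Eye-to-screen distance in mm.
#' @param sampling_rate_hz Eye-tracker sampling rate; must be 120 or 300.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' px_to_deg(geom$width_px, geom) # full screen width in visual angle
#' @export
screen_geometry <- function(display_width_mm = 345,
                            display_height_mm = 259,
                            width_px = 1280,
                            height_px = 961,
                            viewing_distance_mm = 650,
                            sampling_rate_hz = 120) {
  vals <- c(display_width_mm, display_height_mm, width_px, height_px,
            viewing_distance_mm, sampling_rate_hz)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry fields must be finite and strictly positive")
  }
  if (!sampling_rate_hz %in% c(120, 300)) {
    stop("sampling_rate_hz must be 120 or 300")
  }
  aspect_mm <- display_width_mm / display_height_mm
  aspect_px <- width_px / height_px
  if (abs(aspect_px / aspect_mm - 1) > 0.01) {
    stop("pixel aspect ratio inconsistent with physical aspect ratio (> 1%)")
  }
  structure(
    list(display_width_mm = display_width_mm,
         display_height_mm = display_height_mm,
         width_px = width_px,
         height_px = height_px,
         viewing_distance_mm = viewing_distance_mm,
         sampling_rate_hz = sampling_rate_hz,
         mm_per_px = display_width_mm / width_px),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("screen_geometry: %g x %g mm (%d x %d px) at %g mm, %g Hz\n",
              x$display_width_mm, x$display_height_mm, x$width_px, x$height_px,
              x$viewing_distance_mm, x$sampling_rate_hz))
  invisible(x)
}

#' Convert on-screen displacements between pixels, mm and degrees
#'
#' Angles subtended at the eye are computed by the arctangent of the metric
#' on-screen displacement over the viewing distance, so a displacement of the
#' full 345 mm screen width at 650 mm subtends
#' `2 * atan(172.5 / 650)` = 29.7 degrees (two half-width arctangents).
#' For displacement vectors (the typical sample-to-sample case) the single
#' arctangent `atan(d / D)` is used.
#'
#' @param px,mm,deg Displacement magnitude in the source unit.
#' @param geometry A [screen_geometry()].
#' @return Displacement in the target unit.
#' @name angle_conversion
NULL

#' @rdname angle_conversion
#' @export
px_to_mm <- function(px, geometry) px * geometry$mm_per_px

#' @rdname angle_conversion
#' @export
mm_to_px <- function(mm, geometry) mm / geometry$mm_per_px

#' @rdname angle_conversion
#' @export
mm_to_deg <- function(mm, geometry) {
  # symmetric subtense: split the chord about the line of sight
  2 * atan2(mm / 2, geometry$viewing_distance_mm) * 180 / pi
}

#' @rdname angle_conversion
#' @export
deg_to_mm <- function(deg, geometry) {
  2 * geometry$viewing_distance_mm * tan(deg / 2 * pi / 180)
}

#' @rdname angle_conversion
#' @export
px_to_deg <- function(px, geometry) mm_to_deg(px_to_mm(px, geometry), geometry)

#' @rdname angle_conversion
#' @export
deg_to_px <- function(deg, geometry) mm_to_px(deg_to_mm(deg, geometry), geometry)

#' Angular separation between two screen positions
#'
#' @param x1,y1,x2,y2 Screen coordinates in pixels (origin top-left, x
#'   rightward, y downward).
#' @param geometry A [screen_geometry()].
#' @return Separation in degrees of visual angle.
#' @export
angular_distance <- function(x1, y1, x2, y2, geometry) {
  d_mm <- sqrt((x2 - x1)^2 + (y2 - y1)^2) * geometry$mm_per_px
  mm_to_deg(d_mm, geometry)
}
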