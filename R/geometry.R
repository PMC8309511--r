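#' Screen and viewing geometry
#'
#' Describes the monitor and the observer's viewing distance so that gaze
#' positions can be converted between screen pixels and degrees of visual
#' angle. Pixel coordinates have their origin at the top-left corner of the
#' screen (x rightward, y downward); degree coordinates are centered on the
#' screen center with the same axis directions. The conversion uses the
#' per-axis flat-screen tangent approximation about the screen center, which
#' is invertible on the whole screen rectangle.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param physical_width_mm,physical_height_mm Physical panel size in mm.
#' @param viewing_distance_mm Eye-to-screen distance in mm.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(1920, 1080, 510, 287, 600)
#' @export
screen_geometry <- function(width_px, height_px,
                            physical_width_mm, physical_height_mm,
                            viewing_distance_mm) {
  vals <- c(width_px, height_px, physical_width_mm, physical_height_mm,
            viewing_distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be finite and strictly positive")
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         physical_width_mm = physical_width_mm,
         physical_height_mm = physical_height_mm,
         viewing_distance_mm = viewing_distance_mm),
    class = "screen_geometry"
  )
}

#' Read screen geometry from a YAML file
#'
#' Expects keys `width_px`, `height_px`, `physical_width_mm`,
#' `physical_height_mm`, `viewing_distance_mm`.
#'
#' @param path Path to a YAML file.
#' @return A `screen_geometry` object.
#' @export
read_geometry_yaml <- function(path) {
  g <- yaml::read_yaml(path)
  need <- c("width_px", "height_px", "physical_width_mm",
            "physical_height_mm", "viewing_distance_mm")
  missing <- setdiff(need, names(g))
  if (length(missing) > 0) {
    stop("geometry file is missing keys: ", paste(missing, collapse = ", "))
  }
  screen_geometry(g$width_px, g$height_px, g$physical_width_mm,
                  g$physical_height_mm, g$viewing_distance_mm)
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("screen_geometry: %d x %d px, %.0f x %.0f mm, viewed at %.0f mm\n",
              x$width_px, x$height_px, x$physical_width_mm,
              x$physical_height_mm, x$viewing_distance_mm))
  invisible(x)
}

# pixel -> degree for one axis: offset from screen center in mm, then
# atan(offset / viewing distance). Vectorized over positions.
.px_to_deg_axis <- function(px, n_px, phys_mm, dist_mm) {
  mm_per_px <- phys_mm / n_px
  offset_mm <- (px - n_px / 2) * mm_per_px
  atan2(offset_mm, dist_mm) * 180 / pi
}

.deg_to_px_axis <- function(deg, n_px, phys_mm, dist_mm) {
  mm_per_px <- phys_mm / n_px
  offset_mm <- dist_mm * tan(deg * pi / 180)
  offset_mm / mm_per_px + n_px / 2
}

#' Convert pixel coordinates to degrees of visual angle
#'
#' @param x,y Numeric vectors of pixel coordinates (origin top-left).
#' @param geometry A [screen_geometry()] object.
#' @return A list with components `x` and `y` in degrees, centered on the
#'   screen center.
#' @export
pixels_to_degrees <- function(x, y, geometry) {
  list(
    x = .px_to_deg_axis(x, geometry$width_px, geometry$physical_width_mm,
                        geometry$viewing_distance_mm),
    y = .px_to_deg_axis(y, geometry$height_px, geometry$physical_height_mm,
                        geometry$viewing_distance_mm)
  )
}

#' Convert degree coordinates back to screen pixels
#'
#' Inverse of [pixels_to_degrees()].
#'
#' @inheritParams pixels_to_degrees
#' @export
degrees_to_pixels <- function(x, y, geometry) {
  list(
    x = .deg_to_px_axis(x, geometry$width_px, geometry$physical_width_mm,
                        geometry$viewing_distance_mm),
    y = .deg_to_px_axis(y, geometry$height_px, geometry$physical_height_mm,
                        geometry$viewing_distance_mm)
  )
}
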