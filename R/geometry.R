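#' Camera geometry for ears-per-square-metre conversion
#'
#' Describes the acquisition geometry of a zenithal canopy photograph under a
#' rectilinear pinhole model: a camera with sensor dimensions
#' `sensor_width_mm x sensor_height_mm` and focal length `focal_mm`, held at
#' `distance_m` above the canopy, images a ground rectangle of
#' `sensor_width_mm * distance_m / focal_mm` by
#' `sensor_height_mm * distance_m / focal_mm` (similar triangles; the mm/m
#' unit mix cancels in the ratio).  No lens-distortion, tilt, or
#' canopy-height correction is applied.
#'
#' Sensor dimensions must be given in millimetres.  Typical values: a Four
#' Thirds ("4/3 inch") sensor is 17.3 x 13.0 mm; a 1/2.3-inch compact sensor
#' is about 6.17 x 4.55 mm.
#'
#' @param sensor_width_mm,sensor_height_mm sensor size in mm (> 0).
#' @param focal_mm lens focal length in mm (> 0).
#' @param distance_m camera-to-canopy distance in metres (> 0).
#' @param image_width,image_height optional image size in pixels (metadata
#'   only; the footprint does not depend on resolution).
#' @return an object of class `camera_geometry`.
#' @examples
#' g <- camera_geometry(17.3, 13.0, focal_mm = 14, distance_m = 1)
#' ground_area(g)  # ~1.148 m^2
#' @export
camera_geometry <- function(sensor_width_mm, sensor_height_mm, focal_mm,
                            distance_m, image_width = NA_integer_,
                            image_height = NA_integer_) {
  vals <- c(sensor_width_mm, sensor_height_mm, focal_mm, distance_m)
  if (!all(is.finite(vals)) || any(vals <= 0))
    config_error("sensor dimensions, focal length and distance must all be > 0")
  structure(list(sensor_width_mm = sensor_width_mm,
                 sensor_height_mm = sensor_height_mm,
                 focal_mm = focal_mm,
                 distance_m = distance_m,
                 image_width = image_width,
                 image_height = image_height),
            class = "camera_geometry")
}

#' Ground footprint area of a zenithal photograph
#'
#' @param geometry a [camera_geometry()].
#' @return footprint area in square metres:
#'   `(sensor_width * d / focal) * (sensor_height * d / focal)`.
#' @export
ground_area <- function(geometry) {
  stopifnot(inherits(geometry, "camera_geometry"))
  gw <- geometry$sensor_width_mm * geometry$distance_m / geometry$focal_mm
  gh <- geometry$sensor_height_mm * geometry$distance_m / geometry$focal_mm
  gw * gh
}

#' Convert an ear count to ears per square metre
#'
#' Divides a per-image ear count by the ground footprint of the photograph,
#' yielding ear density in the standard agronomic unit (ears/m²).
#'
#' @param count non-negative ear count (vectorised).
#' @param geometry a [camera_geometry()].
#' @return ears per square metre.
#' @export
ears_per_m2 <- function(count, geometry) {
  if (any(!is.finite(count)) || any(count < 0))
    input_error("count must be non-negative")
  count / ground_area(geometry)
}

#' @export
print.camera_geometry <- function(x, ...) {
  cat(sprintf(
    "camera_geometry: sensor %.1f x %.1f mm, focal %.1f mm, distance %.2f m -> footprint %.3f m2\n",
    x$sensor_width_mm, x$sensor_height_mm, x$focal_mm, x$distance_m,
    ground_area(x)))
  invisible(x)
}
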