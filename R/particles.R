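#' Count connected particles in a binary ear mask
#'
#' Counts connected foreground regions of a binary mask — the analysed
#' particles — treating each region with area at least `min_area` as one
#' detected ear.
#'
#' @param mask an [ear_mask] object, a logical matrix, or a 0/1 numeric
#'   matrix (non-binary input is rejected).
#' @param connectivity 4 or 8 (default), the neighbourhood under which
#'   foreground pixels are considered connected.
#' @param min_area minimum region area in pixels (default 1, i.e. no
#'   filtering).
#' @param geometry optional [camera_geometry()]; when supplied the result
#'   carries `density = ear_count / ground_area(geometry)` in ears per square
#'   metre.
#' @return an object of class `count_result`: a list with `ear_count`,
#'   `component_areas` (pixel areas in decreasing order; `ear_count` equals
#'   its length) and `density` (ears/m², `NA` when no geometry is given).
#' @examples
#' m <- matrix(0L, 8, 8); m[2:3, 2:3] <- 1L; m[6, 6] <- 1L
#' count_particles(m)$ear_count  # 2
#' @export
count_particles <- function(mask, connectivity = 8L, min_area = 1L,
                            geometry = NULL) {
  m <- as_binary_matrix(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) config_error("connectivity must be 4 or 8")
  min_area <- as.integer(min_area)
  if (is.na(min_area) || min_area < 1L) config_error("min_area must be >= 1")
  lab <- cpp_label_components(m, connectivity)
  areas <- sort(lab$areas[lab$areas >= min_area], decreasing = TRUE)
  count_result(length(areas), areas, geometry)
}

# internal constructor shared with count_ears
count_result <- function(ear_count, component_areas, geometry = NULL) {
  density <- if (is.null(geometry)) NA_real_
             else ears_per_m2(ear_count, geometry)
  structure(list(ear_count = as.integer(ear_count),
                 component_areas = as.integer(component_areas),
                 density = density),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("count_result: %d ear(s)", x$ear_count))
  if (!is.na(x$density)) cat(sprintf(", %.1f ears/m2", x$density))
  if (x$ear_count > 0)
    cat(sprintf(" | region areas: median %d px, range [%d, %d]",
                as.integer(stats::median(x$component_areas)),
                min(x$component_areas), max(x$component_areas)))
  cat("\n")
  invisible(x)
}
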