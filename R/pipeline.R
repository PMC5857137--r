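#' Count wheat ears in a canopy image
#'
#' Runs the full three-stage counting pipeline on one image: (1) Laplacian
#' frequency enhancement ([laplacian_enhance()]), (2) median smoothing
#' ([median_smooth()]), (3) prominence-based local-maxima segmentation
#' ([find_maxima_segment()]), followed by particle counting
#' ([count_particles()]).  The pipeline is fully deterministic: identical
#' input and configuration always produce identical output.
#'
#' RGB images are reduced to a single channel before filtering.  The default
#' `"average"` policy averages the three bands per pixel (identical to the
#' greyscale simulation rule of [to_greyscale()]); the alternative
#' `"per_band"` policy enhances and smooths each band separately and averages
#' the three filtered bands before segmentation.
#'
#' An optional degradation step emulates lower-cost acquisition before
#' counting: greyscale conversion and/or block-average downscaling by an
#' integer factor, with the median window rescaled in proportion
#' ([scaled_window()]).
#'
#' @param image numeric matrix (single channel) or `height x width x 3` array
#'   in \[0, 255\], or a file path readable by [read_raster()].
#' @param laplacian a [laplacian_spec()].
#' @param median a [median_spec()]; images smaller than the window are
#'   rejected.
#' @param maxima a [maxima_spec()].
#' @param geometry optional [camera_geometry()] for ears/m² conversion.
#' @param channel_policy `"average"` (default) or `"per_band"`.
#' @param resize_factor optional integer >= 2: block-average downscale by
#'   this factor first and reduce the median window proportionally.
#' @param keep_mask attach the segmentation `ear_mask` to the result (off by
#'   default to keep results small).
#' @return a `count_result` (see [count_particles()]) with attributes
#'   `peaks` (accepted peak coordinates) and, if requested, `mask`.
#' @examples
#' sc <- generate_scene(scene_spec(width = 384, height = 384, n_ears = 4,
#'                                 seed = 7))
#' count_ears(sc$image)$ear_count
#' @export
count_ears <- function(image,
                       laplacian = laplacian_spec(),
                       median = median_spec(),
                       maxima = maxima_spec(),
                       geometry = NULL,
                       channel_policy = c("average", "per_band"),
                       resize_factor = NULL,
                       keep_mask = FALSE) {
  channel_policy <- match.arg(channel_policy)
  if (is.character(image)) image <- read_raster(image)

  window <- median$window
  if (!is.null(resize_factor)) {
    image <- downscale(image, resize_factor)
    window <- scaled_window(median$window, resize_factor)
  }

  rgb <- length(dim(image)) == 3L && dim(image)[3] == 3L
  filtered <- if (rgb && channel_policy == "per_band") {
    bands <- lapply(1:3, function(k)
      median_smooth(laplacian_enhance(image[, , k], laplacian),
                    median_spec(window)))
    (bands[[1]] + bands[[2]] + bands[[3]]) / 3
  } else {
    grey <- if (rgb) to_greyscale(image) else as_grey_matrix(image, "count_ears")
    median_smooth(laplacian_enhance(grey, laplacian), median_spec(window))
  }

  if (is.na(maxima$edge_margin))
    maxima$edge_margin <- ceiling(window / 2)
  seg <- find_maxima_segment(filtered, maxima)
  res <- count_particles(seg, connectivity = maxima$connectivity,
                         geometry = geometry)
  attr(res, "peaks") <- seg$peaks
  attr(res, "config") <- list(window = window, tolerance = maxima$tolerance,
                              channel_policy = channel_policy,
                              connectivity = maxima$connectivity,
                              resize_factor = resize_factor)
  if (keep_mask) attr(res, "mask") <- seg
  res
}
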