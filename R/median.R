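#' Median smoothing settings
#'
#' The second pipeline stage replaces every pixel by the median of a square
#' moving window around it.  The default side length of 64 pixels (at native
#' resolution) is large enough to erase awn- and leaf-scale clutter while
#' small enough not to remove the smallest ears; when images are downscaled
#' the window is reduced in proportion (see [scaled_window()]).
#'
#' Boundary handling clips the window to the image, taking the median over
#' the available pixels, so no out-of-image values are invented.  An
#' even-sided window of side `w` is anchored so it spans `[-w/2, w/2 - 1]`
#' around the output pixel in each axis; odd windows are centred
#' symmetrically.  The median is the lower order statistic (the
#' `(n + 1) %/% 2`-th smallest of the `n` window values), which guarantees
#' that every output value occurs somewhere in its source window.
#'
#' @param window window side length in pixels (default 64).
#' @param edge_policy boundary rule; only `"clip"` is provided.
#' @return an object of class `median_spec`.
#' @export
median_spec <- function(window = 64L, edge_policy = "clip") {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) config_error("median window must be >= 1")
  edge_policy <- match.arg(edge_policy, "clip")
  structure(list(window = window, edge_policy = edge_policy),
            class = "median_spec")
}

#' Median rank filtering of a single-channel image
#'
#' Applies the moving-window median described in [median_spec()].  Images
#' whose values lie on the 1/256-grey grid in \[0, 255\] — plain 8-bit data
#' and the default output of [laplacian_enhance()] — are filtered with a
#' sliding two-level-histogram algorithm; other numeric data fall back to an
#' exact sort-based path.  Both paths compute the same order statistic.
#'
#' @param image single-channel numeric matrix.
#' @param spec a [median_spec()]; the window must not exceed either image
#'   dimension.
#' @return numeric matrix of smoothed values, same dimensions as `image`.
#' @examples
#' img <- matrix(0, 5, 5); img[3, 3] <- 255
#' stopifnot(all(median_smooth(img, median_spec(3)) == 0))
#' @export
median_smooth <- function(image, spec = median_spec()) {
  img <- as_grey_matrix(image, "median_smooth")
  w <- spec$window
  if (w > min(dim(img)))
    config_error(sprintf(
      "median window (%d) exceeds image dimensions (%d x %d)",
      w, nrow(img), ncol(img)))
  if (is_grey_grid(img)) cpp_median_filter_q16(img, w)
  else cpp_median_filter_naive(img, w)
}
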