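#' Convert an RGB image to greyscale by band averaging
#'
#' Each output pixel is the arithmetic mean of the red, green and blue values
#' at that pixel — the band-averaging rule used to simulate greyscale
#' acquisition.  A single-channel input is returned unchanged with a warning.
#'
#' @param image `height x width x 3` numeric array in \[0, 255\] (or a
#'   single-channel matrix, passed through with a warning).
#' @return single-channel numeric matrix.
#' @examples
#' px <- array(c(30, 60, 90), c(1, 1, 3))
#' to_greyscale(px)  # 60
#' @export
to_greyscale <- function(image) {
  if (is.matrix(image) ||
      (length(dim(image)) == 3L && dim(image)[3] == 1L)) {
    warning("to_greyscale: input is already single-channel; returning it unchanged")
    return(as_grey_matrix(image, "to_greyscale"))
  }
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    input_error("to_greyscale expects a 3-channel image")
  out <- (image[, , 1L, drop = FALSE] + image[, , 2L, drop = FALSE] +
          image[, , 3L, drop = FALSE]) / 3
  dim(out) <- dim(image)[1:2]
  out
}

#' Downscale an image by block averaging
#'
#' Reduces resolution by an integer factor using plain block means — each
#' output pixel is the average of the corresponding `factor x factor` block
#' of input pixels — with no interpolation.  Dimensions that are not
#' divisible by the factor are centre-cropped to the nearest multiple first.
#' Block averaging preserves the global mean intensity exactly (up to
#' cropping).
#'
#' @param image numeric matrix or `height x width x 3` array.
#' @param factor integer divisor >= 2, at most the smaller image dimension.
#' @return downscaled image, dimensions divided by `factor`.
#' @examples
#' m <- matrix(c(0, 0, 4, 4, 0, 0, 4, 4, 2, 2, 6, 6, 2, 2, 6, 6), 4, 4)
#' downscale(m, 2)
#' @export
downscale <- function(image, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2L)
    config_error("downscale factor must be an integer >= 2")
  d <- dim(image)
  if (factor > d[1] || factor > d[2])
    config_error("downscale factor exceeds an image dimension")
  if (length(d) == 3L) {
    ch <- lapply(seq_len(d[3]), function(k) block_mean(image[, , k], factor))
    out <- array(0, c(dim(ch[[1]]), d[3]))
    for (k in seq_len(d[3])) out[, , k] <- ch[[k]]
    return(out)
  }
  block_mean(image, factor)
}

# internal: centre-crop to a multiple of f, then exact f x f block means
block_mean <- function(m, f) {
  H <- nrow(m); W <- ncol(m)
  h2 <- H %/% f; w2 <- W %/% f
  y0 <- (H - h2 * f) %/% 2L
  x0 <- (W - w2 * f) %/% 2L
  m <- m[(y0 + 1L):(y0 + h2 * f), (x0 + 1L):(x0 + w2 * f), drop = FALSE]
  s <- rowsum(m, rep(seq_len(h2), each = f))
  s <- t(rowsum(t(s), rep(seq_len(w2), each = f)))
  unname(s) / (f * f)
}

#' Median window size for a downscaled image
#'
#' When an image is downscaled by an integer factor the median window is
#' reduced in proportion, so the smoothing scale tracks the apparent size of
#' the ears: `max(1, round(base_window / factor))`, rounding half up.
#'
#' @param base_window native-resolution window side in pixels (default 64).
#' @param factor integer resize divisor >= 1.
#' @return scaled window side in pixels (>= 1).
#' @examples
#' scaled_window(64, 2)   # 32
#' scaled_window(64, 32)  # 2
#' @export
scaled_window <- function(base_window = 64L, factor = 1L) {
  if (base_window < 1L || factor < 1L)
    config_error("base_window and factor must be >= 1")
  max(1L, as.integer(floor(base_window / factor + 0.5)))
}
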