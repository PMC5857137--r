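#' Read a raster image as a pixel matrix or array
#'
#' Reads an 8-bit JPEG or PNG image and returns it in the package's working
#' representation: a numeric matrix (single channel) or a
#' `height x width x 3` array (RGB), with values on the nominal
#' \[0, 255\] scale, rows indexing `y` (top to bottom) and columns indexing
#' `x` (left to right).  An alpha channel, if present, is dropped.
#'
#' @param path path to a JPEG or PNG file.
#' @return numeric matrix or 3-channel array with values in \[0, 255\].
#' @seealso [write_mask()], [count_ears()]
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) input_error(sprintf("image file not found: %s", path))
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  d <- dim(dat)
  if (length(d) == 2L) {
    out <- t(dat) * 255
  } else {
    if (d[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(dat)[3] == 1L) {
      out <- t(dat[, , 1L]) * 255
    } else {
      out <- aperm(dat, c(2L, 1L, 3L)) * 255
    }
  }
  unname(out)
}

#' Write an image matrix or array to disk
#'
#' Writes the package's matrix/array representation (values in \[0, 255\])
#' as an 8-bit PNG or JPEG, chosen from the file extension.
#'
#' @param image numeric matrix or `height x width x 3` array in \[0, 255\].
#' @param path output file path (`.png` or `.jpg`/`.jpeg`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(image, path) {
  x <- pmin(pmax(image / 255, 0), 1)
  dat <- if (length(dim(x)) == 3L) aperm(x, c(2L, 1L, 3L)) else t(x)
  cm <- if (length(dim(x)) == 3L) EBImage::Image(dat, colormode = "Color")
        else EBImage::Image(dat, colormode = "Grayscale")
  type <- if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) "jpeg" else "png"
  EBImage::writeImage(cm, path, type = type)
  invisible(path)
}

#' Write an ear mask as an 8-bit PNG
#'
#' Internally ear pixels are foreground (1).  On disk the default polarity is
#' ears black (0) on a white (255) background, matching the convention of
#' binary output images in which dark regions mark detected ears; set
#' `invert = TRUE` for ears white on black.
#'
#' @param mask an [ear_mask] object or a binary matrix (0 = background,
#'   1 = ear).
#' @param path output PNG path.
#' @param invert write ears as white on black instead of black on white.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, invert = FALSE) {
  m <- as_binary_matrix(mask)
  px <- if (invert) m * 255 else (1 - m) * 255
  write_raster(px, path)
}

# internal: coerce ear_mask / logical / 0-1 numeric matrix to integer 0/1
as_binary_matrix <- function(mask) {
  if (inherits(mask, "ear_mask")) return(mask$mask)
  if (is.logical(mask)) {
    m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
    return(m)
  }
  if (!is.matrix(mask)) input_error("mask must be a matrix or an ear_mask")
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1))) input_error("mask is not binary (values other than 0/1)")
  matrix(as.integer(mask), nrow(mask), ncol(mask))
}

# internal: validate and return a single-channel numeric matrix
as_grey_matrix <- function(image, op = "this operation") {
  if (length(dim(image)) == 3L) {
    if (dim(image)[3] == 1L) {
      image <- image[, , 1L]
    } else {
      input_error(sprintf(
        "%s requires a single-channel image; reduce RGB first (see to_greyscale)",
        op))
    }
  }
  if (!is.matrix(image) || !is.numeric(image))
    input_error("image must be a numeric matrix")
  if (!all(is.finite(image))) input_error("image contains non-finite pixel values")
  image
}

# internal: TRUE if all values lie on the 1/256 grey grid within [0, 255]
is_grey_grid <- function(x) {
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 255) return(FALSE)
  k <- x * 256
  all(abs(k - round(k)) < 1e-9)
}
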