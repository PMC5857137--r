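#' Local-maxima segmentation settings
#'
#' The final pipeline stage detects local intensity peaks in the smoothed
#' image — after filtering, each surviving peak corresponds to one wheat
#' ear — and segments one region per accepted peak.
#'
#' A pixel is a candidate peak if no 8-neighbour is strictly higher.
#' Candidates are examined in decreasing intensity (ties broken in raster
#' order: smallest y, then smallest x) and a candidate of value `v` is
#' accepted when no path leaves it to a higher pixel without first descending
#' more than `tolerance` below `v`; equivalently, the connected region of
#' pixels with value `>= v - tolerance` around the candidate contains nothing
#' higher than `v`.  This is the prominence ("noise tolerance") criterion of
#' ImageJ-style *Find Maxima* peak detection.  Each accepted peak then claims
#' the connected region of unclaimed pixels within `tolerance` below it;
#' pixels bordering a different peak's region are left as background so that
#' regions of distinct peaks never touch.  A plateau of equal values yields a
#' single region, and a perfectly flat image yields an empty mask.
#'
#' @param tolerance minimum prominence, in intensity units, a peak must have
#'   over its surroundings (>= 0).  The default of 12 was calibrated once on
#'   the package's synthetic canopy-scene suite at the default generator
#'   settings.
#' @param exclude_edge_peaks drop accepted peaks lying in the border band of
#'   the image (default `TRUE`, the usual particle-analysis convention for
#'   border objects; it also removes the spurious border ridges that
#'   circular FFT filtering produces when opposite image edges differ in
#'   brightness).  Excluded regions still suppress weaker maxima within
#'   tolerance, exactly as if they had been kept.
#' @param edge_margin width in pixels of the excluded border band.  The
#'   default `NA` means automatic: [count_ears()] uses half the median
#'   window — the band in which the rank filter's window is truncated and
#'   its statistics unreliable — while standalone calls fall back to 0
#'   (only peaks exactly on the border line are dropped).
#' @param connectivity neighbourhood used for region growing, 4 or 8.
#' @return an object of class `maxima_spec`.
#' @export
maxima_spec <- function(tolerance = 12, exclude_edge_peaks = TRUE,
                        edge_margin = NA, connectivity = 8L) {
  if (!is.finite(tolerance) || tolerance < 0)
    config_error("maxima tolerance must be >= 0")
  if (!is.na(edge_margin) && (!is.finite(edge_margin) || edge_margin < 0))
    config_error("edge_margin must be NA (automatic) or >= 0")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    config_error("connectivity must be 4 or 8")
  structure(list(tolerance = tolerance,
                 exclude_edge_peaks = isTRUE(exclude_edge_peaks),
                 edge_margin = edge_margin,
                 connectivity = connectivity),
            class = "maxima_spec")
}

#' Segment ear peaks with prominence-based Find-Maxima detection
#'
#' Runs the peak detection and region growing described in [maxima_spec()]
#' and returns a binary ear mask in which each foreground connected region
#' corresponds to exactly one accepted local maximum.
#'
#' @param image single-channel numeric matrix (normally the output of
#'   [median_smooth()]).
#' @param spec a [maxima_spec()].
#' @return an object of class `ear_mask`: a list with `mask` (integer 0/1
#'   matrix, 1 = ear), `peaks` (data frame of accepted peak coordinates `x`,
#'   `y`, 0-based, and `value`), and `foreground_label` (1).
#' @examples
#' flat <- matrix(7, 10, 10)
#' stopifnot(nrow(find_maxima_segment(flat, maxima_spec(0))$peaks) == 0)
#' @export
find_maxima_segment <- function(image, spec = maxima_spec()) {
  img <- as_grey_matrix(image, "find_maxima_segment")
  res <- cpp_find_maxima(img, spec$tolerance, FALSE, spec$connectivity)
  labels <- res$labels
  keep <- rep(TRUE, length(res$peak_x))
  if (spec$exclude_edge_peaks && length(keep)) {
    m <- if (is.na(spec$edge_margin)) 0L else as.integer(spec$edge_margin)
    bdist <- pmin(res$peak_x, res$peak_y,
                  ncol(img) - 1L - res$peak_x, nrow(img) - 1L - res$peak_y)
    drop <- which(bdist <= m)
    if (length(drop)) {
      keep[drop] <- FALSE
      labels[labels %in% drop] <- 0L
    }
  }
  mask <- matrix(as.integer(labels > 0), nrow(img), ncol(img))
  peaks <- data.frame(x = res$peak_x[keep], y = res$peak_y[keep],
                      value = img[cbind(res$peak_y[keep] + 1L,
                                        res$peak_x[keep] + 1L)])
  structure(list(mask = mask, peaks = peaks, labels = labels,
                 foreground_label = 1L),
            class = "ear_mask")
}

#' @export
print.ear_mask <- function(x, ...) {
  cat(sprintf("ear_mask: %d x %d, %d peak region(s), %d foreground pixel(s)\n",
              nrow(x$mask), ncol(x$mask), nrow(x$peaks), sum(x$mask)))
  invisible(x)
}
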