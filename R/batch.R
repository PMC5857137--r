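#' Process a batch of canopy images
#'
#' Runs [count_ears()] over a set of image files, optionally applying
#' greyscale conversion and/or block-average downscaling first (with the
#' median window rescaled in proportion), and returns one row per input
#' image.  A failure on an individual image is caught and recorded as an
#' error row; it never aborts the batch, so the result always has exactly
#' one row per input.
#'
#' @param inputs character vector of image paths, or a directory from which
#'   all `.png`/`.jpg`/`.jpeg` files are taken.
#' @param output_dir optional directory; when given, a `results.csv` is
#'   written there (and mask PNGs if `write_masks = TRUE`).
#' @param laplacian,median,maxima stage settings (see [laplacian_spec()],
#'   [median_spec()], [maxima_spec()]).
#' @param geometry optional [camera_geometry()] for the ears/m² column.
#' @param greyscale convert RGB inputs to greyscale before counting.
#' @param resize_factor optional integer >= 2 block-average downscale factor.
#' @param channel_policy RGB reduction policy of [count_ears()].
#' @param write_masks write the segmentation mask of each image as
#'   `<name>_mask.png` in `output_dir`.
#' @param verbose print one log line per image with the effective settings.
#' @return data frame with columns `image_path`, `ear_count`,
#'   `density_ears_per_m2`, `window`, `tolerance`, `channel_policy`,
#'   `status` (`"ok"` or `"error"`) and `message`, plus attribute
#'   `n_failed`.
#' @export
run_batch <- function(inputs, output_dir = NULL,
                      laplacian = laplacian_spec(),
                      median = median_spec(),
                      maxima = maxima_spec(),
                      geometry = NULL,
                      greyscale = FALSE,
                      resize_factor = NULL,
                      channel_policy = "average",
                      write_masks = FALSE,
                      verbose = FALSE) {
  if (length(inputs) == 1L && dir.exists(inputs))
    inputs <- list.files(inputs, pattern = "\\.(png|jpe?g)$",
                         ignore.case = TRUE, full.names = TRUE)
  if (!length(inputs)) config_error("no input images")
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)

  window_used <- if (is.null(resize_factor)) median$window
                 else scaled_window(median$window, resize_factor)
  if (verbose)
    message(sprintf(
      "run_batch: %d image(s); window=%d tolerance=%g channel_policy=%s%s%s",
      length(inputs), window_used, maxima$tolerance, channel_policy,
      if (greyscale) " greyscale" else "",
      if (is.null(resize_factor)) "" else sprintf(" resize=1/%d", resize_factor)))

  rows <- lapply(inputs, function(p) {
    tryCatch({
      img <- read_raster(p)
      if (greyscale && length(dim(img)) == 3L) img <- to_greyscale(img)
      res <- count_ears(img, laplacian = laplacian, median = median,
                        maxima = maxima, geometry = geometry,
                        channel_policy = channel_policy,
                        resize_factor = resize_factor,
                        keep_mask = write_masks)
      if (write_masks && !is.null(output_dir)) {
        mp <- file.path(output_dir,
                        paste0(sub("\\.[^.]+$", "", basename(p)), "_mask.png"))
        write_mask(attr(res, "mask"), mp)
      }
      if (verbose)
        message(sprintf("  %s: %d ear(s)", basename(p), res$ear_count))
      data.frame(image_path = p, ear_count = res$ear_count,
                 density_ears_per_m2 = res$density,
                 window = attr(res, "config")$window,
                 tolerance = maxima$tolerance,
                 channel_policy = channel_policy,
                 status = "ok", message = "")
    }, error = function(e) {
      if (verbose) message(sprintf("  %s: ERROR %s", basename(p),
                                   conditionMessage(e)))
      data.frame(image_path = p, ear_count = NA_integer_,
                 density_ears_per_m2 = NA_real_,
                 window = window_used, tolerance = maxima$tolerance,
                 channel_policy = channel_policy,
                 status = "error", message = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- sum(out$status == "error")
  if (!is.null(output_dir))
    utils::write.csv(out, file.path(output_dir, "results.csv"),
                     row.names = FALSE)
  out
}
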