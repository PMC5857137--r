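#' Manual ear marks for one image
#'
#' A set of point annotations (one mark per ear) in pixel coordinates,
#' 0-based, origin at the top-left corner (`x` = column, `y` = row).
#' Duplicate points collapse to one mark; marks outside the stated image
#' bounds are rejected with an error listing the offenders.
#'
#' @param x,y numeric vectors of equal length, mark coordinates in pixels.
#' @param image_id identifier of the annotated image.
#' @param width,height optional image dimensions in pixels used for the
#'   bounds check (marks must satisfy `0 <= x < width`, `0 <= y < height`).
#' @return an object of class `mark_set`.
#' @export
mark_set <- function(x, y, image_id = "", width = NULL, height = NULL) {
  if (length(x) != length(y)) input_error("x and y must have equal length")
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y))))
    input_error("mark coordinates must be finite")
  if (!is.null(width) && !is.null(height) && length(x)) {
    bad <- which(x < 0 | x >= width | y < 0 | y >= height)
    if (length(bad))
      input_error(sprintf(
        "marks outside image bounds (%d x %d) at rows: %s",
        width, height, paste(bad, collapse = ", ")))
  }
  marks <- unique(data.frame(x = as.numeric(x), y = as.numeric(y)))
  structure(list(image_id = image_id, marks = marks,
                 width = width, height = height),
            class = "mark_set")
}

#' Count manual marks
#'
#' Returns the number of unique, in-bounds marks — the manual (image-based)
#' ear count used as ground truth in validation.
#'
#' @param marks a [mark_set()].
#' @return integer count.
#' @export
count_marks <- function(marks) {
  stopifnot(inherits(marks, "mark_set"))
  nrow(marks$marks)
}

#' Read ear marks from a CSV file
#'
#' Reads a mark file with columns `x`, `y` (0-based pixel coordinates), the
#' same format written for synthetic scene truths, so synthetic ground truth
#' flows through the identical validation path as human annotations.
#'
#' @param path CSV path.
#' @param image_id identifier (defaults to the file name).
#' @param width,height optional image bounds (see [mark_set()]).
#' @return a [mark_set()].
#' @export
read_marks <- function(path, image_id = basename(path), width = NULL,
                       height = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    input_error("mark CSV must have columns x and y")
  mark_set(df$x, df$y, image_id = image_id, width = width, height = height)
}

#' Per-image counting success rate
#'
#' The success rate is 100 minus the relative difference between the manual
#' and the algorithm count, in percent:
#' `100 - abs(manual - algorithm) / manual * 100`.  It is 100 exactly when
#' the counts agree, decreases linearly in the absolute count error, treats
#' over- and under-counting symmetrically, and is reported unclamped (it goes
#' below 0 when the algorithm count exceeds twice the manual count).
#'
#' @param manual manual (ground-truth) count, >= 1 (vectorised).
#' @param algorithm algorithm count, >= 0 (vectorised).
#' @return success rate in percent.
#' @examples
#' success_rate(100, 90)   # 90
#' success_rate(100, 130)  # 70
#' @export
success_rate <- function(manual, algorithm) {
  if (any(!is.finite(manual)) || any(manual < 1))
    input_error("manual count must be >= 1 (success rate divides by it)")
  if (any(!is.finite(algorithm)) || any(algorithm < 0))
    input_error("algorithm count must be >= 0")
  100 - abs(manual - algorithm) / manual * 100
}

#' Summarise validation records
#'
#' Computes the summary statistics of a count-validation run: the mean (`mu`)
#' and sample standard deviation (`sigma`) of per-image success rates, the
#' Pearson correlation `r` between manual and algorithm counts, and the
#' ordinary least-squares regression of the algorithm count on the manual
#' count (`slope`, `intercept`, `r_squared`).  With constant manual or
#' algorithm counts `r` and the regression are undefined and reported as
#' `NA` without aborting `mu`/`sigma`.
#'
#' @param records data frame with columns `manual` and `algorithm` (one row
#'   per image; an `image_id` column is carried through if present).
#' @return an object of class `validation_summary`: list with `mu`, `sigma`,
#'   `r`, `r_squared`, `slope`, `intercept`, `n`, and the per-image `records`
#'   (with a `success` column added).
#' @examples
#' rec <- data.frame(manual = c(10, 20), algorithm = c(10, 20))
#' summarize_validation(rec)$r  # 1
#' @export
summarize_validation <- function(records) {
  if (!is.data.frame(records) || !all(c("manual", "algorithm") %in% names(records)))
    input_error("records must be a data frame with columns manual and algorithm")
  if (nrow(records) < 1L) input_error("at least one record is required")
  records$success <- success_rate(records$manual, records$algorithm)
  mu <- mean(records$success)
  sigma <- if (nrow(records) >= 2L) stats::sd(records$success) else NA_real_

  r <- NA_real_; slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
  if (nrow(records) >= 2L &&
      stats::sd(records$manual) > 0 && stats::sd(records$algorithm) > 0) {
    r <- stats::cor(records$manual, records$algorithm)
    fit <- stats::lm(algorithm ~ manual, data = records)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- r^2
  }
  structure(list(mu = mu, sigma = sigma, r = r, r_squared = r2,
                 slope = slope, intercept = intercept,
                 n = nrow(records), records = records),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("validation_summary over %d image(s):\n", x$n))
  cat(sprintf("  success rate: mu = %.2f%%, sigma = %.2f\n", x$mu, x$sigma))
  if (is.na(x$r)) {
    cat("  correlation/regression undefined (constant counts)\n")
  } else {
    cat(sprintf("  Pearson r = %.3f (R2 = %.3f); algorithm = %.3f * manual + %.2f\n",
                x$r, x$r_squared, x$slope, x$intercept))
  }
  invisible(x)
}

#' Write a validation report CSV
#'
#' Writes one row per image (`image_id`, `manual`, `algorithm`, `success`)
#' followed by a summary row holding `mu`, `sigma`, `r`, `r_squared`,
#' `slope` and `intercept`.
#'
#' @param summary a [summarize_validation()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(summary, path) {
  stopifnot(inherits(summary, "validation_summary"))
  rec <- summary$records
  if (is.null(rec$image_id)) rec$image_id <- seq_len(nrow(rec))
  rows <- data.frame(image_id = as.character(rec$image_id),
                     manual = rec$manual, algorithm = rec$algorithm,
                     success = rec$success,
                     mu = NA_real_, sigma = NA_real_, r = NA_real_,
                     r_squared = NA_real_, slope = NA_real_,
                     intercept = NA_real_)
  rows <- rbind(rows, data.frame(
    image_id = "summary", manual = NA, algorithm = NA, success = NA,
    mu = summary$mu, sigma = summary$sigma, r = summary$r,
    r_squared = summary$r_squared, slope = summary$slope,
    intercept = summary$intercept))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
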