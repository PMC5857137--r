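gauss_bump <- function(h, w, cx, cy, amp, sigma) {
  outer(1:h, 1:w, function(y, x)
    amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2)))
}

test_that("a flat image yields an empty mask", {
  seg <- find_maxima_segment(matrix(7, 20, 20), maxima_spec(0))
  expect_identical(nrow(seg$peaks), 0L)
  expect_identical(sum(seg$mask), 0L)
})

test_that("a single smooth bump gives exactly one region containing the peak", {
  img <- 10 + gauss_bump(41, 41, 21, 21, 200, 6)
  seg <- find_maxima_segment(img, maxima_spec(50, exclude_edge_peaks = FALSE))
  expect_identical(nrow(seg$peaks), 1L)
  expect_identical(c(seg$peaks$x, seg$peaks$y), c(20L, 20L))   # 0-based
  expect_identical(seg$mask[21, 21], 1L)
  cr <- count_particles(seg)
  expect_identical(cr$ear_count, 1L)
})

test_that("two well-separated equal bumps give two regions", {
  img <- 10 + gauss_bump(60, 100, 30, 30, 200, 5) +
              gauss_bump(60, 100, 70, 30, 200, 5)
  seg <- find_maxima_segment(img, maxima_spec(20, exclude_edge_peaks = FALSE))
  expect_identical(nrow(seg$peaks), 2L)
  expect_identical(count_particles(seg)$ear_count, 2L)
  # brute-force check: the strict maxima of this surface are the two centres
  sm <- oracle_strict_maxima(img)
  expect_identical(nrow(sm), 2L)
  expect_setequal(paste(seg$peaks$x, seg$peaks$y),
                  paste(sm[, 1], sm[, 2]))
})

test_that("at tolerance 0 accepted peaks equal the strict local-maxima set", {
  for (i in 1:8) {
    set.seed(500 + i)
    img <- matrix(sample(seq_len(18 * 18)), 18, 18)  # distinct values: no plateaus
    seg <- find_maxima_segment(img, maxima_spec(0, exclude_edge_peaks = FALSE))
    sm <- oracle_strict_maxima(img)
    expect_setequal(paste(seg$peaks$x, seg$peaks$y),
                    paste(sm[, 1], sm[, 2]))
  }
})

test_that("a connected plateau yields a single region", {
  img <- matrix(0, 12, 12); img[5:7, 5:8] <- 50
  seg <- find_maxima_segment(img, maxima_spec(10, exclude_edge_peaks = FALSE))
  expect_identical(nrow(seg$peaks), 1L)
  # raster-order tie break: first plateau pixel (smallest y, then x)
  expect_identical(c(seg$peaks$x, seg$peaks$y), c(4L, 4L))
  expect_identical(count_particles(seg)$ear_count, 1L)
})

test_that("a maximum within tolerance of a stronger peak is suppressed", {
  # secondary bump only 5 units proud of the connecting ridge
  img <- 10 + gauss_bump(40, 80, 25, 20, 200, 8)
  img[20, 55] <- img[20, 55] + 150     # spike to ~160, below the 210 main peak
  seg50 <- find_maxima_segment(img, maxima_spec(200, exclude_edge_peaks = FALSE))
  expect_identical(nrow(seg50$peaks), 1L)
  seg5 <- find_maxima_segment(img, maxima_spec(5, exclude_edge_peaks = FALSE))
  expect_gte(nrow(seg5$peaks), 2L)
})

test_that("edge-band exclusion drops border peaks but keeps interior ones", {
  img <- 10 + gauss_bump(40, 40, 20, 20, 200, 4)
  img[1, 8] <- 300                      # spike on the border
  spec0 <- maxima_spec(50, exclude_edge_peaks = FALSE)
  expect_identical(nrow(find_maxima_segment(img, spec0)$peaks), 2L)
  spec1 <- maxima_spec(50, exclude_edge_peaks = TRUE, edge_margin = 2)
  seg <- find_maxima_segment(img, spec1)
  expect_identical(nrow(seg$peaks), 1L)
  expect_identical(c(seg$peaks$x, seg$peaks$y), c(19L, 19L))
})

test_that("each accepted peak owns one connected region (count conservation)", {
  set.seed(99)
  img <- 0
  for (k in 1:6)
    img <- img + gauss_bump(80, 80, runif(1, 15, 65), runif(1, 15, 65), 200, 4)
  seg <- find_maxima_segment(img, maxima_spec(30, exclude_edge_peaks = FALSE))
  expect_identical(count_particles(seg)$ear_count, nrow(seg$peaks))
})

test_that("invalid configurations are rejected", {
  expect_error(maxima_spec(-1), class = "earcount_config_error")
  expect_error(maxima_spec(1, connectivity = 6), class = "earcount_config_error")
  expect_error(maxima_spec(1, edge_margin = -2), class = "earcount_config_error")
})
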