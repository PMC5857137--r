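test_that("greyscale conversion is the per-pixel band mean", {
  px <- array(c(30, 60, 90), c(1, 1, 3))
  expect_equal(to_greyscale(px)[1, 1], 60)

  eq <- array(rep(matrix(1:12, 3, 4), 3), c(3, 4, 3))
  expect_equal(to_greyscale(eq), matrix(1:12, 3, 4))

  set.seed(8)
  rnd <- array(runif(3 * 5 * 3, 0, 255), c(3, 5, 3))
  want <- (rnd[, , 1] + rnd[, , 2] + rnd[, , 3]) / 3   # elementwise oracle
  expect_equal(to_greyscale(rnd), want)

  expect_warning(out <- to_greyscale(matrix(5, 2, 2)), "single-channel")
  expect_equal(out, matrix(5, 2, 2))
})

test_that("downscale computes exact block means", {
  m <- matrix(c(0, 0, 4, 4,
                0, 0, 4, 4,
                2, 2, 6, 6,
                2, 2, 6, 6), 4, 4, byrow = TRUE)
  expect_equal(downscale(m, 2), matrix(c(0, 4, 2, 6), 2, 2, byrow = TRUE))

  const <- matrix(7, 12, 12)
  expect_equal(downscale(const, 3), matrix(7, 4, 4))

  img <- random_u8_image(64, 64, 55)
  expect_equal(downscale(img, 8), oracle_block_mean(img, 8))
})

test_that("non-divisible dimensions are centre-cropped first", {
  m <- matrix(1:35, 5, 7)        # 5 x 7, factor 2 -> crop to rows 1:4? no: centre
  out <- downscale(m, 2)
  expect_identical(dim(out), c(2L, 3L))
  # centre crop of 5 rows to 4 keeps rows 1..4 (offset floor(1/2)=0),
  # 7 cols to 6 keeps cols 1..6
  expect_equal(out, oracle_block_mean(m[1:4, 1:6], 2))
})

test_that("block averaging preserves the global mean", {
  img <- random_u8_image(64, 64, 77)
  for (f in c(2, 4, 8, 16, 32))
    expect_equal(mean(downscale(img, f)), mean(img))
  rgb <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  expect_equal(mean(downscale(rgb, 4)), mean(rgb))
})

test_that("scaled_window follows the proportional rule with a floor of 1", {
  expect_identical(scaled_window(64, 2), 32L)
  expect_identical(scaled_window(64, 1), 64L)
  expect_identical(scaled_window(64, 32), 2L)
  expect_identical(scaled_window(64, 128), 1L)       # floored at 1
  expect_identical(scaled_window(48, 32), 2L)        # 1.5 rounds half up
  expect_identical(scaled_window(40, 16), 3L)        # 2.5 rounds half up
})

test_that("degenerate factors are rejected", {
  expect_error(downscale(matrix(0, 4, 4), 1), class = "earcount_config_error")
  expect_error(downscale(matrix(0, 4, 4), 8), class = "earcount_config_error")
  expect_error(scaled_window(0, 2), class = "earcount_config_error")
})

test_that("density is unchanged by downscaling (footprint is resolution-free)", {
  g <- camera_geometry(17.3, 13.0, 14, 1.0, image_width = 1024,
                       image_height = 1024)
  expect_equal(ears_per_m2(40, g), 40 / ground_area(g))
  g2 <- camera_geometry(17.3, 13.0, 14, 1.0, image_width = 256,
                        image_height = 256)
  expect_equal(ears_per_m2(40, g), ears_per_m2(40, g2))
})
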