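test_that("scene generation is deterministic given the spec", {
  sp <- scene_spec(width = 256, height = 256, n_ears = 6, seed = 12)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$ear_centers, b$truth$ear_centers)
})

test_that("truth count is exact by construction", {
  sc0 <- generate_scene(scene_spec(width = 256, height = 256, n_ears = 0,
                                   seed = 5))
  expect_identical(sc0$truth$ear_count, 0L)
  expect_identical(nrow(sc0$truth$ear_centers), 0L)

  sc <- generate_scene(scene_spec(n_ears = 50, seed = 9))
  expect_identical(sc$truth$ear_count, 50L)
  expect_identical(nrow(sc$truth$ear_centers), 50L)
})

test_that("ear centres honour the minimum separation", {
  sc <- generate_scene(scene_spec(n_ears = 50, min_separation = 40, seed = 4))
  d <- as.matrix(dist(sc$truth$ear_centers))
  diag(d) <- Inf
  expect_gte(min(d), 40)
})

test_that("infeasible packings raise a configuration error", {
  expect_error(
    generate_scene(scene_spec(width = 300, height = 300, n_ears = 40,
                              min_separation = 120, seed = 1)),
    class = "earcount_config_error")
})

test_that("scene images are valid 8-bit RGB with ears brighter than background", {
  sc <- generate_scene(scene_spec(width = 512, height = 512, n_ears = 10,
                                  seed = 2))
  expect_identical(dim(sc$image), c(512L, 512L, 3L))
  expect_gte(min(sc$image), 0)
  expect_lte(max(sc$image), 255)
  grey <- to_greyscale(sc$image)
  ctr <- as.matrix(round(sc$truth$ear_centers)) + 1
  ear_vals <- grey[ctr[, c(2, 1)]]
  expect_gt(min(ear_vals), median(grey) + 30)
})

test_that("senescent mode collapses the ear/background contrast", {
  nrm <- generate_scene(scene_spec(width = 512, height = 512, n_ears = 10,
                                   seed = 3))
  sen <- generate_scene(scene_spec(width = 512, height = 512, n_ears = 10,
                                   seed = 3, contrast_mode = "senescent"))
  gap <- function(sc) {
    g <- to_greyscale(sc$image)
    ctr <- as.matrix(round(sc$truth$ear_centers)) + 1
    median(g[ctr[, c(2, 1)]]) - median(g)
  }
  expect_lt(gap(sen), gap(nrm) / 2)
  # paired seeds share the same layout
  expect_equal(nrm$truth$ear_centers, sen$truth$ear_centers)
})

test_that("suites derive scenes deterministically from the suite seed", {
  base <- scene_spec(width = 256, height = 256)
  s1 <- generate_suite(base, n_scenes = 3, seed = 42, count_range = c(3, 9))
  s2 <- generate_suite(base, n_scenes = 3, seed = 42, count_range = c(3, 9))
  expect_identical(s1[[2]]$image, s2[[2]]$image)

  # a singleton suite equals generate_scene at the derived seed and count
  log1 <- attr(s1, "draw_log")
  sp <- base
  sp$n_ears <- log1$n_ears[1]
  sp$seed <- log1$seed[1]
  expect_identical(s1[[1]]$image, generate_scene(sp)$image)
})

test_that("suite ear counts are uniform over the requested range (draw log)", {
  suite <- generate_suite(scene_spec(width = 128, height = 128, n_ears = 1,
                                     min_separation = 5),
                          n_scenes = 40, seed = 7, count_range = c(2, 8))
  log <- attr(suite, "draw_log")
  expect_identical(sapply(suite, function(s) s$truth$ear_count), log$n_ears)
  expect_true(all(log$n_ears >= 2 & log$n_ears <= 8))
  # mean within sampling error of the midpoint 5 (sd of mean ~ 0.32)
  expect_lt(abs(mean(log$n_ears) - 5), 1.1)
})

test_that("scene truths flow through the mark-CSV validation path", {
  td <- withr::local_tempdir()
  sc <- generate_scene(scene_spec(width = 256, height = 256, n_ears = 7,
                                  seed = 6))
  ip <- file.path(td, "scene.png"); tp <- file.path(td, "scene_marks.csv")
  write_scene(sc, ip, tp)
  ms <- read_marks(tp, width = 256, height = 256)
  expect_identical(count_marks(ms), 7L)
  img <- read_raster(ip)
  expect_identical(dim(img), dim(sc$image))
  expect_lte(max(abs(img - sc$image)), 1)   # 8-bit write/read
})
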