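test_that("count_marks counts unique in-bounds marks", {
  expect_identical(count_marks(mark_set(numeric(0), numeric(0))), 0L)

  set.seed(21)
  x <- sample(0:499, 25); y <- sample(0:499, 25)
  expect_identical(count_marks(mark_set(x, y)), 25L)

  # 25 points with 3 exact duplicates collapse to 22
  xd <- c(x[1:22], x[1:3]); yd <- c(y[1:22], y[1:3])
  expect_identical(count_marks(mark_set(xd, yd)), 22L)
})

test_that("out-of-bounds marks are rejected with offender positions", {
  err <- tryCatch(mark_set(c(10, 600, 20), c(10, 20, -1),
                           width = 500, height = 500),
                  error = identity)
  expect_s3_class(err, "earcount_input_error")
  expect_match(conditionMessage(err), "2, 3")
})

test_that("success_rate implements the symmetric relative-error formula", {
  expect_equal(success_rate(100, 100), 100)
  expect_equal(success_rate(100, 90), 90)
  expect_equal(success_rate(100, 130), 70)
  expect_equal(success_rate(40, 50), 75)
  # unclamped below zero when algorithm exceeds twice the manual count
  expect_equal(success_rate(10, 25), -50)
  # linear in the absolute count error
  expect_equal(success_rate(50, 50 + 0:5), 100 - 2 * (0:5))
  expect_error(success_rate(0, 5), class = "earcount_input_error")
})

test_that("summarize_validation reproduces trivial closed-form cases", {
  rec <- data.frame(manual = c(10, 20, 40), algorithm = c(9, 18, 36))
  s <- summarize_validation(rec)
  expect_equal(s$mu, 90)
  expect_equal(s$sigma, 0)
  expect_equal(s$r, 1)

  s2 <- summarize_validation(data.frame(manual = c(10, 20),
                                        algorithm = c(10, 20)))
  expect_equal(s2$r, 1)
  expect_equal(s2$slope, 1)
  expect_equal(s2$intercept, 0)
})

test_that("summary statistics match a first-principles oracle", {
  manual <- c(120, 95, 143, 88, 110)
  algorithm <- c(112, 99, 130, 70, 108)
  s <- summarize_validation(data.frame(manual = manual, algorithm = algorithm))
  o <- oracle_validation_stats(manual, algorithm)
  expect_equal(s$mu, o$mu)
  expect_equal(s$sigma, o$sigma)
  expect_equal(s$r, o$r)
  expect_equal(s$slope, o$slope)
  expect_equal(s$intercept, o$intercept)
  expect_equal(s$r_squared, o$r_squared)
  expect_equal(s$r_squared, s$r^2)
})

test_that("summaries are permutation-invariant", {
  set.seed(31)
  rec <- data.frame(manual = sample(50:150, 12),
                    algorithm = sample(50:150, 12))
  a <- summarize_validation(rec)
  b <- summarize_validation(rec[sample(12), ])
  for (f in c("mu", "sigma", "r", "slope", "intercept"))
    expect_equal(a[[f]], b[[f]])
})

test_that("constant counts leave r undefined without losing mu and sigma", {
  rec <- data.frame(manual = c(30, 30, 30), algorithm = c(28, 31, 29))
  s <- summarize_validation(rec)
  expect_true(is.na(s$r))
  expect_false(is.na(s$mu))
  expect_false(is.na(s$sigma))
})

test_that("mark CSVs and validation reports round-trip through disk", {
  td <- withr::local_tempdir()
  mp <- file.path(td, "img1_marks.csv")
  write.csv(data.frame(x = c(5, 9, 40), y = c(7, 7, 12)), mp,
            row.names = FALSE)
  ms <- read_marks(mp, width = 100, height = 100)
  expect_identical(count_marks(ms), 3L)

  s <- summarize_validation(data.frame(image_id = c("a", "b"),
                                       manual = c(10, 20),
                                       algorithm = c(9, 21)))
  rp <- file.path(td, "report.csv")
  write_validation_report(s, rp)
  rep <- read.csv(rp)
  expect_identical(nrow(rep), 3L)
  expect_equal(rep$mu[rep$image_id == "summary"], s$mu)
})
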