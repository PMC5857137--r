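# Independent reference implementations used to check the package's fast
# paths.  Each oracle is deliberately naive (direct sums, explicit loops,
# full sorts) and shares no code with the implementation under test.

# Direct DFT Laplacian-enhancement oracle: the forward transform is the
# explicit double sum F(u,v) = sum_xy I(x,y) e^{-2pi i(ux/M + vy/N)}, the
# enhancement gain 1 - H is evaluated on the centred spectrum and permuted
# to the unshifted layout by explicit index arithmetic, and the inverse
# transform is again a direct double sum.  O(M^2 N^2); small images only.
oracle_laplacian <- function(img) {
  M <- nrow(img); N <- ncol(img)
  wm <- exp(-2i * pi * outer(0:(M - 1), 0:(M - 1)) / M)
  wn <- exp(-2i * pi * outer(0:(N - 1), 0:(N - 1)) / N)
  fw <- wm %*% img %*% wn

  # centred-spectrum gain grid: 1 - H at centred coordinates (uc, vc), with
  # H = -4 pi^2 [((uc - M/2)/M)^2 + ((vc - N/2)/N)^2]; for odd dimensions
  # the centre bin is floor(M/2) so the DC gain stays exactly 1 (identical
  # to M/2 for even dimensions)
  gc <- matrix(0, M, N)
  for (uc in 0:(M - 1)) for (vc in 0:(N - 1))
    gc[uc + 1, vc + 1] <- 1 + 4 * pi^2 *
      (((uc - M %/% 2) / M)^2 + ((vc - N %/% 2) / N)^2)
  # permute to unshifted layout: unshifted index u holds centred index
  # (u + floor(M/2)) mod M
  gain <- matrix(0, M, N)
  for (u in 0:(M - 1)) for (v in 0:(N - 1))
    gain[u + 1, v + 1] <- gc[(u + M %/% 2) %% M + 1, (v + N %/% 2) %% N + 1]

  wmi <- exp(2i * pi * outer(0:(M - 1), 0:(M - 1)) / M)
  wni <- exp(2i * pi * outer(0:(N - 1), 0:(N - 1)) / N)
  Re(wmi %*% (gain * fw) %*% wni) / (M * N)
}

# Naive sort-based median filter with the package's window conventions:
# side w anchored on [-w/2, w/2 - 1] (even) or symmetric (odd), clipped at
# the borders, lower median.
oracle_median <- function(img, w) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  lo <- -(w %/% 2); hi <- lo + w - 1
  for (y in 1:H) for (x in 1:W) {
    ys <- max(1, y + lo):min(H, y + hi)
    xs <- max(1, x + lo):min(W, x + hi)
    v <- sort(as.vector(img[ys, xs]))
    out[y, x] <- v[(length(v) + 1) %/% 2]
  }
  out
}

# Brute-force strict 8-neighbourhood local maxima (loops over all pixels).
oracle_strict_maxima <- function(img) {
  H <- nrow(img); W <- ncol(img)
  res <- NULL
  for (y in 1:H) for (x in 1:W) {
    v <- img[y, x]
    strict <- TRUE
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      ny <- y + dy; nx <- x + dx
      if (ny < 1 || ny > H || nx < 1 || nx > W) next
      if (img[ny, nx] >= v) strict <- FALSE
    }
    if (strict) res <- rbind(res, c(x - 1, y - 1))
  }
  res
}

# Double-loop block-average downscale oracle.
oracle_block_mean <- function(img, f) {
  h2 <- nrow(img) %/% f; w2 <- ncol(img) %/% f
  out <- matrix(0, h2, w2)
  for (i in 1:h2) for (j in 1:w2)
    out[i, j] <- mean(img[((i - 1) * f + 1):(i * f),
                          ((j - 1) * f + 1):(j * f)])
  out
}

# Spreadsheet-style summary statistics from first principles (explicit
# sums), independent of mean/sd/cor/lm.
oracle_validation_stats <- function(manual, algorithm) {
  n <- length(manual)
  success <- 100 - abs(manual - algorithm) / manual * 100
  mu <- sum(success) / n
  sigma <- sqrt(sum((success - mu)^2) / (n - 1))
  mx <- sum(manual) / n; my <- sum(algorithm) / n
  sxy <- sum((manual - mx) * (algorithm - my))
  sxx <- sum((manual - mx)^2)
  syy <- sum((algorithm - my)^2)
  r <- sxy / sqrt(sxx * syy)
  slope <- sxy / sxx
  list(mu = mu, sigma = sigma, r = r, slope = slope,
       intercept = my - slope * mx, r_squared = r^2)
}

# Deterministic pseudo-random 8-bit test image (plain base R RNG).
random_u8_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# success rate of a count_ears run against a scene truth
scene_success <- function(scene, ...) {
  success_rate(scene$truth$ear_count, count_ears(scene$image, ...)$ear_count)
}
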