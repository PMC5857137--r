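#' Synthetic canopy scene parameters
#'
#' Describes one synthetic zenithal canopy image with known ground truth:
#' bright elongated ear-shaped blobs (soft-edged ellipses at random
#' orientation) on a darker textured leaf/soil background, thin awn-like
#' bright line clutter radiating near each ear, and an optional smooth
#' illumination gradient.  All sizes are in pixels and all intensities on the
#' \[0, 255\] scale.
#'
#' The default ear dimensions put ear width on the order of the default
#' 64-pixel median window — the regime the pipeline's window choice targets,
#' where the window is small enough not to erase the smallest ears.  In
#' `"senescent"` mode the ear and background intensity distributions are
#' forced to overlap substantially (defaults: ears 162 +/- 14 on background
#' 146 +/- 14), emulating the contrast collapse of yellowed canopies at late
#' grain filling; `"normal"` mode (ears 200 +/- 12 on background 90 +/- 10)
#' emulates a green canopy around anthesis.
#'
#' @param width,height image size in pixels.
#' @param n_ears number of ears to render (>= 0).
#' @param ear_length,ear_width ranges (min, max) of ear ellipse axes in
#'   pixels.
#' @param ear_intensity,background_intensity `c(mean, sd)` of ear fill
#'   intensity and of background texture; `NULL` selects the contrast-mode
#'   default.
#' @param awn_density awn line segments rendered per ear.
#' @param awn_length range (min, max) of awn length in pixels.
#' @param illumination_gradient amplitude (+/- intensity units) of a smooth
#'   linear brightness gradient across the scene; 0 disables it.
#' @param contrast_mode `"normal"` or `"senescent"`.
#' @param min_separation minimum distance in pixels between ear centres.
#' @param seed integer random seed; scenes are fully deterministic given the
#'   spec.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width = 1024L, height = 1024L, n_ears = 50L,
                       ear_length = c(55, 75), ear_width = c(36, 48),
                       ear_intensity = NULL, background_intensity = NULL,
                       awn_density = 6L, awn_length = c(15, 40),
                       illumination_gradient = 12,
                       contrast_mode = c("normal", "senescent"),
                       min_separation = 40, seed = 1L) {
  contrast_mode <- match.arg(contrast_mode)
  if (is.null(ear_intensity))
    ear_intensity <- if (contrast_mode == "senescent") c(162, 14) else c(200, 12)
  if (is.null(background_intensity))
    background_intensity <- if (contrast_mode == "senescent") c(146, 14) else c(90, 10)
  if (n_ears < 0 || min_separation < 0)
    config_error("n_ears and min_separation must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_ears = as.integer(n_ears),
                 ear_length = ear_length, ear_width = ear_width,
                 ear_intensity = ear_intensity,
                 background_intensity = background_intensity,
                 awn_density = as.integer(awn_density),
                 awn_length = awn_length,
                 illumination_gradient = illumination_gradient,
                 contrast_mode = contrast_mode,
                 min_separation = min_separation,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate one synthetic canopy scene with ground truth
#'
#' Renders the scene described by a [scene_spec()]: ear centres are placed by
#' rejection sampling at the requested minimum separation (up to 1000
#' attempts per ear before the packing is declared infeasible), the
#' background is low-frequency smoothed noise (leaf texture) plus sparse
#' darker coarse patches (soil) and an optional linear illumination gradient,
#' ears are soft-edged ellipses, and awns are thin anti-aliased line
#' segments.  The returned image is RGB with a mild material chroma (greenish
#' leaves, yellowish ears) whose per-pixel band average equals the underlying
#' grey rendition before 8-bit rounding.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `canopy_scene`: list with `image`
#'   (`height x width x 3` array in \[0, 255\]) and `truth` (list with
#'   `ear_centers` data frame of 0-based `x`, `y`, `ear_count`, and
#'   `spec_echo`).  The truth count always equals the number of rendered
#'   ears.
#' @examples
#' sc <- generate_scene(scene_spec(width = 256, height = 256, n_ears = 2,
#'                                 seed = 3))
#' sc$truth$ear_count
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  margin <- min(ceiling(max(spec$ear_length) / 2) + 2,
                floor(min(H, W) / 4))

  # --- ear placement and per-ear parameters (drawn first so scenes with the
  #     same seed but different awn/contrast settings share the same layout)
  n <- spec$n_ears
  cx <- numeric(0); cy <- numeric(0)
  if (n > 0) {
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in seq_len(1000L)) {
        px <- stats::runif(1, margin, W - 1 - margin)
        py <- stats::runif(1, margin, H - 1 - margin)
        if (!length(cx) ||
            min((cx - px)^2 + (cy - py)^2) >= spec$min_separation^2) {
          cx <- c(cx, px); cy <- c(cy, py); ok <- TRUE; break
        }
      }
      if (!ok)
        config_error(sprintf(
          "infeasible packing: could not place ear %d of %d at min_separation %.0f",
          i, n, spec$min_separation))
    }
  }
  eL <- stats::runif(n, spec$ear_length[1], spec$ear_length[2])
  eW <- stats::runif(n, spec$ear_width[1], spec$ear_width[2])
  ang <- stats::runif(n, 0, pi)
  eint <- stats::rnorm(n, spec$ear_intensity[1], spec$ear_intensity[2])

  # --- background: fine leaf texture + sparse darker soil patches + gradient
  bgm <- spec$background_intensity[1]
  bgsd <- spec$background_intensity[2]
  L <- matrix(bgm, H, W)
  L <- L + smooth_noise(H, W, sigma = 4) * bgsd
  soil <- smooth_noise(H, W, sigma = 10)
  L <- L + pmin(soil, 0) * bgsd * 0.7
  if (spec$illumination_gradient > 0) {
    th <- stats::runif(1, 0, 2 * pi)
    plane <- outer(seq(-0.5, 0.5, length.out = H) * sin(th),
                   seq(-0.5, 0.5, length.out = W) * cos(th), `+`)
    L <- L + plane * 2 * spec$illumination_gradient
  }

  # --- ears: soft-edged rotated ellipses composited over the background
  C <- matrix(0, H, W)                      # total ear coverage (for chroma)
  for (i in seq_len(n)) {
    rb <- eL[i] / 2 + 3
    xs <- max(0, floor(cx[i] - rb)):min(W - 1, ceiling(cx[i] + rb))
    ys <- max(0, floor(cy[i] - rb)):min(H - 1, ceiling(cy[i] + rb))
    dx <- outer(rep(1, length(ys)), xs - cx[i])
    dy <- outer(ys - cy[i], rep(1, length(xs)))
    u <- dx * cos(ang[i]) + dy * sin(ang[i])
    v <- -dx * sin(ang[i]) + dy * cos(ang[i])
    r <- sqrt((u / (eL[i] / 2))^2 + (v / (eW[i] / 2))^2)
    e <- 0.08
    t <- pmin(pmax((1 + e - r) / (2 * e), 0), 1)
    cov <- t * t * (3 - 2 * t)              # smoothstep edge profile
    # domed shading: an ear is a lit cylinder, darker toward silhouette
    # edges and tips than along its central ridge
    shade <- 1 - 0.3 * pmin(r, 1)^2
    ri <- ys + 1L; ci <- xs + 1L
    L[ri, ci] <- L[ri, ci] * (1 - cov) + eint[i] * shade * cov
    C[ri, ci] <- pmax(C[ri, ci], cov)
  }

  # --- awns: 1-px anti-aliased bright segments radiating near each ear
  if (n > 0 && spec$awn_density > 0) {
    sx <- numeric(0); sy <- numeric(0); sv <- numeric(0)
    for (i in seq_len(n)) {
      for (a in seq_len(spec$awn_density)) {
        t0 <- stats::runif(1, -0.5, 0.5)
        bx <- cx[i] + t0 * eL[i] * cos(ang[i])
        by <- cy[i] + t0 * eL[i] * sin(ang[i])
        phi <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, spec$awn_length[1], spec$awn_length[2])
        s <- seq(0, len, by = 0.6)
        sx <- c(sx, bx + s * cos(phi))
        sy <- c(sy, by + s * sin(phi))
        sv <- c(sv, rep(eint[i] * 0.85, length(s)))
      }
    }
    L <- splat_points(L, sx, sy, sv)
  }

  # --- chroma: leaves slightly green, ears yellowish; band offsets cancel so
  #     the per-pixel band average equals L
  img <- array(0, c(H, W, 3L))
  img[, , 1L] <- L + 12 * C - 2
  img[, , 2L] <- L - 2 * C + 4
  img[, , 3L] <- L - 10 * C - 2
  img <- round(pmin(pmax(img, 0), 255))

  truth <- list(ear_centers = data.frame(x = cx, y = cy),
                ear_count = n, spec_echo = spec)
  structure(list(image = img, truth = truth), class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("canopy_scene: %d x %d px, %d ear(s), %s contrast, seed %d\n",
              x$truth$spec_echo$width, x$truth$spec_echo$height,
              x$truth$ear_count, x$truth$spec_echo$contrast_mode,
              x$truth$spec_echo$seed))
  invisible(x)
}

#' Generate a suite of synthetic scenes
#'
#' Generates `n_scenes` independent scenes whose per-scene seeds and ear
#' counts are drawn deterministically from the suite seed; ear counts are
#' uniform over `count_range` so the suite spans canopy densities.
#'
#' @param base a [scene_spec()] providing all parameters except `n_ears` and
#'   `seed`.
#' @param n_scenes number of scenes (>= 1).
#' @param seed suite seed.
#' @param count_range integer range (min, max) from which per-scene ear
#'   counts are drawn uniformly.
#' @return list of `canopy_scene` objects (class `scene_suite`), with the
#'   draw log (per-scene seed and ear count) in attribute `draw_log`.
#' @export
generate_suite <- function(base = scene_spec(), n_scenes, seed = 1L,
                           count_range = c(20L, 80L)) {
  if (n_scenes < 1L) config_error("n_scenes must be >= 1")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_scenes)
  counts <- sample(count_range[1]:count_range[2], n_scenes, replace = TRUE)
  scenes <- lapply(seq_len(n_scenes), function(i) {
    sp <- base
    sp$n_ears <- counts[i]
    sp$seed <- seeds[i]
    generate_scene(sp)
  })
  structure(scenes, class = "scene_suite",
            draw_log = data.frame(scene = seq_len(n_scenes), seed = seeds,
                                  n_ears = counts))
}

#' Write a scene image and its ground-truth marks to disk
#'
#' Writes the rendered scene as a PNG and its ear centres as a mark CSV
#' (columns `x`, `y`) readable by [read_marks()], so synthetic truths flow
#' through the same validation path as manual annotations.
#'
#' @param scene a `canopy_scene`.
#' @param image_path output PNG path.
#' @param truth_path output CSV path (optional).
#' @return `image_path`, invisibly.
#' @export
write_scene <- function(scene, image_path, truth_path = NULL) {
  stopifnot(inherits(scene, "canopy_scene"))
  write_raster(scene$image, image_path)
  if (!is.null(truth_path))
    utils::write.csv(scene$truth$ear_centers, truth_path, row.names = FALSE)
  invisible(image_path)
}

# internal: unit-variance smoothed Gaussian noise via circular FFT blur
smooth_noise <- function(H, W, sigma) {
  noise <- matrix(stats::rnorm(H * W), H, W)
  fu <- ifelse(0:(H - 1) > H / 2, 0:(H - 1) - H, 0:(H - 1)) / H
  fv <- ifelse(0:(W - 1) > W / 2, 0:(W - 1) - W, 0:(W - 1)) / W
  k <- exp(-2 * pi^2 * sigma^2 * outer(fu^2, fv^2, `+`))
  sm <- Re(stats::fft(stats::fft(noise) * k, inverse = TRUE)) / (H * W)
  sm / stats::sd(sm)
}

# internal: bilinear splat of bright sample points onto L (max-weight wins
# where samples land on the same pixel)
splat_points <- function(L, px, py, val) {
  H <- nrow(L); W <- ncol(L)
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  xi <- c(x0, x0 + 1, x0, x0 + 1)
  yi <- c(y0, y0, y0 + 1, y0 + 1)
  wt <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  vv <- rep(val, 4)
  keep <- xi >= 0 & xi < W & yi >= 0 & yi < H & wt > 0
  xi <- xi[keep]; yi <- yi[keep]; wt <- wt[keep]; vv <- vv[keep]
  if (!length(xi)) return(L)
  idx <- yi + 1 + xi * H
  o <- order(wt)
  idx <- idx[o]; wt <- wt[o]; vv <- vv[o]
  last <- !duplicated(idx, fromLast = TRUE)
  i2 <- idx[last]; w2 <- wt[last]; v2 <- vv[last]
  L[i2] <- L[i2] * (1 - w2) + v2 * w2
  L
}
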