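#' Laplacian frequency-enhancement settings
#'
#' The first pipeline stage multiplies the centred Fourier spectrum of the
#' input image by the enhancement gain `1 - H(u, v)`, where
#' `H(u, v) = -4 * pi^2 * (fu^2 + fv^2)` is the transfer function of the
#' Laplacian (second-derivative) filter in the frequency domain and
#' `(fu, fv)` are frequencies normalised to cycles per pixel,
#' `fu = (u - M/2) / M`, `fv = (v - N/2) / N` on the centred spectrum of an
#' `M x N` image.  The gain is exactly 1 at the spectrum centre (DC), so the
#' original image is retained as background while high frequencies — edges of
#' ears, awns and leaves — are amplified by up to `1 + 2 * pi^2` at the
#' corners of the spectrum.  Normalising frequencies to cycles per pixel
#' makes the enhancement invariant to image size.
#'
#' @param output_rescale how the enhanced image is mapped back to the nominal
#'   \[0, 255\] range: `"grid"` (default) rescales linearly between the
#'   `saturation` quantiles (values beyond them clamp to 0 or 255, the
#'   display-autoscale convention of interactive image software) and
#'   quantises to 1/256-grey steps, so the few extreme high-frequency
#'   responses — awn and edge spikes amplified up to `1 + 2 * pi^2`-fold —
#'   neither flatten the canopy signal nor make the scale of the subsequent
#'   peak-prominence tolerance depend on them; `"uint8"` is the same but
#'   rounded to whole greys (strict 8-bit semantics); `"none"` returns the
#'   raw inverse-transform values.  Within the unclamped range all three
#'   preserve intensity ordering, which is all the median and maxima stages
#'   consume.
#' @param saturation fraction of pixels clamped at each end of the range by
#'   the rescale (default 0.01; 0 gives a plain min-max rescale).
#' @return an object of class `laplacian_spec`.
#' @export
laplacian_spec <- function(output_rescale = c("grid", "uint8", "none"),
                           saturation = 0.01) {
  output_rescale <- match.arg(output_rescale)
  if (!is.finite(saturation) || saturation < 0 || saturation >= 0.5)
    config_error("saturation must be in [0, 0.5)")
  structure(list(output_rescale = output_rescale, saturation = saturation),
            class = "laplacian_spec")
}

#' Laplacian frequency enhancement of a single-channel image
#'
#' Computes `inverse-FFT[ (1 - H(u, v)) * FFT(image) ]` with the
#' size-normalised Laplacian transfer function described in
#' [laplacian_spec()], then (by default) rescales the result linearly to
#' \[0, 255\] and rounds to integers.  A constant image passes through
#' unchanged because its spectrum is concentrated at the centre, where the
#' gain is exactly 1.
#'
#' @param image single-channel numeric matrix (rows = y, cols = x); RGB input
#'   signals an error — reduce with [to_greyscale()] or let [count_ears()]
#'   apply its channel policy.
#' @param spec a [laplacian_spec()].
#' @return numeric matrix with the dimensions of `image`.
#' @examples
#' img <- matrix(128, 16, 16)
#' stopifnot(all(laplacian_enhance(img) == 128))
#' @export
laplacian_enhance <- function(image, spec = laplacian_spec()) {
  img <- as_grey_matrix(image, "laplacian_enhance")
  M <- nrow(img); N <- ncol(img)
  gain <- laplacian_gain(M, N)
  fw <- stats::fft(img)
  out <- Re(stats::fft(gain * fw, inverse = TRUE)) / (M * N)
  switch(spec$output_rescale,
         grid = rescale_range(out, steps = 256L, sat = spec$saturation),
         uint8 = rescale_range(out, steps = 1L, sat = spec$saturation),
         none = out)
}

# internal: enhancement gain 1 - H on the *unshifted* spectrum grid, i.e. the
# centred-gain grid permuted so that element [1, 1] is DC.  Frequencies are
# the signed DFT frequencies in cycles/pixel, identical (up to the sign of
# the Nyquist bin, which squares away) to (u - M/2)/M on a centred spectrum.
laplacian_gain <- function(M, N) {
  u <- 0:(M - 1); v <- 0:(N - 1)
  fu <- ifelse(u > M / 2, u - M, u) / M
  fv <- ifelse(v > N / 2, v - N, v) / N
  1 + 4 * pi^2 * outer(fu^2, fv^2, `+`)
}

# internal: linear rescale to [0, 255] between the sat and 1 - sat quantiles
# (tails clamp), quantised to 1/steps grey levels; a constant image is
# clamped/quantised but otherwise unchanged
rescale_range <- function(x, steps = 256L, sat = 0) {
  r <- if (sat > 0) stats::quantile(x, c(sat, 1 - sat), names = FALSE)
       else range(x)
  # constant up to FFT round-off: pass through (clamped to the value range)
  if (r[2] - r[1] <= 1e-8 * max(1, abs(r[1]), abs(r[2])))
    return(round(pmin(pmax(x, 0), 255) * steps) / steps)
  y <- pmin(pmax(x, r[1]), r[2])
  round((y - r[1]) / (r[2] - r[1]) * 255 * steps) / steps
}
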