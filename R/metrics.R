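#' @title Image quality metrics
#' @description PSNR, SSIM and relative l2-norm error (RLNE) between a
#' reconstruction and its ground truth, on `[0, 1]`-normalized images.
#' @name metrics
NULL

check_same_shape <- function(x, ref) {
  assert_image(x, "x"); assert_image(ref, "ref")
  if (!identical(dim(x), dim(ref)))
    stop_mcnedi("x and ref must have the same shape")
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(\mathrm{peak}^2 / \mathrm{MSE})} in dB; identical
#' images give `Inf`. The peak defaults to 1 for normalized images (absolute
#' dB values therefore depend on this convention).
#'
#' @param x reconstruction. @param ref ground truth. @param peak peak value.
#' @return scalar dB.
#' @export
psnr <- function(x, ref, peak = 1.0) {
  check_same_shape(x, ref)
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard settings: 11x11 Gaussian window of
#' standard deviation 1.5, `K1 = 0.01`, `K2 = 0.03`, dynamic range `L = 1`,
#' Gaussian-weighted (population) moments. The local SSIM map is computed
#' over the full image and averaged over the interior (5-pixel border
#' excluded), so border padding has no influence — this matches the
#' reference implementation used for cross-validation in the test suite.
#'
#' @param x reconstruction. @param ref ground truth (same shape, >= 11x11).
#' @param L dynamic range (default 1).
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(x, ref, L = 1.0) {
  check_same_shape(x, ref)
  if (min(dim(x)) < 11L) stop_mcnedi("ssim requires images of at least 11x11")
  k <- gaussian_kernel(11L, 1.5)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_x <- conv2_replicate(x, k)
  mu_y <- conv2_replicate(ref, k)
  sxx <- conv2_replicate(x * x, k) - mu_x^2
  syy <- conv2_replicate(ref * ref, k) - mu_y^2
  sxy <- conv2_replicate(x * ref, k) - mu_x * mu_y
  smap <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
          ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  h <- nrow(x); w <- ncol(x)
  mean(smap[6:(h - 5L), 6:(w - 5L)])
}

#' Relative l2-norm error
#'
#' \eqn{\|x - \mathrm{ref}\|_2 / \|\mathrm{ref}\|_2} over all pixels; lower
#' is better, 0 iff identical.
#'
#' @param x reconstruction. @param ref ground truth (not all zeros).
#' @return nonnegative scalar.
#' @export
rlne <- function(x, ref) {
  check_same_shape(x, ref)
  denom <- sqrt(sum(ref^2))
  if (denom == 0) stop_mcnedi("reference image is all zeros")
  sqrt(sum((x - ref)^2)) / denom
}

#' All three quality metrics at once
#'
#' @inheritParams psnr
#' @return list of class `metric_report` with `psnr`, `ssim`, `rlne`,
#'   `peak`.
#' @export
metric_report <- function(x, ref, peak = 1.0) {
  structure(list(psnr = psnr(x, ref, peak), ssim = ssim(x, ref),
                 rlne = rlne(x, ref), peak = peak),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> PSNR %.2f dB  SSIM %.4f  RLNE %.4f\n",
              x$psnr, x$ssim, x$rlne))
  invisible(x)
}
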