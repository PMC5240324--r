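#' @title Synthetic multi-contrast test data
#' @description
#' Generators for everything the experiments need: 9x9 two-level toy images
#' with a diagonal-constant structure, multi-contrast brain-like phantoms
#' that share one label structure under two different monotone intensity
#' maps (T1-like and T2-like), the blur + downsample degradation operator,
#' and Rician noise. All randomness is controlled by explicit seeds.
#' @name synthetic-data
NULL

#' 9x9 two-level toy image with diagonal structure
#'
#' Builds the canonical toy example of a multi-contrast pair member: the
#' intensity depends only on `row - col` (constant along the main diagonal
#' direction), taking `omega_p` where `row - col >= 0` and `omega_q`
#' elsewhere. For every admissible level pair, the diagonal-lattice
#' regression weights of the central region are `[0.5, 0, 0, 0.5]` and sum
#' to 1 exactly.
#'
#' @param omega_p,omega_q the two intensity levels, in `[0, 1]`, distinct.
#' @param size image side length (default 9).
#' @return `size x size` numeric matrix.
#' @export
make_toy_pair <- function(omega_p, omega_q, size = 9L) {
  if (!is.finite(omega_p) || !is.finite(omega_q) ||
      omega_p < 0 || omega_p > 1 || omega_q < 0 || omega_q > 1)
    stop_mcnedi("levels must be finite values in [0, 1]")
  if (omega_p == omega_q) stop_mcnedi("the two levels must differ")
  r <- matrix(seq_len(size), size, size)
  ifelse(r - t(r) >= 0, omega_p, omega_q)
}

# Normalized Gaussian kernel, odd size.
gaussian_kernel <- function(size = 3L, sigma = 0.5) {
  stopifnot(size %% 2L == 1L, sigma > 0)
  r <- (size - 1L) %/% 2L
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Degradation specification (blur + downsample + optional noise)
#'
#' The forward model that turns a HR ground truth into its LR counterpart:
#' convolution with a normalized `3x3` Gaussian of standard deviation 0.5
#' (replicate border), then x2 decimation keeping the anchored samples
#' `HR[2i-1, 2j-1]`. Optionally Rician noise at `noise_level` (fraction of
#' the maximum intensity) is applied to the HR image *before* blurring.
#'
#' @param kernel_size Gaussian kernel size (default 3).
#' @param kernel_sigma Gaussian standard deviation (default 0.5).
#' @param factor decimation factor, must be 2.
#' @param noise_level Rician noise level as a fraction of max intensity
#'   (default 0; the study levels are 0.01, 0.03, 0.05).
#' @param seed RNG seed for the noise draw.
#' @return list of class `degradation_spec`.
#' @export
degradation_spec <- function(kernel_size = 3L, kernel_sigma = 0.5,
                             factor = 2L, noise_level = 0, seed = 1L) {
  if (!identical(as.integer(factor), 2L)) stop_mcnedi("factor must be 2")
  if (noise_level < 0) stop_mcnedi("noise_level must be >= 0")
  structure(list(kernel_size = as.integer(kernel_size),
                 kernel_sigma = kernel_sigma, factor = 2L,
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Degrade a HR image to its LR counterpart
#'
#' @param hr numeric matrix with even dimensions.
#' @param spec a [degradation_spec()].
#' @return `nrow/2 x ncol/2` matrix.
#' @export
degrade <- function(hr, spec = degradation_spec()) {
  assert_image(hr, "hr")
  if (any(dim(hr) %% 2L != 0L)) stop_mcnedi("hr must have even dimensions")
  if (spec$noise_level > 0)
    hr <- clip01(add_rician_noise(hr, spec$noise_level, spec$seed))
  k <- gaussian_kernel(spec$kernel_size, spec$kernel_sigma)
  blurred <- conv2_replicate(hr, k)
  blurred[seq(1L, nrow(hr), by = 2L), seq(1L, ncol(hr), by = 2L), drop = FALSE]
}

#' Add Rician noise to an image
#'
#' Magnitude-MRI noise model: independent zero-mean Gaussian noise of
#' standard deviation `level * max(image)` is added to the real and
#' imaginary channels and the modulus is taken,
#' `out = |(I + g1) + i g2|`. At level 0 the output equals `|I| = I` for
#' nonnegative images. Output values can exceed the input maximum; clip or
#' renormalize downstream as appropriate.
#'
#' @param image numeric matrix (nonnegative).
#' @param level noise standard deviation as a fraction of `max(image)`.
#' @param seed RNG seed (draw is deterministic per seed).
#' @return noisy matrix, same shape.
#' @export
add_rician_noise <- function(image, level, seed = 1L) {
  assert_image(image)
  if (level < 0) stop_mcnedi("noise level must be >= 0")
  if (level == 0) return(abs(image))
  sigma <- level * max(image)
  with_seed(seed, {
    g1 <- matrix(stats::rnorm(length(image), 0, sigma), nrow(image))
    g2 <- matrix(stats::rnorm(length(image), 0, sigma), nrow(image))
    sqrt((image + g1)^2 + g2^2)
  })
}

#' Generate a multi-contrast brain-like phantom pair
#'
#' Builds a shared piecewise label structure of nested, smoothly perturbed
#' elliptical layers (background, "skull", tissue layers, "ventricle") and
#' renders it under two monotone intensity maps: `map_a` ascending with
#' label depth (T1-like) and `map_b` a distinct, partially inverted map
#' (T2-like). A light 3x3 Gaussian smoothing (sigma 0.5) emulates
#' partial-volume averaging at tissue boundaries. Both renderings share
#' label boundaries pixel-for-pixel and are deterministic per seed.
#'
#' @param seed integer seed.
#' @param size `(height, width)`, both `>= 64`.
#' @param n_regions number of labels including background (`>= 2`,
#'   default 5).
#' @return list of class `contrast_pair` with `labels` (integer matrix,
#'   values `0..n_regions-1`), `image_a`, `image_b` (normalized matrices),
#'   `map_a`, `map_b` (label -> intensity tables), `seed`.
#' @export
make_brain_phantom <- function(seed, size = c(128L, 128L), n_regions = 5L) {
  if (any(size < 64L)) stop_mcnedi("phantom size must be at least 64x64")
  if (n_regions < 2L) stop_mcnedi("n_regions must be >= 2")
  h <- as.integer(size[1]); w <- as.integer(size[2])
  n_bound <- n_regions - 1L
  with_seed(as.integer(seed), {
    # nested boundary radii (fractions of the half-extent), outermost first
    bases <- seq(0.88, 0.22, length.out = n_bound)
    gap <- if (n_bound > 1L) min(abs(diff(bases))) else 0.3
    amp <- 0.35 * gap
    coef <- lapply(seq_len(n_bound), function(k)
      list(a = stats::runif(3, -amp, amp), phi = stats::runif(3, 0, 2 * pi)))
    cy <- h / 2 + stats::runif(1, -0.02, 0.02) * h
    cx <- w / 2 + stats::runif(1, -0.02, 0.02) * w
    ecc <- stats::runif(1, 0.75, 0.95)   # vertical/horizontal axis ratio

    u <- (row(matrix(0, h, w)) - cy) / (h / 2)
    v <- (col(matrix(0, h, w)) - cx) / (w / 2) / ecc
    rr <- sqrt(u^2 + v^2)
    th <- atan2(u, v)
    labels <- matrix(0L, h, w)
    for (k in seq_len(n_bound)) {
      Rk <- bases[k] * (1 + coef[[k]]$a[1] * cos(2 * th + coef[[k]]$phi[1])
                          + coef[[k]]$a[2] * cos(3 * th + coef[[k]]$phi[2])
                          + coef[[k]]$a[3] * cos(5 * th + coef[[k]]$phi[3]))
      labels <- labels + (rr < Rk)
    }

    # T1-like: ascending with depth; T2-like: partially inverted, non-affine.
    # Small seeded jitter keeps pairs distinct across seeds while preserving
    # a minimum contrast of ~0.1 between adjacent (nested) labels.
    jit <- function(n) stats::runif(n, -0.03, 0.03)
    map_a <- clip01(seq(0.05, 0.95, length.out = n_regions) + jit(n_regions))
    base_b <- 1 - sqrt(seq(0.05, 0.95, length.out = n_regions))
    base_b <- (base_b - min(base_b)) / (max(base_b) - min(base_b))
    base_b <- 0.05 + 0.9 * base_b
    # partial inversion: swap two interior levels so map_b is not monotone
    # in label order everywhere (distinct tissue contrast), while keeping
    # adjacent labels separated
    if (n_regions >= 4L) {
      i1 <- 2L; i2 <- n_regions - 1L
      tmp <- base_b[i1]; base_b[i1] <- base_b[i2]; base_b[i2] <- tmp
    }
    map_b <- clip01(base_b + jit(n_regions))
    k <- gaussian_kernel(3L, 0.5)
    image_a <- clip01(conv2_replicate(matrix(map_a[labels + 1L], h, w), k))
    image_b <- clip01(conv2_replicate(matrix(map_b[labels + 1L], h, w), k))
    structure(list(labels = labels, image_a = image_a, image_b = image_b,
                   map_a = map_a, map_b = map_b, seed = as.integer(seed)),
              class = "contrast_pair")
  })
}

#' @export
print.contrast_pair <- function(x, ...) {
  cat("<contrast_pair>", paste(dim(x$labels), collapse = "x"),
      "labels 0..", max(x$labels), " seed", x$seed, "\n")
  invisible(x)
}
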