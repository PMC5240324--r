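# x2 engines: expansion, per-pixel interpolation, NEDI, multi-contrast.

test_that("expand_nearest replicates 2x2 blocks with the anchoring convention", {
  lr <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)
  hr <- expand_nearest(lr)
  expect_identical(dim(hr), c(4L, 4L))
  for (i in 1:2) for (j in 1:2)
    expect_true(all(hr[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] == lr[i, j]))
  expect_identical(hr[seq(1, 4, 2), seq(1, 4, 2)], lr)
  expect_error(expand_nearest(lr, factor = 3), "factor")
})

test_that("interpolate_pixel is b's', clipped", {
  expect_equal(interpolate_pixel(c(0.25, 0.25, 0.25, 0.25), rep(0.6, 4)), 0.6)
  expect_equal(interpolate_pixel(c(0.5, 0, 0, 0.5), c(0.78, 0, 0, 0.78)), 0.78)
  expect_equal(interpolate_pixel(c(1, 0, 0, 0), c(0.33, 0.9, 0.1, 0.5)), 0.33)
  expect_equal(interpolate_pixel(c(2, 0, 0, 2), rep(1, 4)), 1)  # clipped
  expect_error(interpolate_pixel(c(1, 0, 0), rep(0, 4)), "length 4")
})

test_that("bicubic_baseline reproduces ramps and keeps shape/anchoring", {
  cimg <- matrix(0.42, 10, 10)
  expect_true(all(abs(bicubic_baseline(cimg) - 0.42) < 1e-12))
  ramp <- matrix(rep(seq(0.1, 0.9, length.out = 16), each = 16), 16, 16)
  up <- bicubic_baseline(ramp)
  expect_identical(dim(up), c(32L, 32L))
  # interior even columns sit exactly midway on a linear ramp
  step <- (0.9 - 0.1) / 15
  expect_equal(up[10, 8], ramp[5, 4] + step / 2, tolerance = 1e-12)
  expect_identical(up[seq(1, 32, 2), seq(1, 32, 2)], ramp)
})

test_that("nedi_upscale: constants, diagonal structure, data consistency", {
  cimg <- matrix(0.3, 12, 12)
  res <- nedi_upscale(cimg)
  expect_true(all(abs(res$image - 0.3) < 1e-12))
  expect_equal(res$edge_fraction, 0)

  # diagonal-constant two-level signal: odd-odd (0-based) HR pixels average
  # two equal diagonal neighbors -> structure reproduced exactly (interior)
  g <- function(d) ifelse(d >= 0, 0.1, 0.88)
  lr <- outer(1:16, 1:16, function(r, c2) g(r - c2))
  hr_true <- outer(1:32, 1:32, function(r, c2) g(r - c2))
  res <- nedi_upscale(lr)
  # pass-1 pixels: edge pixels reproduce the structure exactly via the
  # [.5, 0, 0, .5] weights; deep-constant pixels exactly via bicubic.
  # (pixels whose bicubic support straddles the step but whose quad is
  # constant legitimately ring and are excluded.)
  for (i in 4:13) for (j in 4:13) {
    d <- i - j
    if (d %in% c(-1L, 0L) || d >= 4L || d <= -5L)
      expect_equal(res$image[2 * i, 2 * j], hr_true[2 * i, 2 * j],
                   tolerance = 1e-9)
  }
  expect_identical(res$image[seq(1, 32, 2), seq(1, 32, 2)], lr)
  expect_gt(res$edge_fraction, 0)
  expect_error(nedi_upscale(matrix(0.1, 8, 8)), "9x9")
})

test_that("engines are deterministic and beat nearest-neighbor on a phantom", {
  ph <- make_brain_phantom(7, size = c(64, 64))
  hr <- ph$image_b
  lr <- degrade(hr)
  r1 <- nedi_upscale(lr)
  r2 <- nedi_upscale(lr)
  expect_identical(r1$image, r2$image)
  expect_gt(psnr(r1$image, hr), psnr(expand_nearest(lr), hr))
  m1 <- multicontrast_upscale(lr, ph$image_a)
  m2 <- multicontrast_upscale(lr, ph$image_a)
  expect_identical(m1$image, m2$image)
  expect_gt(psnr(m1$image, hr), psnr(bicubic_baseline(lr), hr))
  # data consistency for both engines
  expect_identical(r1$image[seq(1, 64, 2), seq(1, 64, 2)], lr)
  expect_identical(m1$image[seq(1, 64, 2), seq(1, 64, 2)], lr)
  expect_true(all(r1$image >= 0 & r1$image <= 1))
  expect_true(all(m1$image >= 0 & m1$image <= 1))
})

test_that("multicontrast_upscale validates shapes and handles constants", {
  lr <- matrix(0.5, 12, 12)
  ref <- matrix(stats::runif(576), 24, 24)
  out <- multicontrast_upscale(lr, ref)
  expect_true(all(abs(out$image - 0.5) < 1e-12))
  expect_error(multicontrast_upscale(lr, ref[1:23, ]), "twice the dimensions")
})

test_that("multicontrast weights are invariant to reference rescaling", {
  ph <- make_brain_phantom(5, size = c(64, 64))
  lr <- degrade(ph$image_b)
  base <- multicontrast_upscale(lr, ph$image_a)
  for (alpha in c(0.5, 2)) {
    scaled <- multicontrast_upscale(lr, alpha * ph$image_a)
    expect_identical(scaled$image, base$image)
  }
})

test_that("self-referenced multi-contrast matches NEDI-quality on a diagonal phantom", {
  g <- function(d) ifelse(d >= 0, 0.15, 0.8)
  hr <- outer(1:40, 1:40, function(r, c2) g(r - c2))
  lr <- degrade(hr)
  res_mc <- multicontrast_upscale(lr, hr)
  res_nedi <- nedi_upscale(lr)
  expect_gte(psnr(res_mc$image, hr), psnr(res_nedi$image, hr))
})
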