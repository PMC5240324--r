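# Readers/writers, normalization, geometric utilities.

test_that("normalize_unit is the min-max affine map with documented conventions", {
  img <- matrix(c(0, 128, 255, 128), 2, 2)
  nm <- normalize_unit(img)
  expect_equal(sort(unique(as.numeric(nm))), c(0, 128 / 255, 1))
  expect_equal(as.numeric(normalize_unit(matrix(c(0.2, 0.7, 0.2, 0.7), 2, 2))),
               c(0, 1, 0, 1))
  # constant maps to zeros; idempotence; input untouched
  expect_true(all(normalize_unit(matrix(3, 4, 4)) == 0))
  r <- matrix(stats::runif(64, 2, 7), 8, 8)
  expect_equal(normalize_unit(normalize_unit(r)), normalize_unit(r))
  expect_error(normalize_unit(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("shift_image translates with edge replication", {
  img <- matrix(0, 9, 9); img[5, 5] <- 1
  expect_identical(shift_image(img, "slant", 0), img)
  expect_equal(which(shift_image(img, "slant", 1) == 1, arr.ind = TRUE)[1, ],
               c(row = 6L, col = 6L))
  expect_equal(which(shift_image(img, "anti-slant", 1) == 1, arr.ind = TRUE)[1, ],
               c(row = 6L, col = 4L))
  expect_equal(which(shift_image(img, "vertical", 2) == 1, arr.ind = TRUE)[1, ],
               c(row = 7L, col = 5L))
  expect_equal(which(shift_image(img, "horizontal", 2) == 1, arr.ind = TRUE)[1, ],
               c(row = 5L, col = 7L))
  # interior of a slant-2 shift equals the original offset by (2, 2)
  r <- matrix(stats::runif(144), 12, 12)
  sh <- shift_image(r, "slant", 2)
  expect_identical(sh[3:12, 3:12], r[1:10, 1:10])
  expect_identical(dim(sh), dim(r))
  expect_error(shift_image(r, "diag", 1), "unknown direction")
  expect_error(shift_image(r, "slant", 6), "too large")
})

test_that("PNG round-trips through the png codec", {
  f <- tempfile(fileext = ".png")
  img <- matrix(128 / 255, 16, 16)
  save_image(img, f)
  back <- load_image(f)
  expect_identical(dim(back), c(16L, 16L))
  expect_true(all(back == 128))
  expect_identical(attr(back, "bit_depth"), 8L)
  # gradient round-trip at 8-bit quantization
  g <- matrix(seq(0, 1, length.out = 64), 8, 8)
  save_image(g, f)
  expect_equal(load_image(f) / 255, g, tolerance = 1 / 255,
               ignore_attr = TRUE)
  # truncated file errors without partial output
  writeBin(readBin(f, "raw", 20), f)
  expect_error(load_image(f), "PNG")
})

test_that("16-bit TIFF round-trip is bit-exact", {
  f <- tempfile(fileext = ".tif")
  set.seed(4)
  ints <- matrix(sample(0:65535, 32 * 20, replace = TRUE), 32, 20)
  save_image(ints / 65535, f, bit_depth = 16L)
  back <- load_image(f)
  expect_identical(attr(back, "bit_depth"), 16L)
  expect_equal(back, ints, ignore_attr = TRUE)
  # save -> load -> save -> load reproduces exactly (levels like 0.78 survive)
  save_image(back / 65535, f, bit_depth = 16L)
  expect_equal(load_image(f), ints, ignore_attr = TRUE)
  # 8-bit variant
  save_image(matrix(0.5, 9, 9), f, bit_depth = 8L)
  b8 <- load_image(f)
  expect_true(all(b8 == 128) && attr(b8, "bit_depth") == 8L)
  writeBin(readBin(f, "raw", 10), f)
  expect_error(load_image(f), "TIFF")
})

test_that("NIfTI codec round-trips and slices, and agrees with nibabel", {
  f <- tempfile(fileext = ".nii")
  img <- matrix(stats::runif(64 * 48), 64, 48)
  save_image(img, f)
  back <- load_image(f)
  expect_equal(back, img, tolerance = 1e-6, ignore_attr = TRUE)
  # nibabel as the independent oracle: read ours, write a 3D volume for us
  out <- run_python(sprintf("
import nibabel as nib, numpy as np
v = np.asanyarray(nib.load('%s').dataobj)
print(v.shape[0], v.shape[1], float(v[2, 3]), float(v.mean()))
a = (np.arange(64*64*10).reshape(64, 64, 10) %% 257).astype(np.float32)
nib.save(nib.Nifti1Image(a, np.eye(4)), '%s')
", f, sub("\\.nii$", "_vol.nii", f)))
  vals <- as.numeric(strsplit(out, " ")[[1]])
  expect_equal(vals[1:2], c(64, 48))
  expect_equal(vals[3], img[3, 4], tolerance = 1e-6)   # nibabel is 0-based
  expect_equal(vals[4], mean(img), tolerance = 1e-6)
  vol <- sub("\\.nii$", "_vol.nii", f)
  expect_error(load_image(vol), "slice_axis")
  sl <- load_image(vol, slice_axis = 3, slice_index = 5)
  expect_identical(dim(sl), c(64L, 64L))
  a_sl <- matrix((((seq_len(64 * 64 * 10) - 1)[seq(5, 64 * 64 * 10, 10)]) %% 257),
                 64, 64, byrow = TRUE)
  expect_equal(sl, a_sl, ignore_attr = TRUE)
})

test_that("load_image errors are informative", {
  expect_error(load_image(tempfile(fileext = ".png")), "not found")
  fx <- tempfile(fileext = ".xyz"); writeLines("x", fx)
  expect_error(load_image(fx), "format")
  # multi-channel PNG demands explicit channel selection
  f <- tempfile(fileext = ".png")
  png::writePNG(array(stats::runif(48), c(4, 4, 3)), f)
  expect_error(load_image(f), "channel")
  ch <- load_image(f, channel = 2)
  expect_identical(dim(ch), c(4L, 4L))
})
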