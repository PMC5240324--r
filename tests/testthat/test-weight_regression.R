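# Local patch sampling, least-squares weights, edge rule.

test_that("extract_region_samples has the contracted geometry", {
  img <- matrix(stats::runif(15 * 15), 15, 15)
  smp <- extract_region_samples(img, c(8, 8), lattice = "diagonal")
  expect_length(smp$y, 49L)
  expect_equal(dim(smp$X), c(49L, 4L))
  # row i of X holds the j-th lattice neighbor of the pixel giving y_i
  grid <- expand.grid(dc = -3:3, dr = -3:3)
  k <- sample.int(49L, 5L)
  for (i in k) {
    r <- 8 + grid$dr[i]; c2 <- 8 + grid$dc[i]
    expect_identical(smp$y[i], img[r, c2])
    expect_identical(smp$X[i, ], c(img[r - 1, c2 - 1], img[r - 1, c2 + 1],
                                   img[r + 1, c2 - 1], img[r + 1, c2 + 1]))
  }
  # axial lattice, spacing 2, region 13 -> (13 - 4)^2 = 81 patches
  smp2 <- extract_region_samples(img, c(8, 8), lattice = "axial",
                                 spacing = 2L, region = 13L)
  expect_length(smp2$y, 81L)
  expect_identical(smp2$X[41, ], c(img[6, 8], img[8, 10], img[10, 8], img[8, 6]))

  expect_error(extract_region_samples(img, c(8, 8), region = 8L), "odd")
  expect_error(extract_region_samples(img, c(8, 8), spacing = 0L), "spacing")
  expect_error(extract_region_samples(matrix(0, 5, 5), c(3, 3)), "9x9")
})

test_that("constant and diagonal-constant structures sample as expected", {
  cimg <- matrix(0.4, 12, 12)
  smp <- extract_region_samples(cimg, c(6, 6))
  expect_true(all(smp$y == 0.4) && all(smp$X == 0.4))
  # f(r,c) = g(r - c): diagonal columns 1 (UL) and 4 (LR) equal y exactly
  dimg <- diag_step_image(20)
  smp <- extract_region_samples(dimg, c(10, 10))
  expect_identical(smp$X[, 1], smp$y)
  expect_identical(smp$X[, 4], smp$y)
})

test_that("estimate_weights matches the normal-equation oracle on full-rank systems", {
  set.seed(11)
  for (k in 1:200) {
    sys <- random_system()
    b_ne <- solve(crossprod(sys$X), crossprod(sys$X, sys$y))  # (X'X)^-1 X'y
    w <- estimate_weights(sys)
    expect_equal(w$b, as.numeric(b_ne), tolerance = 1e-10)
    expect_identical(w$rank, 4L)
    # residual orthogonality X'(y - Xb) = 0
    expect_lt(max(abs(crossprod(sys$X, sys$y - sys$X %*% w$b))), 1e-10)
  }
})

test_that("rank-deficient systems get the minimal-norm solution", {
  set.seed(12)
  for (k in 1:100) {
    sys <- random_system(rank_deficient = TRUE)
    w <- estimate_weights(sys)
    expect_identical(w$rank, 3L)
    b_or <- svd_minnorm_oracle(sys$y, sys$X)
    expect_equal(w$b, b_or, tolerance = 1e-8)
    # any LS minimizer differs by null-space vectors; minimal norm picks the
    # symmetric split between the duplicated columns 1 and 4
    expect_equal(w$b[1], w$b[4], tolerance = 1e-8)
  }
})

test_that("weights are invariant to positive rescaling of the region", {
  set.seed(13)
  sys <- random_system()
  b0 <- estimate_weights(sys)$b
  for (alpha in c(0.5, 2, 0.037, 119.5)) {
    b1 <- estimate_weights(list(y = alpha * sys$y, X = alpha * sys$X))$b
    if (alpha %in% c(0.5, 2)) expect_identical(b1, b0)  # power-of-two: exact
    else expect_equal(b1, b0, tolerance = 1e-12)
  }
  img <- diag_step_image(20, 0.1, 0.9)
  smp <- extract_region_samples(img, c(10, 10))
  b_img <- estimate_weights(smp)$b
  b_scaled <- estimate_weights(list(y = 0.5 * smp$y, X = 0.5 * smp$X))$b
  expect_identical(b_img, b_scaled)
})

test_that("two-level diagonal toy images give weights [0.5, 0, 0, 0.5]", {
  # all six contrast pairs of the toy-example table
  pairs <- list(c(0, 0.78), c(0.39, 0.78), c(0.76, 0.78),
                c(0.78, 0.76), c(0.78, 0.39), c(0.78, 0))
  for (p in pairs) {
    img <- make_toy_pair(p[1], p[2])
    w <- estimate_weights(extract_region_samples(img, c(5, 5)))
    expect_equal(w$b, c(0.5, 0, 0, 0.5), tolerance = 1e-12)
    expect_equal(sum_of_weights(w), 1, tolerance = 1e-12)
    expect_lt(w$residual_norm, 1e-12)
  }
})

test_that("sum_of_weights is plain arithmetic over the 4 taps", {
  expect_equal(sum_of_weights(c(0.25, 0.25, 0.25, 0.25)), 1)
  expect_equal(sum_of_weights(c(-0.19, 0.70, 0.55, -0.07)), 0.99)
})

test_that("edge_mask flags exactly the high-variance pixels", {
  cimg <- matrix(0.3, 16, 16)
  expect_false(any(edge_mask(cimg)$mask))
  # pixel whose 4 diagonal neighbors are {0, 0, .78, .78}:
  # population variance = 0.78^2/4 = 0.1521 > 1e-4
  img <- matrix(0, 16, 16)
  img[7, 7] <- 0.78; img[7, 9] <- 0.78
  em <- edge_mask(img, lattice = "diagonal")
  expect_true(em$mask[8, 8])
  expect_equal(em$threshold, 1e-4)
  nb <- c(img[7, 7], img[7, 9], img[9, 7], img[9, 9])
  expect_equal(mean((nb - mean(nb))^2), 0.1521)
  # variance exactly at the threshold is not an edge (strict inequality)
  flat <- matrix(0.5, 16, 16)
  expect_false(any(edge_mask(flat, threshold = 0)$mask))
  expect_error(edge_mask(2 * img), "normalized")
})
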