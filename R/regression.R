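#' @title Local regression weights
#' @description
#' The statistical core of NEDI-style interpolation: within a local square
#' region, every interior pixel \eqn{y_i} is modeled as a linear combination
#' of its 4 lattice neighbors \eqn{x_{i,1..4}} plus residual,
#' \deqn{y_i = b_1 x_{i,1} + b_2 x_{i,2} + b_3 x_{i,3} + b_4 x_{i,4} +
#'   \varepsilon_i,}
#' and the 4 weights are estimated by least squares over all patches in the
#' region (49 patches for the default 9x9 region). The weights are invariant
#' to global intensity scaling, which is the mechanism that lets one image
#' contrast lend its weights to another.
#' @name weight-regression
NULL

# Neighbor displacement stencils, per lattice.  Column order is a package-wide
# contract: the same order is used at estimation and at interpolation time.
#   diagonal: upper-left, upper-right, lower-left, lower-right
#   axial:    up, right, down, left
lattice_offsets <- function(lattice, spacing) {
  s <- as.integer(spacing)
  switch(lattice,
    diagonal = cbind(dr = c(-s, -s,  s, s), dc = c(-s,  s, -s,  s)),
    axial    = cbind(dr = c(-s,  0,  s, 0), dc = c( 0,  s,  0, -s)),
    stop_mcnedi("unknown lattice '", lattice, "'"))
}

#' Sample the local patch system of a region
#'
#' Collects, for every patch center inside a `region x region` window around
#' `center`, the center intensity and its 4 lattice neighbors. Patch centers
#' are all pixels whose neighbors still fall inside the window, i.e. a
#' `(region - 2 spacing)^2` grid in raster order: 49 patches for the default
#' 9x9 region at spacing 1. The image is replicate-padded, so regions
#' centered near (or on) the image border are always well defined.
#'
#' @param image numeric matrix (intensities in `[0, 1]`).
#' @param center `(row, col)` of the region center, 1-based.
#' @param lattice `"diagonal"` (neighbors at the 4 diagonal corners) or
#'   `"axial"` (up/right/down/left).
#' @param spacing positive integer neighbor distance.
#' @param region odd region size `>= 5` (default 9).
#' @return an object of class `region_samples`: a list with `y` (length
#'   \eqn{n} vector), `X` (\eqn{n \times 4} matrix), `center`, `lattice`,
#'   `spacing`, `region`.
#' @export
extract_region_samples <- function(image, center, lattice = c("diagonal", "axial"),
                                   spacing = 1L, region = 9L) {
  assert_image(image)
  lattice <- match.arg(lattice)
  if (nrow(image) < 9L || ncol(image) < 9L)
    stop_mcnedi("region sampling requires an image of at least 9x9")
  if (length(center) != 2L || any(center < 1) ||
      center[1] > nrow(image) || center[2] > ncol(image))
    stop_mcnedi("center must be a (row, col) position inside the image")
  region <- as.integer(region)
  if (region < 5L || region %% 2L == 0L)
    stop_mcnedi("region must be an odd integer >= 5")
  spacing <- as.integer(spacing)
  if (spacing < 1L) stop_mcnedi("spacing must be >= 1")
  half_in <- (region - 1L) %/% 2L - spacing  # patch-center half-extent
  if (half_in < 0L) stop_mcnedi("spacing too large for region size")

  pad <- (region - 1L) %/% 2L + spacing
  p <- pad_replicate(image, pad)
  r0 <- as.integer(center[1]) + pad
  c0 <- as.integer(center[2]) + pad
  grid <- expand.grid(dc = -half_in:half_in, dr = -half_in:half_in)  # raster order
  rows <- r0 + grid$dr; cols <- c0 + grid$dc
  y <- p[cbind(rows, cols)]
  off <- lattice_offsets(lattice, spacing)
  X <- vapply(1:4, function(j) p[cbind(rows + off[j, 1], cols + off[j, 2])],
              numeric(length(y)))
  structure(list(y = y, X = X, center = as.integer(center), lattice = lattice,
                 spacing = spacing, region = region),
            class = "region_samples")
}

#' Estimate the 4 regression weights of a region by least squares
#'
#' Solves \eqn{\min_b \|y - X b\|_2}. When `X` has full column rank this is
#' the normal-equation solution \eqn{(X^T X)^{-1} X^T y}; in general the
#' minimal-norm least-squares solution is returned (SVD with singular values
#' below `1e-10` of the largest treated as zero), which never fails on
#' rank-deficient regions such as perfectly flat or perfectly diagonal
#' patches. Inputs are pre-scaled by a power of two so the result is
#' bit-identical under global rescaling of the region by powers of two and
#' stable under any positive rescaling.
#'
#' @param samples a `region_samples` object (or a list with `y` and `X`).
#' @param source optional identifier of the originating image, kept as
#'   provenance.
#' @return an object of class `weight_vector`: list with `b` (4 weights),
#'   `residual_norm`, `rank`, `source`.
#' @export
estimate_weights <- function(samples, source = NULL) {
  y <- samples$y; X <- samples$X
  if (!all(is.finite(y)) || !all(is.finite(X)))
    stop_mcnedi("samples contain non-finite values")
  if (ncol(X) != 4L || length(y) != nrow(X))
    stop_mcnedi("samples must pair a length-n y with an n x 4 X")
  m <- max(abs(X), abs(y))
  if (m > 0) {
    s <- 2^ceiling(log2(m))    # exact power-of-two scaling
    X <- X / s; y <- y / s
  }
  sv <- svd(X)
  tol <- 1e-10 * sv$d[1]
  keep <- sv$d > tol
  rank <- sum(keep)
  b <- if (rank == 0L) numeric(4L)
       else sv$v[, keep, drop = FALSE] %*%
            ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
  b <- as.numeric(b)
  structure(list(b = b, residual_norm = sqrt(sum((y - X %*% b)^2)) *
                   (if (m > 0) s else 1),
                 rank = rank, source = source),
            class = "weight_vector")
}

#' Sum of the 4 regression weights
#'
#' The quantity whose concentration near 1 underpins cross-contrast weight
#' sharing: in regions whose neighbor columns have nearly equal sums, the
#' least-squares weights sum to approximately 1.
#'
#' @param w a `weight_vector` (or a numeric vector of 4 weights).
#' @return scalar \eqn{\sum_{j=1}^4 b_j}.
#' @export
sum_of_weights <- function(w) {
  b <- if (inherits(w, "weight_vector")) w$b else as.numeric(w)
  sum(b)
}

#' Edge-pixel mask from local neighbor variance
#'
#' Flags a pixel as an edge pixel iff the population variance of its 4
#' lattice neighbors exceeds `threshold` (default `1e-4`, calibrated for
#' intensities normalized to `[0, 1]`). Only edge pixels receive regression
#' weights during super-resolution; the rest use the smooth fallback.
#'
#' @param image normalized numeric matrix.
#' @param lattice `"diagonal"` or `"axial"`.
#' @param spacing positive integer neighbor distance.
#' @param threshold variance threshold (default `1e-4`).
#' @return an object of class `edge_mask`: list with `mask` (logical matrix),
#'   `threshold`, `lattice`, `spacing`.
#' @export
edge_mask <- function(image, lattice = c("diagonal", "axial"), spacing = 1L,
                      threshold = 1e-4) {
  assert_normalized(image)
  lattice <- match.arg(lattice)
  spacing <- as.integer(spacing)
  if (spacing < 1L) stop_mcnedi("spacing must be >= 1")
  off <- lattice_offsets(lattice, spacing)
  h <- nrow(image); w <- ncol(image)
  p <- pad_replicate(image, spacing)
  nb <- lapply(1:4, function(j)
    p[(1L + spacing + off[j, 1]):(h + spacing + off[j, 1]),
      (1L + spacing + off[j, 2]):(w + spacing + off[j, 2]), drop = FALSE])
  mu <- (nb[[1]] + nb[[2]] + nb[[3]] + nb[[4]]) / 4
  v <- ((nb[[1]] - mu)^2 + (nb[[2]] - mu)^2 +
        (nb[[3]] - mu)^2 + (nb[[4]] - mu)^2) / 4
  structure(list(mask = v > threshold, threshold = threshold,
                 lattice = lattice, spacing = spacing),
            class = "edge_mask")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector> b = [", paste(sprintf("%.4f", x$b), collapse = ", "),
      "]  sum =", sprintf("%.4f", sum(x$b)),
      " rank =", x$rank,
      " residual =", sprintf("%.3e", x$residual_norm), "\n")
  invisible(x)
}

#' @export
print.region_samples <- function(x, ...) {
  cat("<region_samples>", length(x$y), "patches,", x$lattice,
      "lattice, spacing", x$spacing, ", region", x$region,
      ", center (", x$center[1], ",", x$center[2], ")\n")
  invisible(x)
}
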