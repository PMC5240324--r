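#' @title Weight-invariance diagnostics
#' @description
#' Numerical checks of the two properties that justify borrowing regression
#' weights across image contrasts:
#' \enumerate{
#'   \item the 4 weights of a local region sum to approximately 1, because
#'     the 4 neighbor columns and the center column of the patch system share
#'     almost all their pixels, so their sums nearly coincide;
#'   \item weights estimated from two co-registered images of different
#'     contrast are close, with the computable bound
#'     \deqn{\|\tilde b - b\|_2 \le \|\tilde X^{+}(y - Xb)\|_2 +
#'           \|\tilde X^{+}(d - Cb)\|_2,}
#'     where \eqn{d = \tilde y - y} and \eqn{C = \tilde X - X}.
#' }
#' @name theory-diagnostics
NULL

pinv_svd <- function(X, rtol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > rtol * sv$d[1]
  if (!any(keep)) return(matrix(0, ncol(X), nrow(X)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Column-sum balance of a region's patch system
#'
#' The premise behind "sum of weights is about 1": within one region the four
#' neighbor columns of `X` and the center vector `y` consist largely of the
#' same repeated pixels, so their sums are nearly equal. Reports the five
#' sums and the maximum relative discrepancy between any neighbor-column sum
#' and the center sum.
#'
#' @param samples a `region_samples` object.
#' @return list with `column_sums` (4 values), `y_sum`,
#'   `max_rel_discrepancy`.
#' @export
neighbor_sum_balance <- function(samples) {
  cs <- colSums(samples$X)
  ys <- sum(samples$y)
  list(column_sums = cs, y_sum = ys,
       max_rel_discrepancy = max(abs(cs - ys)) / max(abs(ys), 1e-12))
}

fraction_report <- function(values, bin_edges, range_lo, range_hi) {
  n <- length(values)
  fr <- if (n == 0L) rep(0, length(bin_edges) - 1L)
        else tabulate(findInterval(values, bin_edges, rightmost.closed = TRUE,
                                   all.inside = TRUE),
                      nbins = length(bin_edges) - 1L) / n
  structure(list(bin_edges = bin_edges, fractions = fr, n_regions = n,
                 values = values,
                 frac_in_range = if (n == 0L) NA_real_
                                 else mean(values >= range_lo & values <= range_hi),
                 range = c(range_lo, range_hi)),
            class = "fraction_report")
}

# Edge-region centers on a stride grid (1-based), interior-margin aware only
# through replicate padding, so all pixels are eligible.
survey_centers <- function(image, stride, lattice, threshold) {
  em <- edge_mask(image, lattice = lattice, spacing = 1L,
                  threshold = threshold)$mask
  rows <- seq(1L, nrow(image), by = stride)
  cols <- seq(1L, ncol(image), by = stride)
  sub <- em[rows, cols, drop = FALSE]
  which(sub, arr.ind = TRUE) |>
    (\(ix) cbind(rows[ix[, 1L]], cols[ix[, 2L]]))()
}

#' Survey the sum of weights over edge regions of an image
#'
#' Estimates the 4 diagonal-lattice weights for every edge-flagged region
#' center on a stride grid and histograms \eqn{\sum_j b_j}. The headline
#' number is the fraction of regions whose sum lies in `[0.95, 1.05]`.
#'
#' @param image normalized image.
#' @param stride survey stride in pixels (default 1 for images up to
#'   128x128, 4 above).
#' @param region odd region size (default 9).
#' @param threshold edge variance threshold (default `1e-4`).
#' @param bin_edges histogram bin edges for the report.
#' @return a `fraction_report`: `bin_edges`, `fractions` (sum to 1),
#'   `n_regions`, `values`, `frac_in_range`.
#' @export
sum_of_weights_survey <- function(image, stride = NULL, region = 9L,
                                  threshold = 1e-4,
                                  bin_edges = c(-Inf, seq(0.5, 1.5, by = 0.05), Inf)) {
  assert_normalized(image)
  if (is.null(stride)) stride <- if (prod(dim(image)) <= 128^2) 1L else 4L
  centers <- survey_centers(image, stride, "diagonal", threshold)
  if (nrow(centers) == 0L) {
    warning("no edge regions found; empty survey")
    return(fraction_report(numeric(0), bin_edges, 0.95, 1.05))
  }
  sums <- vapply(seq_len(nrow(centers)), function(k) {
    sum(estimate_weights(extract_region_samples(
      image, centers[k, ], lattice = "diagonal", spacing = 1L,
      region = region))$b)
  }, numeric(1))
  fraction_report(sums, bin_edges, 0.95, 1.05)
}

#' Decompose the cross-contrast weight-error bound for one region pair
#'
#' Given the patch systems of the *same* region sampled from two contrasts,
#' computes the left side \eqn{\|\tilde b - b\|_2} and the two right-side
#' terms of the bound (see the package vignette), using the minimal-norm
#' pseudoinverse of \eqn{\tilde X}.
#'
#' @param samples_a `region_samples` from the first image (gives \eqn{b}).
#' @param samples_b `region_samples` from the second image (gives
#'   \eqn{\tilde b}); must share center, lattice and spacing with
#'   `samples_a`.
#' @return list of class `bound_decomposition` with `lhs`, `term_residual`,
#'   `term_perturb`, `bound_holds`.
#' @export
bound_decomposition <- function(samples_a, samples_b) {
  if (!identical(samples_a$center, samples_b$center) ||
      !identical(samples_a$lattice, samples_b$lattice) ||
      !identical(samples_a$spacing, samples_b$spacing))
    stop_mcnedi("samples_a and samples_b must share region geometry")
  b <- estimate_weights(samples_a)$b
  bt <- estimate_weights(samples_b)$b
  Xp <- pinv_svd(samples_b$X)
  d <- samples_b$y - samples_a$y
  C <- samples_b$X - samples_a$X
  term_residual <- sqrt(sum((Xp %*% (samples_a$y - samples_a$X %*% b))^2))
  term_perturb <- sqrt(sum((Xp %*% (d - C %*% b))^2))
  lhs <- sqrt(sum((bt - b)^2))
  scale <- max(1, abs(term_residual), abs(term_perturb))
  structure(list(lhs = lhs, term_residual = term_residual,
                 term_perturb = term_perturb,
                 bound_holds = lhs <= term_residual + term_perturb +
                   1e-9 * scale),
            class = "bound_decomposition")
}

#' Survey cross-contrast weight similarity over edge regions
#'
#' For every edge-flagged region center of `image_a` on a stride grid,
#' estimates diagonal-lattice weights independently from both images and
#' histograms \eqn{\|\tilde b - b\|_2}. The headline number is the fraction
#' of regions with error in `[0, 0.25]`.
#'
#' @param image_a,image_b co-registered normalized images of the same scene
#'   in two contrasts (same shape).
#' @inheritParams sum_of_weights_survey
#' @return a `fraction_report` (range `[0, 0.25]`).
#' @export
weight_similarity_survey <- function(image_a, image_b, stride = NULL,
                                     region = 9L, threshold = 1e-4,
                                     bin_edges = c(seq(0, 1, by = 0.05), Inf)) {
  assert_normalized(image_a, "image_a")
  assert_normalized(image_b, "image_b")
  if (!identical(dim(image_a), dim(image_b)))
    stop_mcnedi("image_a and image_b must have the same shape")
  if (is.null(stride)) stride <- if (prod(dim(image_a)) <= 128^2) 1L else 4L
  centers <- survey_centers(image_a, stride, "diagonal", threshold)
  if (nrow(centers) == 0L) {
    warning("no edge regions found; empty survey")
    return(fraction_report(numeric(0), bin_edges, 0, 0.25))
  }
  errs <- vapply(seq_len(nrow(centers)), function(k) {
    ba <- estimate_weights(extract_region_samples(
      image_a, centers[k, ], lattice = "diagonal", spacing = 1L,
      region = region))$b
    bb <- estimate_weights(extract_region_samples(
      image_b, centers[k, ], lattice = "diagonal", spacing = 1L,
      region = region))$b
    sqrt(sum((bb - ba)^2))
  }, numeric(1))
  fraction_report(errs, bin_edges, 0, 0.25)
}

#' @export
print.fraction_report <- function(x, ...) {
  cat("<fraction_report>", x$n_regions, "regions;",
      if (is.na(x$frac_in_range)) "empty"
      else sprintf("%.1f%% in [%g, %g]", 100 * x$frac_in_range,
                   x$range[1], x$range[2]), "\n")
  invisible(x)
}
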