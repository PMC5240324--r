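# Shared fixtures, built in code at test time.

# Two-level image constant along the main diagonal: f(r, c) = g(r - c) for a
# step function g. The closed-form diagonal-lattice weights are [.5, 0, 0, .5].
diag_step_image <- function(size = 32L, lo = 0, hi = 0.78, at = 0L) {
  r <- matrix(seq_len(size), size, size)
  ifelse(r - t(r) >= at, lo, hi)
}

# Smooth low-gradient patch for neighbor-balance tests.
smooth_patch <- function(size = 15L, scale = 0.02) {
  r <- matrix(seq_len(size), size, size)
  0.5 + scale * sin(r / 6) * cos(t(r) / 7)
}

# Random full-rank regression system shaped like a region sample set.
random_system <- function(n = 49L, rank_deficient = FALSE) {
  X <- matrix(stats::runif(n * 4L), n, 4L)
  if (rank_deficient) X[, 4L] <- X[, 1L]           # exact column repeat
  y <- X %*% stats::runif(4L, -1, 1) + stats::rnorm(n, 0, 0.05)
  list(y = as.numeric(y), X = X)
}

# Independent minimal-norm LS oracle via reduced SVD (kept separate from the
# implementation path on purpose).
svd_minnorm_oracle <- function(y, X, rtol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > rtol * sv$d[1]
  as.numeric(sv$v[, keep, drop = FALSE] %*%
               ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep]))
}

run_python <- function(code, input = NULL) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  on.exit(unlink(f))
  system2("python", f, stdout = TRUE, stderr = FALSE, input = input)
}
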