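# Internal helpers shared across modules.

# Clamp integer indices into [1, n] (replicate-border semantics).
clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Replicate-pad a matrix by k pixels on every side.
pad_replicate <- function(img, k) {
  stopifnot(is.matrix(img), k >= 0)
  if (k == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  img[c(rep(1L, k), seq_len(h), rep(h, k)),
      c(rep(1L, k), seq_len(w), rep(w, k)), drop = FALSE]
}

# 2D convolution with an odd-sized kernel and replicate border, same-size
# output.  Direct sum of shifted copies: kernels here are small (3x3, 11x11).
conv2_replicate <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  rh <- (kh - 1L) %/% 2L; rw <- (kw - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  p <- pad_replicate(img, max(rh, rw))
  off <- max(rh, rw)
  out <- matrix(0, h, w)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      kv <- kernel[a, b]
      if (kv == 0) next
      out <- out + kv * p[(off + 1L - rh + (a - 1L)):(off + h - rh + (a - 1L)),
                          (off + 1L - rw + (b - 1L)):(off + w - rw + (b - 1L))]
    }
  }
  out
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# FNV-1a 32-bit hash of a character scalar; provenance stamp for experiment
# configs (no cryptographic intent).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256                       # xor touches only the low byte
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_mcnedi <- function(...) stop(..., call. = FALSE)

assert_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_mcnedi(arg, " must be a numeric matrix")
  if (!all(is.finite(img)))
    stop_mcnedi(arg, " contains non-finite values")
  invisible(img)
}

assert_normalized <- function(img, arg = "image", tol = 1e-8) {
  assert_image(img, arg)
  if (min(img) < -tol || max(img) > 1 + tol)
    stop_mcnedi(arg, " must be normalized to [0, 1] (see normalize_unit())")
  invisible(img)
}
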