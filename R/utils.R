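#' @useDynLib bmradiomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rlnorm sd var cor pt quantile predict coef
#'   dist fft nextn setNames
#' @importFrom utils read.csv write.csv head
NULL

#' Derive a reproducible integer sub-seed from a root seed and a stream name
#'
#' All stochastic stages (cohort, folds, permutations, classifiers) draw their
#' seeds from one root seed through named substreams, so that a single integer
#' reproduces an entire run while stages stay independently re-runnable.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @param index optional integer (e.g. lesion or permutation counter).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  h <- (h * 31 + as.double(index)) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Reflect (mirror, edge included) an out-of-range 1-based index into [1, n].
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- (i - 1L) %% (2L * n)
  m <- ifelse(m < 0L, m + 2L * n, m)
  as.integer(ifelse(m < n, m + 1L, 2L * n - m))
}

# n x n convolution matrix applying a 1D Gaussian of standard deviation
# `sigma` (in samples) with reflect boundary handling.
gaussian_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3.5 * sigma))
  w <- exp(-0.5 * ((-r:r) / sigma)^2)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (t in seq_along(w)) {
    off <- t - r - 1L
    j <- reflect_index(seq_len(n) + off, n)
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + w[t]
  }
  K
}

# Separable Gaussian smoothing of a 3D array, sigma per axis in voxels.
smooth_gaussian3d <- function(x, sigma_vox) {
  d <- dim(x)
  stopifnot(length(d) == 3L, length(sigma_vox) == 3L)
  Ks <- lapply(1:3, function(a) gaussian_conv_matrix(d[a], sigma_vox[a]))
  # axis 1
  y <- Ks[[1]] %*% matrix(x, d[1], d[2] * d[3])
  y <- array(y, d)
  # axis 2
  y <- aperm(y, c(2, 1, 3))
  y <- Ks[[2]] %*% matrix(y, d[2], d[1] * d[3])
  y <- aperm(array(y, d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  y <- aperm(y, c(3, 1, 2))
  y <- Ks[[3]] %*% matrix(y, d[3], d[1] * d[2])
  aperm(array(y, d[c(3, 1, 2)]), c(2, 3, 1))
}

# Per-voxel standard deviation of smooth_gaussian3d applied to unit white
# noise: outer product of the row-wise L2 norms of the three conv matrices.
smooth_gaussian3d_sdmap <- function(dims, sigma_vox) {
  rs <- lapply(1:3, function(a)
    sqrt(rowSums(gaussian_conv_matrix(dims[a], sigma_vox[a])^2)))
  array(outer(outer(rs[[1]], rs[[2]]), rs[[3]]), dims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
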