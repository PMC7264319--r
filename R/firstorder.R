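#' Quantize the in-mask intensities of a lesion volume
#'
#' Equal-width binning between the in-mask minimum and maximum into
#' `n_levels` gray levels `0 .. n_levels-1`; the maximum maps to the top
#' level and a constant region maps entirely to level 0. Voxels outside the
#' mask are `NA`.
#'
#' @param volume a [lesion_volume()], or a 3D array with `mask` supplied.
#' @param n_levels number of gray levels (>= 2).
#' @param mask optional 0/1 array when `volume` is a plain array.
#' @return a `quantized_roi` list: `levels` (integer array, `NA` outside the
#'   mask), `n_levels`, `mask`.
#' @export
quantize <- function(volume, n_levels = 32L, mask = NULL) {
  if (inherits(volume, "lesion_volume")) {
    x <- volume$intensities; mask <- volume$mask
  } else x <- volume
  if (is.null(mask)) stop("mask required")
  if (n_levels < 2L) stop("n_levels must be >= 2")
  inside <- mask == 1L
  if (!any(inside)) stop("mask is empty")
  v <- x[inside]
  rng <- range(v)
  lv <- array(NA_integer_, dim = dim(x))
  if (rng[2] == rng[1]) {
    lv[inside] <- 0L
  } else {
    q <- floor((v - rng[1]) / (rng[2] - rng[1]) * n_levels)
    lv[inside] <- as.integer(pmin(q, n_levels - 1L))
  }
  structure(list(levels = lv, n_levels = as.integer(n_levels),
                 mask = array(as.integer(inside), dim = dim(x))),
            class = "quantized_roi")
}

#' First-order (histogram) features of the in-mask intensities
#'
#' Mean, population variance, moment-based skewness and excess kurtosis
#' (both defined as 0 when the variance is 0), and histogram energy
#' `sum(p^2)` and entropy `-sum(p log2 p)` over an `n_bins` equal-width
#' in-mask histogram.
#'
#' @param volume a [lesion_volume()] or numeric vector of in-mask values.
#' @param n_bins histogram bin count for energy/entropy.
#' @return named numeric vector of length 6:
#'   `mean, variance, skewness, kurtosis, energy, entropy`.
#' @export
first_order_features <- function(volume, n_bins = 64L) {
  v <- if (inherits(volume, "lesion_volume"))
    volume$intensities[volume$mask == 1L] else as.numeric(volume)
  n <- length(v)
  if (n < 2L) stop("need at least 2 in-mask voxels")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2 - 3
  } else skew <- kurt <- 0
  rng <- range(v)
  if (rng[2] == rng[1]) {
    p <- 1
  } else {
    b <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins), n_bins - 1L)
    p <- tabulate(b + 1L, nbins = n_bins) / n
    p <- p[p > 0]
  }
  c(mean = m, variance = m2, skewness = skew, kurtosis = kurt,
    energy = sum(p^2), entropy = -sum(p * log2(p)))
}
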