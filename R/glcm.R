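#' The 13 unique 3D displacement directions at distance 1
#'
#' One representative per opposite-direction pair; together with
#' symmetrization this covers all 26 neighbors.
#'
#' @return a 13 x 3 integer matrix.
#' @export
glcm_offsets <- function() {
  m <- rbind(c(1,0,0), c(0,1,0), c(0,0,1),
             c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1),
             c(0,1,1), c(0,1,-1),
             c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))
  storage.mode(m) <- "integer"
  m
}

#' Gray-level co-occurrence matrix of a quantized ROI
#'
#' Counts ordered level pairs `(a, b)` for voxel pairs separated by each
#' offset, skipping pairs with either voxel outside the mask, accumulated
#' over all offsets. With `symmetric = TRUE` (default) both orderings are
#' counted, so the matrix equals its transpose and the total equals twice
#' the number of valid in-mask pairs.
#'
#' @param roi a [quantize()]d ROI.
#' @param offsets integer matrix of displacement vectors (rows).
#' @param symmetric count both orderings.
#' @return a `glcm` list: `counts` (n_levels x n_levels), `offsets`,
#'   `symmetric`.
#' @export
compute_glcm <- function(roi, offsets = glcm_offsets(), symmetric = TRUE) {
  stopifnot(inherits(roi, "quantized_roi"))
  storage.mode(offsets) <- "integer"
  counts <- glcm_accumulate(as.integer(roi$levels), as.integer(dim(roi$levels)),
                            offsets, roi$n_levels, symmetric)
  if (sum(counts) == 0L)
    stop("no valid in-mask voxel pairs for any offset")
  structure(list(counts = counts, offsets = offsets, symmetric = symmetric),
            class = "glcm")
}

#' The 14 Haralick texture statistics of a co-occurrence matrix
#'
#' Computed on the normalized matrix `p = counts / sum(counts)` with
#' logarithms base 2 and `0 log 0 = 0`. Correlation is defined as 0 when a
#' marginal standard deviation vanishes; the maximal correlation coefficient
#' (MCC) is the square root of the second-largest eigenvalue of the Q matrix
#' and is defined as 0 for degenerate (single-level) matrices.
#'
#' @param glcm a [compute_glcm()] result (or a plain matrix of counts or
#'   probabilities).
#' @return named numeric vector of length 14.
#' @export
haralick_features <- function(glcm) {
  cm <- if (inherits(glcm, "glcm")) glcm$counts else glcm
  tot <- sum(cm)
  if (tot <= 0) stop("GLCM total must be positive")
  p <- cm / tot
  n <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(n) * px); muy <- sum(seq_len(n) * py)
  sx <- sqrt(sum((seq_len(n) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(n) - muy)^2 * py))
  plog <- function(x) ifelse(x > 0, log2(x), 0)

  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sx > 0 && sy > 0)
    (sum(i * j * p) - mux * muy) / (sx * sy) else 0
  variance <- sum((i - mux)^2 * p)      # sum of squares variance
  idm <- sum(p / (1 + (i - j)^2))
  # p_{x+y}(k), k = 2..2n ; p_{|x-y|}(k), k = 0..n-1
  psum <- vapply(2:(2 * n), function(k) sum(p[(i + j) == k]), numeric(1))
  pdif <- vapply(0:(n - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * n); kd <- 0:(n - 1)
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(psum * plog(psum))
  entropy <- -sum(p * plog(p))
  mu_d <- sum(kd * pdif)
  difference_variance <- sum((kd - mu_d)^2 * pdif)
  difference_entropy <- -sum(pdif * plog(pdif))
  hx <- -sum(px * plog(px)); hy <- -sum(py * plog(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * plog(pxy))
  hxy2 <- -sum(pxy * plog(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  # maximal correlation coefficient
  act <- which(px > 0)
  mcc <- 0
  if (length(act) >= 2) {
    ps <- p[act, act, drop = FALSE]
    # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
    q <- sweep(ps %*% t(sweep(ps, 2, py[act], "/")), 1, px[act], "/")
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(pmax(min(ev[2], 1), 0))
  }
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2,
    mcc = mcc)
}
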