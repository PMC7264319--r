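#' Build the 38-filter root filter set (RFS) bank
#'
#' The canonical RFS construction: 36 oriented anisotropic
#' derivative-of-Gaussian kernels — first derivative ("edge") and second
#' derivative ("bar") across the short axis, at 3 scales
#' `(sigma_short, sigma_long) = base * {(1,3), (2,6), (4,12)}` (voxels) and 6
#' orientations in 30 degree steps — plus one isotropic Gaussian and one
#' Laplacian-of-Gaussian (both `sigma = 10 * base`). Derivative and LoG
#' kernels are made exactly zero-sum and L1-normalized; the Gaussian sums
#' to 1. Kernel support is `49 x 49` at the largest scale and `2*ceil(2.5
#' sigma_long)+1` at smaller scales.
#'
#' @param base_sigma scale multiplier applied to every sigma (voxels).
#' @return a `filter_bank` list with `kernels` (named list of matrices),
#'   `names`, and an internal FFT cache.
#' @export
build_rfs_bank <- function(base_sigma = 1) {
  stopifnot(base_sigma > 0)
  make_kernel <- function(r, fun) {
    g <- expand.grid(x = -r:r, y = -r:r)
    matrix(fun(g$x, g$y), 2 * r + 1, 2 * r + 1)
  }
  norm_deriv <- function(k) { k <- k - mean(k); k / sum(abs(k)) }
  scales <- lapply(c(1, 2, 4), function(s) base_sigma * c(s, 3 * s))
  thetas <- (0:5) * pi / 6
  kernels <- list()
  s10 <- 10 * base_sigma
  r10 <- min(24L, ceiling(2.5 * s10))
  kg <- make_kernel(r10, function(x, y) exp(-(x^2 + y^2) / (2 * s10^2)))
  kernels[["gauss"]] <- kg / sum(kg)
  kernels[["log"]] <- norm_deriv(make_kernel(r10, function(x, y) {
    r2 <- x^2 + y^2
    (r2 - 2 * s10^2) / s10^4 * exp(-r2 / (2 * s10^2))
  }))
  for (kind in c("edge", "bar")) {
    for (si in seq_along(scales)) {
      ss <- scales[[si]][1]; sl <- scales[[si]][2]
      r <- min(24L, ceiling(2.5 * sl))
      for (oi in seq_along(thetas)) {
        th <- thetas[oi]
        k <- make_kernel(r, function(x, y) {
          u <- x * cos(th) + y * sin(th)    # short (derivative) axis
          v <- -x * sin(th) + y * cos(th)   # long (smoothing) axis
          g <- exp(-u^2 / (2 * ss^2) - v^2 / (2 * sl^2))
          if (kind == "edge") -u / ss^2 * g
          else (u^2 / ss^4 - 1 / ss^2) * g
        })
        kernels[[sprintf("%s.s%d.o%d", kind, si, oi)]] <- norm_deriv(k)
      }
    }
  }
  stopifnot(length(kernels) == 38L)
  structure(list(kernels = kernels, names = names(kernels),
                 base_sigma = base_sigma, cache = new.env(parent = emptyenv())),
            class = "filter_bank")
}

# Reflect-pad a 2D matrix to target size: `pad` on the low side of each
# axis, remainder on the high side; reflection tiles for small inputs.
reflect_pad2d <- function(m, pad, nx_out, ny_out) {
  ix <- reflect_index(seq_len(nx_out) - pad, nrow(m))
  iy <- reflect_index(seq_len(ny_out) - pad, ncol(m))
  m[ix, iy, drop = FALSE]
}

# Embed a (2r+1)^2 kernel into an Nx x Ny grid wrapped at the origin and
# return its FFT (cross-correlation convention uses the conjugate).
kernel_fft <- function(k, nx, ny) {
  r <- (nrow(k) - 1L) %/% 2L
  kp <- matrix(0, nx, ny)
  sx <- ((-r:r) %% nx) + 1L
  sy <- ((-r:r) %% ny) + 1L
  kp[sx, sy] <- k
  Conj(fft(kp))
}

#' Apply the RFS filter bank slice-wise to a lesion volume
#'
#' Each 2D kernel is cross-correlated with every axial slice (third array
#' axis) under reflect padding, via FFT. Response volumes have the input's
#' shape and follow the bank's registry order.
#'
#' @param volume a [lesion_volume()] (or 3D array).
#' @param bank a [build_rfs_bank()] bank.
#' @return named list of 38 response arrays.
#' @export
apply_filter_bank <- function(volume, bank) {
  stopifnot(inherits(bank, "filter_bank"))
  x <- if (inherits(volume, "lesion_volume")) volume$intensities else volume
  d <- dim(x)
  if (length(d) != 3L || any(d < 1L)) stop("expected a non-empty 3D volume")
  pad <- max(vapply(bank$kernels, function(k) (nrow(k) - 1L) %/% 2L, 0L))
  nx <- nextn(d[1] + 2L * pad, c(2, 3, 5))
  ny <- nextn(d[2] + 2L * pad, c(2, 3, 5))
  key <- sprintf("%d_%d", nx, ny)
  if (is.null(bank$cache[[key]])) {
    bank$cache[[key]] <- lapply(bank$kernels, kernel_fft, nx = nx, ny = ny)
  }
  kffts <- bank$cache[[key]]
  out <- lapply(bank$names, function(nm) array(0, dim = d))
  names(out) <- bank$names
  sel_x <- pad + seq_len(d[1]); sel_y <- pad + seq_len(d[2])
  for (z in seq_len(d[3])) {
    fp <- fft(reflect_pad2d(x[, , z], pad, nx, ny))
    for (nm in bank$names) {
      cc <- Re(fft(fp * kffts[[nm]], inverse = TRUE)) / (nx * ny)
      out[[nm]][, , z] <- cc[sel_x, sel_y]
    }
  }
  out
}
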