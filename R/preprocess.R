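#' Construct a lesion volume (intensities + mask + spacing)
#'
#' @param intensities 3D numeric array.
#' @param mask 3D array of 0/1, same shape.
#' @param spacing_mm voxel spacing, 3-vector (mm).
#' @param lesion_id optional identifier used in error messages.
#' @return a `lesion_volume` object.
#' @export
lesion_volume <- function(intensities, mask, spacing_mm = c(1, 1, 1),
                          lesion_id = NA_character_) {
  if (!identical(dim(intensities), dim(mask)))
    stop("intensities and mask must have identical shapes")
  if (length(dim(intensities)) != 3L) stop("expected a 3D array")
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  mask <- array(as.integer(mask != 0), dim = dim(mask))
  if (sum(mask) == 0L) stop("mask is empty")
  structure(list(intensities = intensities, mask = mask,
                 spacing_mm = spacing_mm, lesion_id = lesion_id),
            class = "lesion_volume")
}

#' Multiplicative bias correction by low-pass division
#'
#' Estimates the slowly varying intensity nonuniformity as a heavy Gaussian
#' low-pass of the (positivity-shifted) volume and divides it out, then
#' rescales so the masked mean of the input is preserved. This removes smooth
#' multiplicative shading; it is not a histogram-sharpening nonuniformity
#' solver.
#'
#' @param volume a [lesion_volume()].
#' @param smoothing_fwhm_mm full width at half maximum of the low-pass (mm).
#' @return a corrected `lesion_volume`.
#' @export
correct_bias <- function(volume, smoothing_fwhm_mm = 60) {
  stopifnot(inherits(volume, "lesion_volume"))
  x <- volume$intensities
  if (all(x == 0)) stop("all-zero volume: nothing to correct")
  offset <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + offset
  sigma_vox <- (smoothing_fwhm_mm / 2.35482) / volume$spacing_mm
  est <- smooth_gaussian3d(xs, sigma_vox)
  est <- pmax(est, 1e-8)
  out <- xs / est
  inside <- volume$mask == 1L
  out <- out * (mean(x[inside]) / mean(out[inside]))
  volume$intensities <- out
  volume
}

#' Crop a lesion volume to the mask bounding box plus a margin
#'
#' @param volume a [lesion_volume()].
#' @param margin_voxels nonnegative margin added on every side (clipped to
#'   the volume bounds).
#' @return the cropped `lesion_volume`; the mask voxel count is unchanged.
#' @export
crop_to_roi <- function(volume, margin_voxels = 2L) {
  stopifnot(inherits(volume, "lesion_volume"), margin_voxels >= 0)
  d <- dim(volume$mask)
  idx <- which(volume$mask == 1L, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin_voxels, 1L)
  hi <- pmin(apply(idx, 2, max) + margin_voxels, d)
  volume$intensities <- volume$intensities[lo[1]:hi[1], lo[2]:hi[2],
                                           lo[3]:hi[3], drop = FALSE]
  volume$mask <- volume$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                             drop = FALSE]
  volume
}

#' Normalize a lesion volume to zero mean, unit variance
#'
#' Statistics are computed over the whole (cropped) volume by default,
#' matching whole-image normalization; set `region = "mask"` to normalize on
#' mask statistics instead.
#'
#' @param volume a [lesion_volume()].
#' @param region `"volume"` (default) or `"mask"`.
#' @return the normalized `lesion_volume`.
#' @export
normalize_zscore <- function(volume, region = c("volume", "mask")) {
  stopifnot(inherits(volume, "lesion_volume"))
  region <- match.arg(region)
  vals <- if (region == "mask") volume$intensities[volume$mask == 1L]
          else as.vector(volume$intensities)
  s <- sd(vals)
  if (!is.finite(s) || s == 0)
    stop("zero intensity variance; cannot normalize lesion ",
         volume$lesion_id)
  volume$intensities <- (volume$intensities - mean(vals)) / s
  volume
}

#' Preprocess one lesion: bias correction, crop, z-score normalization
#'
#' The stage order is fixed: multiplicative bias correction on the full
#' volume, cropping to the mask bounding box plus margin, then z-score
#' normalization with statistics from the cropped volume.
#'
#' @param volume a [lesion_volume()].
#' @param bias_fwhm_mm low-pass FWHM for bias correction (mm).
#' @param margin_voxels crop margin.
#' @param bias logical; disable to skip bias correction.
#' @return a preprocessed `lesion_volume`.
#' @export
preprocess_lesion <- function(volume, bias_fwhm_mm = 60, margin_voxels = 2L,
                              bias = TRUE) {
  if (bias) volume <- correct_bias(volume, bias_fwhm_mm)
  volume <- crop_to_roi(volume, margin_voxels)
  normalize_zscore(volume)
}
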