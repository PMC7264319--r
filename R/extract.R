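#' Default extraction parameters
#'
#' @param n_levels gray levels for GLCM/GLRLM quantization.
#' @param n_bins histogram bins for first-order energy/entropy.
#' @param base_sigma RFS bank scale multiplier (voxels).
#' @param bank optionally a prebuilt [build_rfs_bank()] (rebuilt otherwise).
#' @return an `extract_params` list.
#' @export
extract_params <- function(n_levels = 32L, n_bins = 64L, base_sigma = 1,
                           bank = NULL) {
  structure(list(n_levels = as.integer(n_levels), n_bins = as.integer(n_bins),
                 base_sigma = base_sigma,
                 bank = bank %||% build_rfs_bank(base_sigma)),
            class = "extract_params")
}

first_order_names <- function()
  c("mean", "variance", "skewness", "kurtosis", "energy", "entropy")
haralick_names <- function()
  c("asm", "contrast", "correlation", "variance", "idm", "sum_average",
    "sum_variance", "sum_entropy", "entropy", "difference_variance",
    "difference_entropy", "imc1", "imc2", "mcc")
glrlm_feature_names <- function()
  c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre", "srlge", "srhge",
    "lrlge", "lrhge")

#' The ordered 1209-entry feature-name registry
#'
#' 6 first-order + 25 second-order (14 Haralick GLCM + 11 GLRLM) on the raw
#' ROI, then the same 31 for each of the 38 filter-response maps, prefixed
#' `rfs.<kernel>.`.
#'
#' @param bank a [build_rfs_bank()] bank (for kernel names).
#' @return character vector of length 1209, unique and stable across runs.
#' @export
feature_registry <- function(bank = build_rfs_bank()) {
  base31 <- c(paste0("fo.", first_order_names()),
              paste0("glcm.", haralick_names()),
              paste0("glrlm.", glrlm_feature_names()))
  c(base31, unlist(lapply(bank$names, function(nm) paste0("rfs.", nm, ".", base31))))
}

# 6 + 25 block for one set of in-mask values (already masked ROI).
block31 <- function(vals, mask_arr, vol_arr, params) {
  fo <- first_order_features(vals, n_bins = params$n_bins)
  q <- quantize(vol_arr, n_levels = params$n_levels, mask = mask_arr)
  gl <- haralick_features(compute_glcm(q))
  rl <- glrlm_features(compute_glrlm(q))
  c(fo, gl, rl)
}

#' Extract the full ordered 1209-feature radiomic vector for one lesion
#'
#' First-order and texture features on the (preprocessed) ROI, then on each
#' of the 38 RFS response maps; response maps are standardized within the
#' mask before re-quantization (equal-width quantization on the in-mask
#' range is affine-invariant, so this amounts to quantizing each map on its
#' own in-mask range).
#'
#' @param volume a preprocessed [lesion_volume()] with >= 8 mask voxels.
#' @param params an [extract_params()] list.
#' @return named numeric vector of length 1209, all finite.
#' @export
extract_all <- function(volume, params = extract_params()) {
  stopifnot(inherits(volume, "lesion_volume"))
  if (sum(volume$mask) < 8L)
    stop("mask too small (< 8 voxels) for lesion ", volume$lesion_id)
  inside <- volume$mask == 1L
  vals <- volume$intensities[inside]
  out <- tryCatch(
    block31(vals, volume$mask, volume$intensities, params),
    error = function(e) stop("feature extraction failed for lesion ",
                             volume$lesion_id, ": ", conditionMessage(e)))
  responses <- apply_filter_bank(volume, params$bank)
  for (nm in params$bank$names) {
    r <- responses[[nm]]
    out <- c(out, block31(r[inside], volume$mask, r, params))
  }
  names(out) <- feature_registry(params$bank)
  if (!all(is.finite(out)))
    stop("non-finite feature values for lesion ", volume$lesion_id, ": ",
         paste(head(names(out)[!is.finite(out)], 5), collapse = ", "))
  out
}

#' Preprocess and extract features for a whole cohort
#'
#' Accepts either an in-memory cohort from [generate_cohort()] or a manifest
#' data frame with NIfTI paths. Each lesion is preprocessed (bias
#' correction, crop, z-score) and passed to [extract_all()].
#'
#' @param cohort a [generate_cohort()] result, or a manifest data.frame.
#' @param params an [extract_params()] list.
#' @param bias_fwhm_mm,margin_voxels,bias preprocessing settings, see
#'   [preprocess_lesion()].
#' @param verbose print progress.
#' @return a `cohort_table` list: `X` (lesions x 1209 matrix), `y`,
#'   `patient_ids`, `lesion_ids`, `diameters_mm`, `feature_names`.
#' @export
extract_cohort <- function(cohort, params = extract_params(),
                           bias_fwhm_mm = 60, margin_voxels = 2L,
                           bias = TRUE, verbose = FALSE) {
  manifest <- if (is.data.frame(cohort)) cohort else cohort$manifest
  n <- nrow(manifest)
  in_memory <- !is.data.frame(cohort) && !is.null(cohort$volumes)
  spacing <- if (!is.data.frame(cohort)) cohort$spacing else NULL
  X <- matrix(NA_real_, n, 1209L)
  for (i in seq_len(n)) {
    if (in_memory) {
      vol <- cohort$volumes[[i]]; msk <- cohort$masks[[i]]; sp <- spacing
    } else {
      vol <- as.array(RNifti::readNifti(manifest$volume_path[i]))
      msk <- as.array(RNifti::readNifti(manifest$mask_path[i]))
      sp <- RNifti::pixdim(RNifti::readNifti(manifest$volume_path[i]))[1:3]
    }
    lv <- lesion_volume(vol, msk, sp, lesion_id = manifest$lesion_id[i])
    lv <- preprocess_lesion(lv, bias_fwhm_mm, margin_voxels, bias)
    X[i, ] <- extract_all(lv, params)
    if (verbose && i %% 25 == 0) message("  extracted ", i, "/", n, " lesions")
  }
  colnames(X) <- feature_registry(params$bank)
  cohort_table(X, manifest$label, manifest$patient_id, manifest$lesion_id,
               manifest$diameter_mm)
}

#' Assemble a cohort feature table
#'
#' @param X lesions x features numeric matrix (no missing values).
#' @param y binary labels (0/1).
#' @param patient_ids,lesion_ids,diameters_mm per-lesion metadata.
#' @return a `cohort_table` list.
#' @export
cohort_table <- function(X, y, patient_ids, lesion_ids,
                         diameters_mm = rep(NA_real_, nrow(X))) {
  stopifnot(nrow(X) == length(y), length(y) == length(patient_ids),
            length(y) == length(lesion_ids))
  if (anyNA(X)) stop("feature matrix contains missing values")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  structure(list(X = X, y = y, patient_ids = as.character(patient_ids),
                 lesion_ids = as.character(lesion_ids),
                 diameters_mm = as.numeric(diameters_mm),
                 feature_names = colnames(X)),
            class = "cohort_table")
}
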