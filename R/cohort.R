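#' Configuration for the synthetic two-class lesion cohort
#'
#' Defines the study conditions the generator emulates: ~60 patients carrying
#' 1-12 contrast-enhancing brain metastases each (cohort mean about 3.4
#' lesions/patient), lesion diameters between 3 and 40 mm (mean near 10.6 mm),
#' and a per-patient binary molecular label (0 = wild type, 1 = mutant) shared
#' by all of a patient's lesions. Class membership shifts the intralesional
#' texture: each class has its own stationary-random-field parameters
#' (Gaussian correlation length in mm, field standard deviation, rim
#' contrast). Volumes carry background noise and a smooth multiplicative
#' bias field.
#'
#' @param n_patients number of patients.
#' @param lesions_per_patient list with `min`, `max`, `mean` of the truncated
#'   geometric lesion count per patient.
#' @param diameter_mm list with `min`, `max`, `mean`, `sd` of the truncated
#'   log-normal lesion diameter (longest axis, mm).
#' @param class_fraction fraction of patients assigned label 1.
#' @param texture_effect list with elements `class0` and `class1`, each a list
#'   `correlation_length_mm`, `field_sd`, `rim_contrast`.
#' @param voxel_spacing_mm 3-vector of voxel spacing (mm).
#' @param background_sd standard deviation of additive background noise.
#' @param bias_field_amplitude log-scale amplitude of the multiplicative bias.
#' @param tissue_mean baseline tissue intensity.
#' @param lesion_contrast mean enhancement of the lesion over tissue.
#' @param seed RNG seed for the cohort substream.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 61L,
                          lesions_per_patient = list(min = 1L, max = 12L, mean = 3.44),
                          diameter_mm = list(min = 3, max = 40, mean = 10.6, sd = 8),
                          class_fraction = 29 / 61,
                          texture_effect = list(
                            class0 = list(correlation_length_mm = 1.5,
                                          field_sd = 15, rim_contrast = 20),
                            class1 = list(correlation_length_mm = 3.0,
                                          field_sd = 15, rim_contrast = 20)),
                          voxel_spacing_mm = c(1, 1, 1),
                          background_sd = 5,
                          bias_field_amplitude = 0.2,
                          tissue_mean = 100,
                          lesion_contrast = 40,
                          seed = 1L) {
  if (n_patients < 1L) stop("degenerate config: n_patients must be >= 1")
  if (diameter_mm$min < 3) stop("diameter lower bound must be >= 3 mm")
  if (diameter_mm$max < diameter_mm$min) stop("invalid diameter bounds")
  if (class_fraction < 0 || class_fraction > 1)
    stop("class_fraction must lie in [0, 1]")
  if (any(voxel_spacing_mm <= 0)) stop("voxel spacing must be positive")
  if (lesions_per_patient$min < 1L) stop("lesions_per_patient min must be >= 1")
  for (cl in c("class0", "class1")) {
    te <- texture_effect[[cl]]
    if (te$correlation_length_mm < 0 || te$field_sd < 0)
      stop("texture parameters must be nonnegative")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    lesions_per_patient = lesions_per_patient,
    diameter_mm = diameter_mm, class_fraction = class_fraction,
    texture_effect = texture_effect, voxel_spacing_mm = voxel_spacing_mm,
    background_sd = background_sd, bias_field_amplitude = bias_field_amplitude,
    tissue_mean = tissue_mean, lesion_contrast = lesion_contrast,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Zero-mean stationary Gaussian random field
#'
#' White Gaussian noise convolved with a separable Gaussian kernel whose
#' standard deviation is `correlation_length_mm` (per axis, converted to
#' voxels by `spacing`), then rescaled voxel-wise by the exact per-voxel
#' standard deviation of the smoother so the marginal SD equals `field_sd`
#' everywhere, boundaries included. A correlation length of zero yields
#' i.i.d. noise.
#'
#' @param shape 3-vector of array dimensions.
#' @param correlation_length_mm Gaussian kernel SD in mm (>= 0).
#' @param field_sd target marginal standard deviation (>= 0).
#' @param spacing voxel spacing in mm (3-vector).
#' @param seed RNG seed.
#' @return a 3D array.
#' @export
texture_field <- function(shape, correlation_length_mm, field_sd,
                          spacing = c(1, 1, 1), seed = 1L) {
  if (any(shape <= 0)) stop("shape must be positive")
  if (correlation_length_mm < 0 || field_sd < 0)
    stop("correlation length and field SD must be nonnegative")
  with_seed(seed, {
    z <- array(rnorm(prod(shape)), dim = shape)
    if (field_sd == 0) return(array(0, dim = shape))
    if (correlation_length_mm == 0) return(field_sd * z)
    sig <- correlation_length_mm / spacing
    f <- smooth_gaussian3d(z, sig)
    f / smooth_gaussian3d_sdmap(shape, sig) * field_sd
  })
}

#' Embed an ellipsoidal textured lesion into a background volume
#'
#' The mask is the exact set of voxels whose centers fall inside the
#' axis-aligned ellipsoid. Interior voxels get `base_intensity` plus a
#' stationary texture field; voxels in the outer shell (normalized ellipsoid
#' radius > `rim_fraction`) additionally get `rim_contrast`, emulating ring
#' enhancement.
#'
#' @param background 3D array to embed into (modified copy returned).
#' @param center voxel coordinates (1-based, 3-vector) of the lesion center.
#' @param radii_mm ellipsoid semi-axes in mm (3-vector).
#' @param interior list `correlation_length_mm`, `field_sd` for the texture.
#' @param rim_contrast added intensity of the rim shell.
#' @param spacing voxel spacing (mm).
#' @param base_intensity interior base level.
#' @param rim_fraction normalized radius where the rim shell starts.
#' @param seed RNG seed for the texture field.
#' @return list with `volume` (array) and `mask` (0/1 integer array).
#' @export
embed_lesion <- function(background, center, radii_mm, interior,
                         rim_contrast = 0, spacing = c(1, 1, 1),
                         base_intensity = 140, rim_fraction = 0.85,
                         seed = 1L) {
  d <- dim(background)
  r_vox <- radii_mm / spacing
  if (any(center - r_vox < 1) || any(center + r_vox > d))
    stop("ellipsoid does not fit inside the volume")
  ax <- (seq_len(d[1]) - center[1]) / r_vox[1]
  ay <- (seq_len(d[2]) - center[2]) / r_vox[2]
  az <- (seq_len(d[3]) - center[3]) / r_vox[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  mask <- array(as.integer(r2 <= 1), dim = d)
  if (sum(mask) == 0L) stop("ellipsoid contains no voxel centers")
  tex <- texture_field(d, interior$correlation_length_mm, interior$field_sd,
                       spacing, seed = seed)
  vol <- background
  inside <- mask == 1L
  vol[inside] <- base_intensity + tex[inside]
  rim <- inside & r2 > rim_fraction^2
  vol[rim] <- vol[rim] + rim_contrast
  list(volume = vol, mask = mask)
}

# Truncated geometric-like sampler for lesions/patient: weights q^(k-min),
# with q solved so the truncated mean matches the configured mean (q > 1
# tilts toward the upper bound).
sample_lesion_counts <- function(n, spec) {
  ks <- seq.int(spec$min, spec$max)
  if (length(ks) == 1L) return(rep(ks, n))
  target <- min(max(spec$mean, spec$min + 1e-6), spec$max - 1e-6)
  mean_for <- function(lq) { w <- exp(lq * (ks - ks[1])); sum(ks * w) / sum(w) }
  lq <- stats::uniroot(function(lq) mean_for(lq) - target, c(-40, 40),
                       tol = 1e-10)$root
  w <- exp(lq * (ks - ks[1]))
  sample(ks, n, replace = TRUE, prob = w / sum(w))
}

# Truncated log-normal diameters matching the configured mean/sd.
sample_diameters <- function(n, spec) {
  cv <- spec$sd / spec$mean
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(spec$mean) - sdlog^2 / 2
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(2L * n, meanlog, sdlog)
    out <- c(out, x[x >= spec$min & x <= spec$max])
  }
  out[seq_len(n)]
}

#' Generate a synthetic two-class lesion cohort
#'
#' Draws per-patient labels and lesion counts, per-lesion diameters, and for
#' each lesion builds a 3D volume: background tissue plus noise, an embedded
#' ellipsoidal lesion with class-conditional interior texture and rim, all
#' multiplied by a smooth log-normal bias field. Deterministic given
#' `config$seed`. If `dir` is given, volumes and masks are written as
#' NIfTI-1 (`.nii.gz`) and a manifest CSV is written alongside.
#'
#' @param config a [cohort_config()].
#' @param dir output directory (created if needed), or `NULL` to keep the
#'   cohort in memory only.
#' @param keep_volumes logical; attach volumes/masks to the returned records.
#' @return list with `manifest` (data.frame: lesion_id, patient_id, label,
#'   diameter_mm, volume_path, mask_path) and, if `keep_volumes`, `volumes`
#'   and `masks` (lists of arrays) and `spacing`.
#' @export
generate_cohort <- function(config, dir = NULL, keep_volumes = is.null(dir)) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(dir)) stop("output directory is not writable: ", dir)
  }
  sp <- config$voxel_spacing_mm
  root <- config$seed
  n_pat <- config$n_patients
  cohort <- with_seed(derive_seed(root, "cohort"), {
    n1 <- round(config$class_fraction * n_pat)
    labels <- rep(0L, n_pat)
    if (n1 > 0) labels[sample.int(n_pat, n1)] <- 1L
    counts <- sample_lesion_counts(n_pat, config$lesions_per_patient)
    list(labels = labels, counts = counts,
         diameters = sample_diameters(sum(counts), config$diameter_mm))
  })
  n_lesions <- sum(cohort$counts)
  patient_idx <- rep(seq_len(n_pat), cohort$counts)
  manifest <- data.frame(
    lesion_id = sprintf("L%04d", seq_len(n_lesions)),
    patient_id = sprintf("P%03d", patient_idx),
    label = cohort$labels[patient_idx],
    diameter_mm = round(cohort$diameters, 3),
    volume_path = NA_character_, mask_path = NA_character_,
    stringsAsFactors = FALSE)

  volumes <- masks <- vector("list", n_lesions)
  pad <- 4L
  for (i in seq_len(n_lesions)) {
    li_seed <- derive_seed(root, "lesion", i)
    rec <- with_seed(li_seed, {
      a <- manifest$diameter_mm[i] / 2            # longest semi-axis, mm
      radii <- c(a, a * runif(1, 0.7, 1), a * runif(1, 0.7, 1))
      radii <- radii[sample.int(3)]               # random axis assignment
      r_vox <- ceiling(radii / sp)
      dims <- 2L * (r_vox + pad) + 1L
      center <- r_vox + pad + 1L
      te <- if (manifest$label[i] == 1L) config$texture_effect$class1
            else config$texture_effect$class0
      bg <- config$tissue_mean +
        array(rnorm(prod(dims), sd = config$background_sd), dim = dims)
      repeat {
        emb <- embed_lesion(bg, center, radii, interior = te,
                            rim_contrast = te$rim_contrast, spacing = sp,
                            base_intensity = config$tissue_mean + config$lesion_contrast,
                            seed = derive_seed(root, "texture", i))
        # the smallest measurable lesions must still voxelize to a usable
        # mask (>= 8 voxels, the minimum for texture pair statistics)
        if (sum(emb$mask) >= 8L) break
        radii <- pmin(radii * 1.1, (r_vox + pad) * sp)
      }
      if (config$bias_field_amplitude > 0) {
        g <- texture_field(dims, correlation_length_mm = 20, field_sd = 1,
                           spacing = sp, seed = derive_seed(root, "bias", i))
        emb$volume <- emb$volume * exp(config$bias_field_amplitude * g)
      }
      # record the realized longest axis (caliper-style diameter)
      list(volume = emb$volume, mask = emb$mask, diameter = 2 * max(radii))
    })
    manifest$diameter_mm[i] <- round(rec$diameter, 3)
    if (!is.null(dir)) {
      vp <- file.path(dir, sprintf("%s_vol.nii.gz", manifest$lesion_id[i]))
      mp <- file.path(dir, sprintf("%s_mask.nii.gz", manifest$lesion_id[i]))
      RNifti::writeNifti(RNifti::asNifti(rec$volume, pixdim = sp), vp)
      RNifti::writeNifti(RNifti::asNifti(rec$mask, pixdim = sp), mp)
      manifest$volume_path[i] <- vp
      manifest$mask_path[i] <- mp
    }
    if (keep_volumes) { volumes[[i]] <- rec$volume; masks[[i]] <- rec$mask }
  }
  if (!is.null(dir)) {
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  out <- list(manifest = manifest, spacing = sp, config = config)
  if (keep_volumes) { out$volumes <- volumes; out$masks <- masks }
  out
}
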