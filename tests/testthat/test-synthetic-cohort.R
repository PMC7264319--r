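test_that("texture_field is a calibrated stationary random field", {
  f <- texture_field(c(32, 32, 32), correlation_length_mm = 2, field_sd = 10,
                     seed = 3)
  expect_lt(abs(sd(f) - 10) / 10, 0.10)
  # zero mean in expectation; the correlated field has few effective
  # independent samples, so allow a few standard errors
  expect_lt(abs(mean(f)), 2.5)

  # zero correlation length -> i.i.d. noise, lag-1 autocorrelation ~ 0
  f0 <- texture_field(c(64, 64, 64), 0, 1, seed = 4)
  r1 <- cor(as.vector(f0[1:63, , ]), as.vector(f0[2:64, , ]))
  expect_lt(abs(r1), 0.05)

  # longer correlation length -> larger lag-1 autocorrelation
  lag1 <- function(cl, seed) {
    f <- texture_field(c(32, 32, 32), cl, 5, seed = seed)
    cor(as.vector(f[1:31, , ]), as.vector(f[2:32, , ]))
  }
  expect_gt(lag1(3, 7), lag1(1, 7))

  # determinism and degenerate cases
  expect_identical(texture_field(c(8, 8, 8), 2, 5, seed = 9),
                   texture_field(c(8, 8, 8), 2, 5, seed = 9))
  expect_false(identical(texture_field(c(8, 8, 8), 2, 5, seed = 9),
                         texture_field(c(8, 8, 8), 2, 5, seed = 10)))
  expect_true(all(texture_field(c(8, 8, 8), 2, 0, seed = 1) == 0))
  expect_error(texture_field(c(0, 8, 8), 2, 1), "positive")
})

test_that("embed_lesion voxelizes the ellipsoid correctly", {
  bg <- array(0, c(21, 21, 21))
  emb <- embed_lesion(bg, c(11, 11, 11), radii_mm = c(5, 5, 5),
                      interior = list(correlation_length_mm = 0, field_sd = 0),
                      base_intensity = 7, rim_contrast = 0)
  vox <- sum(emb$mask)
  expect_lt(abs(vox - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.10)
  # constant interior when texture and rim are off
  expect_equal(unique(emb$volume[emb$mask == 1]), 7)
  # no mask voxels outside the ellipsoid bounding box
  idx <- which(emb$mask == 1, arr.ind = TRUE)
  expect_true(all(idx >= 6 & idx <= 16))
  # out-of-bounds ellipsoid is an error
  expect_error(embed_lesion(bg, c(2, 2, 2), c(5, 5, 5),
                            list(correlation_length_mm = 0, field_sd = 0)),
               "fit")
})

test_that("generate_cohort is deterministic and structurally valid", {
  co <- tiny_cohort()
  m <- co$manifest
  expect_true(all(m$diameter_mm >= 3))
  expect_false(any(duplicated(m$lesion_id)))
  # all lesions of one patient share the patient's label
  expect_true(all(tapply(m$label, m$patient_id,
                         function(v) length(unique(v))) == 1))
  co2 <- generate_cohort(co$config)
  expect_identical(m, co2$manifest)
  expect_identical(co$volumes, co2$volumes)

  # degenerate class fraction
  cfg0 <- cohort_config(n_patients = 4L, class_fraction = 0, seed = 5L,
                        lesions_per_patient = list(min = 1L, max = 2L, mean = 1.5),
                        diameter_mm = list(min = 4, max = 10, mean = 6, sd = 2))
  expect_true(all(generate_cohort(cfg0)$manifest$label == 0L))
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(diameter_mm = list(min = 2, max = 10, mean = 6, sd = 1)),
               ">= 3")
})

test_that("cohort diameter and lesion-count distributions match the config", {
  cfg <- cohort_config(n_patients = 80L, seed = 13L)
  co <- generate_cohort(cfg, keep_volumes = FALSE)
  m <- co$manifest
  expect_gt(nrow(m), 200)
  expect_lt(abs(mean(m$diameter_mm) - cfg$diameter_mm$mean) /
              cfg$diameter_mm$mean, 0.15)
  per_pat <- table(m$patient_id)
  expect_lt(abs(mean(per_pat) - cfg$lesions_per_patient$mean), 0.8)
  expect_true(all(per_pat >= 1 & per_pat <= 12))
})

test_that("cohort round-trips through NIfTI files and the manifest", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 3L, seed = 17L,
                       lesions_per_patient = list(min = 1L, max = 2L, mean = 1.4),
                       diameter_mm = list(min = 4, max = 10, mean = 6, sd = 2))
  co <- generate_cohort(cfg, dir = dir, keep_volumes = TRUE)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), nrow(co$manifest))
  v <- RNifti::readNifti(m$volume_path[1])
  expect_equal(dim(v), dim(co$volumes[[1]]))
  expect_equal(as.vector(v), as.vector(co$volumes[[1]]), tolerance = 1e-6)
})
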