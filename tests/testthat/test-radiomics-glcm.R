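test_that("quantize maps the in-mask range onto 0..n_levels-1", {
  arr <- array(0:31, c(8, 4, 1))
  mask <- array(1L, c(8, 4, 1))
  q <- quantize(arr, 32L, mask)
  expect_equal(as.vector(q$levels), 0:31)
  # constant ROI -> all level 0
  qc <- quantize(array(5, c(2, 2, 2)), 32L, array(1L, c(2, 2, 2)))
  expect_true(all(qc$levels == 0L))
  # two values, two levels
  q2 <- quantize(array(c(0, 10, 0, 10), c(4, 1, 1)), 2L, array(1L, c(4, 1, 1)))
  expect_equal(as.vector(q2$levels), c(0L, 1L, 0L, 1L))
  expect_error(quantize(arr, 1L, mask), "n_levels")
})

test_that("first-order features match hand computations and analytic cases", {
  f <- first_order_features(c(1, 2, 3, 4))
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["variance"]), 1.25)
  # constant ROI conventions
  fc <- first_order_features(rep(3, 10))
  expect_equal(unname(fc[c("variance", "skewness", "kurtosis")]), c(0, 0, 0))
  expect_equal(unname(fc["energy"]), 1)
  expect_equal(unname(fc["entropy"]), 0)
  # exactly uniform over 64 bins: entropy 6 bits, energy 1/64
  v <- rep(seq(0, 63) + 0.5, times = 4) / 64
  fu <- first_order_features(v, n_bins = 64L)
  expect_equal(unname(fu["entropy"]), 6)
  expect_equal(unname(fu["energy"]), 1 / 64)
  expect_error(first_order_features(3), "2 in-mask")
})

test_that("GLCM counting matches by-definition examples", {
  # constant 2x2x1 ROI, single offset, symmetric -> cell (0,0) = 4
  roi <- roi_from_levels(array(0L, c(2, 2, 1)), 2L)
  g <- compute_glcm(roi, offsets = matrix(c(0L, 1L, 0L), 1))
  expect_equal(g$counts[1, 1], 4L)
  expect_equal(sum(g$counts), 4L)

  # 1D alternating ROI [0,1,0,1]
  roi2 <- roi_from_levels(array(c(0L, 1L, 0L, 1L), c(4, 1, 1)), 2L)
  g2 <- compute_glcm(roi2, offsets = matrix(c(1L, 0L, 0L), 1))
  expect_equal(g2$counts[1, 2], 3L)
  expect_equal(g2$counts[2, 1], 3L)
  expect_equal(g2$counts[1, 1] + g2$counts[2, 2], 0L)

  # no valid pairs -> error
  lone <- array(NA_integer_, c(3, 3, 3)); lone[2, 2, 2] <- 0L
  expect_error(compute_glcm(roi_from_levels(lone, 2L)), "pairs")
})

test_that("GLCM equals brute-force pair enumeration on small ROIs", {
  offs <- glcm_offsets()
  for (lv in random_small_rois()) {
    roi <- roi_from_levels(lv, 4L)
    got <- tryCatch(compute_glcm(roi)$counts, error = function(e) NULL)
    want <- oracle_glcm(lv, offs, 4L)
    if (is.null(got)) { expect_equal(sum(want), 0L); next }
    expect_identical(unname(got), unname(want))
    # symmetry and pair-count conservation
    expect_identical(got, t(got))
  }
})

test_that("Haralick statistics match hand-computed matrices", {
  # delta distribution
  h1 <- haralick_features(matrix(c(8, 0, 0, 0), 2, 2))
  expect_equal(unname(h1["asm"]), 1)
  expect_equal(unname(h1["contrast"]), 0)
  expect_equal(unname(h1["entropy"]), 0)
  expect_equal(unname(h1["idm"]), 1)

  # uniform 2x2 joint distribution: every value known in closed form
  h <- haralick_features(matrix(0.25, 2, 2))
  expect_equal(unname(h["asm"]), 0.25, tolerance = 1e-9)
  expect_equal(unname(h["contrast"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(h["correlation"]), 0, tolerance = 1e-9)
  expect_equal(unname(h["variance"]), 0.25, tolerance = 1e-9)
  expect_equal(unname(h["idm"]), 0.75, tolerance = 1e-9)
  expect_equal(unname(h["sum_average"]), 3, tolerance = 1e-9)
  expect_equal(unname(h["sum_variance"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(h["sum_entropy"]), 1.5, tolerance = 1e-9)
  expect_equal(unname(h["entropy"]), 2, tolerance = 1e-9)
  expect_equal(unname(h["difference_variance"]), 0.25, tolerance = 1e-9)
  expect_equal(unname(h["difference_entropy"]), 1, tolerance = 1e-9)
  expect_equal(unname(h["imc1"]), 0, tolerance = 1e-9)
  expect_equal(unname(h["imc2"]), 0, tolerance = 1e-9)
  expect_equal(unname(h["mcc"]), 0, tolerance = 1e-9)
})

test_that("Haralick values are bounded on random matrices", {
  set.seed(11)
  for (i in 1:10) {
    cm <- matrix(rpois(16, 3), 4, 4)
    cm <- cm + t(cm)
    if (sum(cm) == 0) next
    h <- haralick_features(cm)
    expect_true(h["asm"] > 0 && h["asm"] <= 1)
    expect_gte(unname(h["entropy"]), 0)
    expect_true(abs(h["correlation"]) <= 1 + 1e-12)
    expect_true(h["mcc"] >= 0 && h["mcc"] <= 1 + 1e-9)
  }
})
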