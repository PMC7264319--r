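# Shared fixtures and independent oracles for the test suite.

# session-level cache so expensive fixtures are built once per test run
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Brute-force GLCM: triple loop over voxels and offsets, counting level
# pairs with both voxels in the mask (both orderings when symmetric).
oracle_glcm <- function(levels, offsets, n_levels, symmetric = TRUE) {
  d <- dim(levels)
  counts <- matrix(0L, n_levels, n_levels)
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- levels[x, y, z]
      if (is.na(a)) next
      x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
          z2 < 1 || z2 > d[3]) next
      b <- levels[x2, y2, z2]
      if (is.na(b)) next
      counts[a + 1L, b + 1L] <- counts[a + 1L, b + 1L] + 1L
      if (symmetric) counts[b + 1L, a + 1L] <- counts[b + 1L, a + 1L] + 1L
    }
  }
  counts
}

# Brute-force GLRLM: walk every line in each direction, run-length encode.
oracle_glrlm <- function(levels, directions, n_levels, max_run) {
  d <- dim(levels)
  counts <- matrix(0L, n_levels, max_run)
  add_run <- function(lv, len) {
    len <- min(len, max_run)
    counts[lv + 1L, len] <<- counts[lv + 1L, len] + 1L
  }
  for (o in seq_len(nrow(directions))) {
    off <- directions[o, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      # line start: predecessor out of bounds
      px <- x - off[1]; py <- y - off[2]; pz <- z - off[3]
      if (px >= 1 && px <= d[1] && py >= 1 && py <= d[2] &&
          pz >= 1 && pz <= d[3]) next
      cur <- NA; len <- 0L
      cx <- x; cy <- y; cz <- z
      while (cx >= 1 && cx <= d[1] && cy >= 1 && cy <= d[2] &&
             cz >= 1 && cz <= d[3]) {
        v <- levels[cx, cy, cz]
        if (is.na(v)) {
          if (len > 0L) add_run(cur, len)
          cur <- NA; len <- 0L
        } else if (!is.na(cur) && v == cur) {
          len <- len + 1L
        } else {
          if (len > 0L) add_run(cur, len)
          cur <- v; len <- 1L
        }
        cx <- cx + off[1]; cy <- cy + off[2]; cz <- cz + off[3]
      }
      if (len > 0L) add_run(cur, len)
    }
  }
  counts
}

# quantized_roi from a plain integer array (NA outside mask)
roi_from_levels <- function(levels, n_levels) {
  structure(list(levels = levels, n_levels = as.integer(n_levels),
                 mask = array(as.integer(!is.na(levels)), dim = dim(levels))),
            class = "quantized_roi")
}

# random small ROI fixture set for oracle-equivalence checks
random_small_rois <- function(n = 12, n_levels = 4, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    d <- sample(2:5, 3, replace = TRUE)
    lv <- array(sample(0:(n_levels - 1), prod(d), replace = TRUE), dim = d)
    lv[array(runif(prod(d)) < 0.3, dim = d)] <- NA   # holes in the mask
    if (all(is.na(lv))) lv[1, 1, 1] <- 0L
    lv
  })
}

# synthetic feature table: n1 informative features at effect size d, rest
# pure noise; returns a cohort_table
make_informative_table <- function(n = 200, p_info = 5, p_noise = 95,
                                   d = 1.5, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- cbind(
    matrix(rnorm(n * p_info) + d * y, n, p_info),
    matrix(rnorm(n * p_noise), n, p_noise))
  colnames(X) <- c(paste0("info", seq_len(p_info)),
                   paste0("noise", seq_len(p_noise)))
  cohort_table(X, y, patient_ids = paste0("P", seq_len(n)),
               lesion_ids = paste0("L", seq_len(n)))
}

# small in-memory cohort for pipeline-level tests
tiny_cohort <- function() cached("tiny_cohort", function() {
  cfg <- cohort_config(
    n_patients = 10L,
    lesions_per_patient = list(min = 1L, max = 4L, mean = 2.2),
    diameter_mm = list(min = 4, max = 14, mean = 8, sd = 3),
    class_fraction = 0.5, seed = 31L)
  generate_cohort(cfg)
})

tiny_table <- function() cached("tiny_table", function()
  extract_cohort(tiny_cohort()))

# full-size cohorts for the end-to-end recovery checks: the default
# configuration carries the class texture effect (2x correlation length);
# the null configuration gives both classes identical texture
strong_table <- function() cached("strong_table", function()
  extract_cohort(generate_cohort(cohort_config(seed = 11L))))

null_table <- function() cached("null_table", function() {
  te <- list(correlation_length_mm = 1.5, field_sd = 15, rim_contrast = 20)
  cfg <- cohort_config(texture_effect = list(class0 = te, class1 = te),
                       seed = 21L)
  extract_cohort(generate_cohort(cfg))
})

# intermediate effect: mutant correlation length 2.0 mm instead of 3.0 mm
weak_table <- function() cached("weak_table", function() {
  cfg <- cohort_config(texture_effect = list(
    class0 = list(correlation_length_mm = 1.5, field_sd = 15, rim_contrast = 20),
    class1 = list(correlation_length_mm = 2.0, field_sd = 15, rim_contrast = 20)),
    seed = 11L)
  extract_cohort(generate_cohort(cfg))
})
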