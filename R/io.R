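#' Read and validate a cohort manifest
#'
#' Expects a CSV with header `lesion_id,patient_id,label,diameter_mm,
#' volume_path,mask_path`. Duplicate lesion ids, labels outside {0,1},
#' diameters below 3 mm, and missing volume/mask files are rejected with an
#' error naming the offending row and column.
#'
#' @param path manifest CSV path.
#' @param check_files verify that volume/mask files exist.
#' @return a validated manifest data.frame.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("lesion_id", "patient_id", "label", "diameter_mm",
                "volume_path", "mask_path")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0L)
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "))
  dup <- which(duplicated(m$lesion_id))
  if (length(dup) > 0L)
    stop("duplicate lesion_id at row ", dup[1], " (column lesion_id): ",
         m$lesion_id[dup[1]])
  bad <- which(!(m$label %in% c(0, 1)))
  if (length(bad) > 0L)
    stop("invalid label at row ", bad[1], " (column label): ", m$label[bad[1]])
  bad <- which(!is.finite(m$diameter_mm) | m$diameter_mm < 3)
  if (length(bad) > 0L)
    stop("invalid diameter at row ", bad[1], " (column diameter_mm): ",
         m$diameter_mm[bad[1]])
  # a lesion maps to exactly one patient by construction (one row per lesion)
  if (check_files) {
    for (col in c("volume_path", "mask_path")) {
      bad <- which(!file.exists(m[[col]]))
      if (length(bad) > 0L)
        stop("missing file at row ", bad[1], " (column ", col, "): ",
             m[[col]][bad[1]])
    }
  }
  m$label <- as.integer(m$label)
  m
}

#' Assemble a full-pipeline run configuration
#'
#' A single JSON-serializable document holding every knob of a run:
#' generator config, preprocessing, extraction, selection/evaluation grids,
#' permutation settings, and the root seed all substreams derive from.
#'
#' @param output_dir where artifacts are written.
#' @param seed root seed.
#' @param cohort a [cohort_config()] (or NULL to use an existing manifest).
#' @param manifest path to an existing manifest (ignored when `cohort`
#'   given).
#' @param selectors,classifiers grid subsets.
#' @param k_grid candidate feature counts.
#' @param n_permutations label permutations for the significance test.
#' @param subgroup_threshold_mm small/large diameter cut (mm).
#' @param bias_fwhm_mm,margin_voxels,bias preprocessing settings.
#' @param n_levels,n_bins extraction settings.
#' @param alpha prefilter significance level.
#' @param grouping fold grouping (`"lesion"` or `"patient"`).
#' @param subgroups also evaluate small/large subgroups.
#' @return a `run_config` list.
#' @export
run_config <- function(output_dir = "bmradiomics_run", seed = 1L,
                       cohort = cohort_config(seed = seed), manifest = NULL,
                       selectors = selector_names(),
                       classifiers = classifier_names(),
                       k_grid = 2:50, n_permutations = 500L,
                       subgroup_threshold_mm = 10,
                       bias_fwhm_mm = 60, margin_voxels = 2L, bias = TRUE,
                       n_levels = 32L, n_bins = 64L, alpha = 0.05,
                       grouping = "lesion", subgroups = TRUE) {
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 cohort = cohort, manifest = manifest, selectors = selectors,
                 classifiers = classifiers, k_grid = k_grid,
                 n_permutations = as.integer(n_permutations),
                 subgroup_threshold_mm = subgroup_threshold_mm,
                 bias_fwhm_mm = bias_fwhm_mm,
                 margin_voxels = as.integer(margin_voxels), bias = bias,
                 n_levels = as.integer(n_levels), n_bins = as.integer(n_bins),
                 alpha = alpha, grouping = grouping, subgroups = subgroups),
            class = "run_config")
}

#' Run the full pipeline from one configuration
#'
#' Generate (or load) the cohort, preprocess and extract features, evaluate
#' the selector x classifier grid on all lesions and optionally on the
#' small/large subgroups, and run the permutation test on the best cell.
#' Writes, under `config$output_dir`: the resolved configuration JSON, the
#' feature CSV with an extraction-parameter sidecar, grid and AUC-matrix
#' CSVs plus heatmaps per subgroup, the fold audit CSV, and the permutation
#' JSON. Reruns with the same config are identical at the CSV level.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return invisibly, a list with the cohort table, grid reports and
#'   permutation result.
#' @export
run_all <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))

  say("stage: generate/load cohort")
  cohort <- stage("generate", {
    if (!is.null(config$cohort)) generate_cohort(config$cohort)
    else read_manifest(config$manifest)
  })
  say("stage: preprocess + extract features")
  params <- extract_params(n_levels = config$n_levels, n_bins = config$n_bins)
  table <- stage("extract",
    extract_cohort(cohort, params, bias_fwhm_mm = config$bias_fwhm_mm,
                   margin_voxels = config$margin_voxels, bias = config$bias,
                   verbose = verbose))
  feat_path <- file.path(config$output_dir, "features.csv")
  write.csv(data.frame(lesion_id = table$lesion_ids,
                       patient_id = table$patient_ids, label = table$y,
                       diameter_mm = table$diameters_mm, table$X,
                       check.names = FALSE),
            feat_path, row.names = FALSE)
  jsonlite::write_json(
    list(n_levels = config$n_levels, n_bins = config$n_bins,
         bias_fwhm_mm = config$bias_fwhm_mm,
         margin_voxels = config$margin_voxels, bias = config$bias,
         n_features = ncol(table$X), package = "bmradiomics",
         version = as.character(utils::packageVersion("bmradiomics"))),
    file.path(config$output_dir, "extraction_params.json"),
    auto_unbox = TRUE, pretty = TRUE)

  say("stage: evaluate grid (all lesions)")
  plan <- cv_plan("kfold", k = 10L, grouping = config$grouping,
                  seed = derive_seed(config$seed, "folds"))
  reports <- list()
  reports$all <- stage("evaluate",
    evaluate_grid(table, config$selectors, config$classifiers, plan,
                  config$k_grid, seed = derive_seed(config$seed, "grid"),
                  alpha = config$alpha, subgroup = "all", verbose = verbose))
  render_grid(reports$all, config$output_dir)
  write.csv(reports$all$cells[[1]]$audit,
            file.path(config$output_dir, "fold_audit.csv"), row.names = FALSE)

  if (config$subgroups) {
    say("stage: subgroup grids")
    sub <- stage("subgroups",
      subgroup_grids(table, config$subgroup_threshold_mm, config$selectors,
                     config$classifiers, config$k_grid,
                     seed = derive_seed(config$seed, "subgroups"),
                     alpha = config$alpha, grouping = config$grouping,
                     verbose = verbose))
    for (sg in names(sub)) render_grid(sub[[sg]], config$output_dir)
    reports <- c(reports, sub)
  }

  say("stage: permutation test on best cell")
  best <- reports$all$summary[which.max(reports$all$summary$auc), ]
  perm <- stage("permutation",
    permutation_test(table, best$selector, best$classifier, plan,
                     config$k_grid, n_permutations = config$n_permutations,
                     seed = derive_seed(config$seed, "permutation"),
                     alpha = config$alpha))
  jsonlite::write_json(
    list(selector = best$selector, classifier = best$classifier,
         observed_auc = perm$observed_auc, n_permutations = perm$n_permutations,
         n_higher = perm$n_higher, p_value = perm$p_value),
    file.path(config$output_dir, "permutation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  resolved <- config
  resolved$cohort <- unclass(resolved$cohort)
  jsonlite::write_json(unclass(resolved),
                       file.path(config$output_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  say("done")
  invisible(list(table = table, reports = reports, permutation = perm))
}
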