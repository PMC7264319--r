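#' Cross-validation plan
#'
#' @param scheme `"kfold"` or `"leave_one_out"`.
#' @param k folds for `"kfold"`.
#' @param grouping `"lesion"` (folds over lesions, replicating the original
#'   design and its acknowledged leakage risk when patients contribute
#'   several lesions) or `"patient"` (all of a patient's lesions share a
#'   fold).
#' @param stratified stratify folds by class label.
#' @param seed RNG seed for fold assignment.
#' @return a `cv_plan` list.
#' @export
cv_plan <- function(scheme = c("kfold", "leave_one_out"), k = 10L,
                    grouping = c("lesion", "patient"), stratified = TRUE,
                    seed = 1L) {
  scheme <- match.arg(scheme)
  grouping <- match.arg(grouping)
  if (scheme == "kfold" && k < 2L) stop("k must be >= 2")
  structure(list(scheme = scheme, k = as.integer(k), grouping = grouping,
                 stratified = stratified, seed = as.integer(seed)),
            class = "cv_plan")
}

# Stratified assignment of units to k folds with sizes differing by <= 1:
# each class contributes floor(n_c / k) units per fold, and the class
# remainders are laid out over complementary fold ranges.
stratified_fold_ids <- function(y, k) {
  n <- length(y)
  fold <- integer(n)
  offset <- 0L
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    n_c <- length(idx)
    base <- n_c %/% k; rem <- n_c %% k
    sizes <- rep(base, k)
    if (rem > 0) {
      pos <- ((offset + seq_len(rem) - 1L) %% k) + 1L
      sizes[pos] <- sizes[pos] + 1L
      offset <- offset + rem
    }
    fold[idx] <- rep(seq_len(k), times = sizes)
  }
  fold
}

#' Build cross-validation folds
#'
#' Stratified partition into test sets; fold sizes differ by at most one.
#' With patient grouping, every lesion of a patient lands in the same fold
#' (patients are assigned to folds stratified by patient label, balancing
#' lesion counts greedily). Deterministic given `plan$seed`.
#'
#' @param table a [cohort_table()].
#' @param plan a [cv_plan()].
#' @return list of folds, each `list(train = idx, test = idx)`.
#' @export
make_folds <- function(table, plan) {
  n <- length(table$y)
  if (plan$scheme == "leave_one_out") {
    return(lapply(seq_len(n), function(i)
      list(train = setdiff(seq_len(n), i), test = i)))
  }
  k <- plan$k
  if (plan$grouping == "lesion") {
    if (n < k) stop("fewer lesions than folds")
    fold <- with_seed(plan$seed, stratified_fold_ids(table$y, k))
  } else {
    pats <- unique(table$patient_ids)
    if (length(pats) < k) stop("fewer patients than folds")
    plab <- vapply(pats, function(p)
      table$y[match(p, table$patient_ids)], integer(1))
    psize <- vapply(pats, function(p) sum(table$patient_ids == p), integer(1))
    pfold <- with_seed(plan$seed, {
      fold_load <- rep(0L, k)
      out <- integer(length(pats))
      for (cl in sort(unique(plab))) {
        # biggest patients first, random ties, onto the lightest fold
        o <- order(-psize, runif(length(pats)))
        o <- o[plab[o] == cl]
        for (i in o) {
          f <- which.min(fold_load)
          out[i] <- f
          fold_load[f] <- fold_load[f] + psize[i]
        }
      }
      out
    })
    fold <- pfold[match(table$patient_ids, pats)]
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

#' Area under the ROC curve (Mann-Whitney estimator), in percent
#'
#' Probability that a random positive outscores a random negative; ties
#' count one half. Equivalent to the rank-sum statistic with midranks.
#'
#' @param scores numeric decision scores.
#' @param labels binary labels (1 = positive).
#' @return AUC on the 0-100 scale.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  100 * (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal threshold of a score vector
#'
#' The candidate threshold (over observed scores) maximizing
#' sensitivity + specificity - 1, predicting positive when `score >= t`;
#' ties resolved toward the smallest threshold.
#'
#' @param scores,labels decision scores and binary labels.
#' @return a threshold value.
#' @export
youden_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sum(pred & labels == 1L) / sum(labels == 1L) +
      sum(!pred & labels == 0L) / sum(labels == 0L) - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Sensitivity, specificity, accuracy at a threshold, in percent
#'
#' Class 1 (mutant) is the positive class; predictions are positive when
#' `score >= threshold`. The threshold defaults to the Youden-optimal value
#' on the supplied scores.
#'
#' @param scores,labels decision scores and binary labels.
#' @param threshold decision threshold (default: Youden).
#' @return named vector `sensitivity`, `specificity`, `accuracy`,
#'   `threshold`.
#' @export
confusion_metrics <- function(scores, labels, threshold = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes required")
  threshold <- threshold %||% youden_threshold(scores, labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L); fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L); fp <- sum(pred & labels == 0L)
  c(sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / length(labels),
    threshold = threshold)
}

#' Evaluate one selector x classifier grid cell under cross-validation
#'
#' Per fold: the t-test prefilter and the selector are fit on the training
#' lesions only; for every candidate feature count `k` the classifier is
#' fit on the top-k features and scores the test fold. Test scores are
#' pooled across folds per `k`; the optimal feature count maximizes pooled
#' AUC (smallest k on ties) and sensitivity/specificity/accuracy are
#' computed at the Youden threshold of its pooled scores. An audit table
#' records the exact train/test membership of every fold.
#'
#' @param table a [cohort_table()].
#' @param selector one of [selector_names()].
#' @param classifier one of [classifier_names()].
#' @param plan a [cv_plan()].
#' @param k_grid candidate feature counts.
#' @param seed root seed for selector/classifier substreams.
#' @param alpha prefilter significance level.
#' @param selector_params,classifier_params hyperparameter overrides.
#' @return a `cell_result` list: `selector`, `classifier`, `optimal_k`,
#'   `auc`, `sensitivity`, `specificity`, `accuracy`, `threshold`,
#'   `auc_by_k`, `pooled` (scores/labels at optimal k), `per_fold_scores`,
#'   `audit`.
#' @export
train_eval_cell <- function(table, selector, classifier, plan,
                            k_grid = 2:50, seed = 1L, alpha = 0.05,
                            selector_params = list(),
                            classifier_params = list()) {
  stopifnot(inherits(table, "cohort_table"))
  selector <- match.arg(selector, selector_names())
  classifier <- match.arg(classifier, classifier_names())
  folds <- make_folds(table, plan)
  n <- length(table$y)
  pooled <- matrix(NA_real_, n, length(k_grid))
  audit <- do.call(rbind, lapply(seq_along(folds), function(f)
    data.frame(fold = f,
               lesion_id = table$lesion_ids[c(folds[[f]]$train, folds[[f]]$test)],
               patient_id = table$patient_ids[c(folds[[f]]$train, folds[[f]]$test)],
               role = rep(c("train", "test"),
                          c(length(folds[[f]]$train), length(folds[[f]]$test))),
               stringsAsFactors = FALSE)))
  per_fold <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    ytr <- table$y[tr]
    if (length(unique(ytr)) < 2L) stop("fold ", f, " has a single training class")
    keep <- ttest_prefilter(table$X[tr, , drop = FALSE], ytr, alpha = alpha)
    Xtr <- table$X[tr, keep, drop = FALSE]
    Xte <- table$X[te, keep, drop = FALSE]
    rk <- do.call(rank_features,
                  c(list(X = Xtr, y = ytr, method = selector,
                         seed = derive_seed(seed, "selector", f)),
                    selector_params))
    for (ki in seq_along(k_grid)) {
      k <- min(k_grid[ki], length(keep))
      top <- rk$order[seq_len(k)]
      pooled[te, ki] <- fit_score(Xtr[, top, drop = FALSE], ytr,
                                  Xte[, top, drop = FALSE], classifier,
                                  seed = derive_seed(seed, "classifier",
                                                     f * 1000L + ki),
                                  params = classifier_params)
    }
    per_fold[[f]] <- list(test = te, prefilter = keep,
                          ranking_head = keep[rk$order[seq_len(min(50, length(keep)))]])
  }
  aucs <- apply(pooled, 2, auc_score, labels = table$y)
  best <- which.max(aucs)       # ties -> smallest k by which.max
  sc <- pooled[, best]
  cm <- confusion_metrics(sc, table$y)
  structure(list(selector = selector, classifier = classifier,
                 optimal_k = as.integer(min(k_grid[best], ncol(table$X))),
                 auc = aucs[best],
                 sensitivity = unname(cm["sensitivity"]),
                 specificity = unname(cm["specificity"]),
                 accuracy = unname(cm["accuracy"]),
                 threshold = unname(cm["threshold"]),
                 auc_by_k = setNames(aucs, k_grid),
                 pooled = list(scores = sc, labels = table$y),
                 per_fold_scores = per_fold, audit = audit, seed = seed),
            class = "cell_result")
}

#' Exact permutation-test p-value formula
#'
#' `p = (1 + m) / (n + 1)` where `m` permutations achieve an AUC at least as
#' high as the observed one and `n` permutations were run; the observed
#' labeling counts as one test.
#'
#' @param n_higher permutations with AUC >= observed.
#' @param n_permutations number of label permutations.
#' @return the p-value.
#' @export
perm_pvalue <- function(n_higher, n_permutations)
  (1 + n_higher) / (n_permutations + 1)

#' Label-permutation significance test of a grid cell
#'
#' Permutes the class labels (patient-level labels when the plan groups by
#' patient, lesion-level otherwise), reruns the full cross-validated cell on
#' each permuted labeling, and counts permutations whose pooled AUC is at
#' least the observed AUC.
#'
#' @inheritParams train_eval_cell
#' @param n_permutations number of permutations (the original design used
#'   500).
#' @param observed optionally a precomputed `cell_result` for the true
#'   labels.
#' @return a `permutation_result` list: `observed_auc`, `n_permutations`,
#'   `n_higher`, `p_value`, `perm_aucs`.
#' @export
permutation_test <- function(table, selector, classifier, plan,
                             k_grid = 2:50, n_permutations = 500L,
                             seed = 1L, alpha = 0.05,
                             selector_params = list(),
                             classifier_params = list(),
                             observed = NULL) {
  if (is.null(observed))
    observed <- train_eval_cell(table, selector, classifier, plan, k_grid,
                                seed = seed, alpha = alpha,
                                selector_params = selector_params,
                                classifier_params = classifier_params)
  perm_aucs <- vapply(seq_len(n_permutations), function(b) {
    pt <- table
    pt$y <- with_seed(derive_seed(seed, "permutation", b), {
      if (plan$grouping == "patient") {
        pats <- unique(table$patient_ids)
        plab <- table$y[match(pats, table$patient_ids)]
        plab <- sample(plab)
        plab[match(table$patient_ids, pats)]
      } else sample(table$y)
    })
    bp <- plan
    bp$seed <- derive_seed(seed, "permutation_folds", b)
    cell <- train_eval_cell(pt, selector, classifier, bp, k_grid,
                            seed = derive_seed(seed, "permutation_cell", b),
                            alpha = alpha, selector_params = selector_params,
                            classifier_params = classifier_params)
    cell$auc
  }, numeric(1))
  n_higher <- sum(perm_aucs >= observed$auc)
  structure(list(observed_auc = observed$auc,
                 n_permutations = as.integer(n_permutations),
                 n_higher = as.integer(n_higher),
                 p_value = perm_pvalue(n_higher, n_permutations),
                 perm_aucs = perm_aucs),
            class = "permutation_result")
}

#' Evaluate a selector x classifier grid
#'
#' @inheritParams train_eval_cell
#' @param selectors,classifiers method subsets (defaults: all 7 x 4).
#' @param subgroup label recorded in the report (`"all"`, `"small"`,
#'   `"large"`).
#' @param verbose print per-cell progress.
#' @return a `grid_report` list: `cells` (list of `cell_result`), `summary`
#'   (data.frame with one row per cell), `subgroup`, `plan`.
#' @export
evaluate_grid <- function(table, selectors = selector_names(),
                          classifiers = classifier_names(), plan = cv_plan(),
                          k_grid = 2:50, seed = 1L, alpha = 0.05,
                          subgroup = "all", verbose = FALSE) {
  cells <- list()
  for (s in selectors) for (cl in classifiers) {
    if (verbose) message("  cell ", s, " x ", cl)
    cells[[paste(s, cl, sep = ".")]] <-
      train_eval_cell(table, s, cl, plan, k_grid,
                      seed = derive_seed(seed, paste("cell", s, cl)),
                      alpha = alpha)
  }
  summary <- do.call(rbind, lapply(cells, function(ce)
    data.frame(selector = ce$selector, classifier = ce$classifier,
               optimal_k = ce$optimal_k, auc = ce$auc,
               sensitivity = ce$sensitivity, specificity = ce$specificity,
               accuracy = ce$accuracy, stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(cells = cells, summary = summary, subgroup = subgroup,
                 plan = plan), class = "grid_report")
}

#' Size-subgroup evaluation (small vs large lesions)
#'
#' Partitions the cohort at `threshold_mm` (small: diameter < threshold,
#' large: diameter >= threshold, so the two subgroups tile the cohort),
#' evaluates the small subgroup under 10-fold CV and the large subgroup
#' under leave-one-out, mirroring the original design. A subgroup missing
#' either class is skipped with a warning.
#'
#' @inheritParams evaluate_grid
#' @param threshold_mm diameter threshold (mm).
#' @return named list of `grid_report`s (`small`, `large`; absent if
#'   skipped).
#' @export
subgroup_grids <- function(table, threshold_mm = 10,
                           selectors = selector_names(),
                           classifiers = classifier_names(),
                           k_grid = 2:50, seed = 1L, alpha = 0.05,
                           grouping = "lesion", verbose = FALSE) {
  pick <- function(idx) cohort_table(table$X[idx, , drop = FALSE],
                                     table$y[idx], table$patient_ids[idx],
                                     table$lesion_ids[idx],
                                     table$diameters_mm[idx])
  out <- list()
  small_idx <- which(table$diameters_mm < threshold_mm)
  large_idx <- which(table$diameters_mm >= threshold_mm)
  for (sg in c("small", "large")) {
    idx <- if (sg == "small") small_idx else large_idx
    if (length(idx) == 0L || length(unique(table$y[idx])) < 2L) {
      warning("skipping ", sg, " subgroup: empty or single-class")
      next
    }
    plan <- if (sg == "small")
      cv_plan("kfold", k = 10L, grouping = grouping,
              seed = derive_seed(seed, "small_folds"))
    else cv_plan("leave_one_out", grouping = grouping,
                 seed = derive_seed(seed, "large_folds"))
    out[[sg]] <- evaluate_grid(pick(idx), selectors, classifiers, plan,
                               k_grid, seed = derive_seed(seed, sg),
                               alpha = alpha, subgroup = sg,
                               verbose = verbose)
  }
  out
}

#' Write a grid report as CSV matrices and a heatmap
#'
#' Writes `grid_<subgroup>.csv` (long form: selector, classifier, optimal_k,
#' AUC, sensitivity, specificity, accuracy), `auc_matrix_<subgroup>.csv`
#' (classifiers x selectors AUC matrix in registry order) and
#' `heatmap_<subgroup>.png`.
#'
#' @param report a `grid_report`.
#' @param dir output directory.
#' @return invisibly, the AUC matrix.
#' @export
render_grid <- function(report, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sg <- report$subgroup
  write.csv(report$summary, file.path(dir, sprintf("grid_%s.csv", sg)),
            row.names = FALSE)
  sels <- intersect(selector_names(), unique(report$summary$selector))
  clfs <- intersect(classifier_names(), unique(report$summary$classifier))
  m <- matrix(NA_real_, length(clfs), length(sels),
              dimnames = list(clfs, sels))
  for (i in seq_len(nrow(report$summary)))
    m[report$summary$classifier[i], report$summary$selector[i]] <-
      report$summary$auc[i]
  write.csv(m, file.path(dir, sprintf("auc_matrix_%s.csv", sg)))
  grDevices::png(file.path(dir, sprintf("heatmap_%s.png", sg)),
                 width = 720, height = 480)
  op <- graphics::par(mar = c(5, 6, 3, 2))
  graphics::image(seq_along(sels), seq_along(clfs), t(m)[, rev(seq_along(clfs)),
                                                         drop = FALSE],
                  axes = FALSE, xlab = "feature selection",
                  ylab = "", main = sprintf("AUC (%s lesions)", sg),
                  col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE))
  graphics::axis(1, seq_along(sels), sels)
  graphics::axis(2, seq_along(clfs), rev(clfs), las = 1)
  for (i in seq_along(sels)) for (j in seq_along(clfs))
    graphics::text(i, length(clfs) - j + 1, sprintf("%.1f", m[j, i]))
  graphics::par(op)
  grDevices::dev.off()
  invisible(m)
}
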