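test_that("stratified 10-fold folding of 210 lesions gives train 189 / test 21", {
  y <- c(rep(0L, 116), rep(1L, 94))
  tab <- cohort_table(matrix(rnorm(210 * 4), 210, 4), y,
                      patient_ids = paste0("P", seq_len(210)),
                      lesion_ids = paste0("L", seq_len(210)))
  folds <- make_folds(tab, cv_plan("kfold", 10L, seed = 2))
  expect_length(folds, 10L)
  expect_true(all(vapply(folds, function(f) length(f$test), 0L) == 21L))
  expect_true(all(vapply(folds, function(f) length(f$train), 0L) == 189L))
  # test sets partition the cohort exactly once
  expect_identical(sort(unlist(lapply(folds, `[[`, "test"))), 1:210)
  # stratification: class balance per fold within one lesion
  cls1 <- vapply(folds, function(f) sum(tab$y[f$test]), 0L)
  expect_lte(diff(range(cls1)), 1L)
})

test_that("leave-one-out and patient-grouped folding are valid partitions", {
  tab <- tiny_table()
  loo <- make_folds(tab, cv_plan("leave_one_out"))
  expect_length(loo, length(tab$y))
  expect_true(all(vapply(loo, function(f) length(f$test), 0L) == 1L))

  plan <- cv_plan("kfold", 3L, grouping = "patient", seed = 4)
  folds <- make_folds(tab, plan)
  expect_identical(sort(unlist(lapply(folds, `[[`, "test"))),
                   seq_along(tab$y))
  for (f in folds) {
    split_pats <- intersect(tab$patient_ids[f$train], tab$patient_ids[f$test])
    expect_length(split_pats, 0L)
  }
  expect_error(make_folds(tab, cv_plan("kfold", 100L)), "fewer")
})

test_that("the Mann-Whitney AUC matches pair enumeration and its invariances", {
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 100)
  expect_equal(auc_score(c(0.2, 0.9, 0.4, 0.3), c(0, 1, 0, 1)), 75)
  expect_equal(auc_score(rep(0.5, 10), rep(c(0, 1), 5)), 50)
  expect_error(auc_score(1:4, rep(1, 4)), "classes")
  # invariant under strictly monotone transforms; ties counted half
  set.seed(31)
  for (i in 1:20) {
    s <- rnorm(40); y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    a <- auc_score(s, y)
    expect_equal(auc_score(exp(s), y), a)
    expect_equal(auc_score(qlogis(plogis(s)), y), a, tolerance = 1e-9)
    # agreement with an independent ROC implementation
    expect_equal(a, 100 * as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                         direction = "<"))))
  }
})

test_that("confusion metrics follow the standard definitions", {
  # TP=3, FN=1, TN=4, FP=1 at threshold 0.5
  scores <- c(0.9, 0.8, 0.6, 0.2, 0.1, 0.2, 0.3, 0.4, 0.7)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0)
  m <- confusion_metrics(scores, labels, threshold = 0.5)
  expect_equal(unname(m["sensitivity"]), 75)
  expect_equal(unname(m["specificity"]), 80)
  expect_equal(unname(m["accuracy"]), 700 / 9, tolerance = 1e-9)
  # degenerate rules
  all_pos <- confusion_metrics(scores, labels, threshold = min(scores))
  expect_equal(unname(all_pos["sensitivity"]), 100)
  perfect <- confusion_metrics(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(perfect[c("sensitivity", "specificity", "accuracy")]),
               c(100, 100, 100))
})

test_that("all four classifiers separate an easy problem and error on one class", {
  set.seed(9)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3); X[, 1] <- X[, 1] + 2.5 * y
  colnames(X) <- paste0("f", 1:3)
  te <- seq(1, n, by = 4)
  tr <- setdiff(seq_len(n), te)
  for (cl in classifier_names()) {
    s <- fit_score(X[tr, ], y[tr], X[te, ], cl, seed = 7)
    expect_gt(auc_score(s, y[te]), 85)
    expect_error(fit_score(X[tr, ], rep(1L, length(tr)), X[te, ], cl),
                 "single class")
  }
})

test_that("the permutation p-value formula and machinery are exact", {
  expect_equal(perm_pvalue(0, 500), 1 / 501)
  expect_equal(perm_pvalue(500, 500), 1)
  expect_equal(perm_pvalue(24, 99), 0.25)
  tab <- make_informative_table(n = 40, p_info = 2, p_noise = 6, d = 3,
                                seed = 21)
  plan <- cv_plan("kfold", 4L, seed = 3)
  pr <- permutation_test(tab, "mrmr", "svm", plan, k_grid = 2L,
                         n_permutations = 9L, seed = 5,
                         selector_params = list(k = 2L))
  expect_equal(pr$p_value, (1 + pr$n_higher) / 10)
  expect_length(pr$perm_aucs, 9L)
  # a strong effect should never lose to its own permutations here
  expect_equal(pr$p_value, 0.1)
})

test_that("train_eval_cell keeps selection inside the training folds", {
  tab <- make_informative_table(n = 60, p_info = 3, p_noise = 17, d = 2,
                                seed = 8)
  plan <- cv_plan("kfold", 5L, seed = 6)
  cell <- train_eval_cell(tab, "mrmr", "svm", plan, k_grid = c(2L, 5L),
                          seed = 3, selector_params = list(k = 5L))
  expect_s3_class(cell, "cell_result")
  expect_true(cell$optimal_k %in% c(2L, 5L))
  expect_true(all(c(cell$auc, cell$sensitivity, cell$specificity,
                    cell$accuracy) >= 0))
  expect_true(all(c(cell$sensitivity, cell$specificity, cell$accuracy) <= 100))
  # audit: every lesion appears as test exactly once, never in its own
  # fold's training set
  aud <- cell$audit
  test_rows <- aud[aud$role == "test", ]
  expect_identical(sort(test_rows$lesion_id), sort(tab$lesion_ids))
  for (f in unique(aud$fold)) {
    tr_ids <- aud$lesion_id[aud$fold == f & aud$role == "train"]
    te_ids <- aud$lesion_id[aud$fold == f & aud$role == "test"]
    expect_length(intersect(tr_ids, te_ids), 0L)
  }
  # determinism of the whole cell
  cell2 <- train_eval_cell(tab, "mrmr", "svm", plan, k_grid = c(2L, 5L),
                           seed = 3, selector_params = list(k = 5L))
  expect_identical(cell$pooled$scores, cell2$pooled$scores)
})

test_that("subgroup evaluation partitions at the diameter threshold", {
  tab <- tiny_table()
  small <- sum(tab$diameters_mm < 8)
  large <- sum(tab$diameters_mm >= 8)
  expect_equal(small + large, length(tab$y))
  # all lesions below the threshold: the large grid is skipped with warning
  tab_small <- cohort_table(tab$X, tab$y, tab$patient_ids, tab$lesion_ids,
                            rep(5, length(tab$y)))
  expect_warning(
    out <- subgroup_grids(tab_small, threshold_mm = 10, selectors = "mrmr",
                          classifiers = "svm", k_grid = 3L),
    "skipping")
  expect_named(out, "small")
})

test_that("grid rendering round-trips the AUC matrix through CSV", {
  tab <- make_informative_table(n = 40, p_info = 2, p_noise = 6, d = 2,
                                seed = 10)
  rep_ <- evaluate_grid(tab, selectors = c("mrmr", "relieff"),
                        classifiers = c("svm", "lasso"),
                        plan = cv_plan("kfold", 4L, seed = 2), k_grid = 2L,
                        seed = 4)
  expect_equal(nrow(rep_$summary), 4L)
  dir <- withr::local_tempdir()
  m <- render_grid(rep_, dir)
  back <- as.matrix(read.csv(file.path(dir, "auc_matrix_all.csv"),
                             row.names = 1))
  expect_equal(unname(back), unname(m), tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "heatmap_all.png")))
})
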