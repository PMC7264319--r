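#' Names of the four classifiers, in registry order
#' @return character vector of length 4.
#' @export
classifier_names <- function() c("rf", "svm", "adaboost", "lasso")

# Discrete AdaBoost.M1 with depth-1 rpart stumps. Returns the additive
# margin score sum_t alpha_t h_t(x) (positive favors class 1).
fit_adaboost_stumps <- function(Xtr, ytr, Xte, n_stumps = 200L) {
  n <- nrow(Xtr)
  w <- rep(1 / n, n)
  yy <- ifelse(ytr == 1L, 1, -1)
  dtr <- data.frame(Xtr, check.names = FALSE)
  dte <- data.frame(Xte, check.names = FALSE)
  score <- rep(0, nrow(Xte))
  for (t in seq_len(n_stumps)) {
    fit <- rpart::rpart(y ~ ., data = cbind(y = factor(yy), dtr), weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1L, cp = -1,
                                                       minsplit = 2L,
                                                       minbucket = 1L,
                                                       xval = 0L))
    pred <- ifelse(predict(fit, dtr, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    if (err <= 0) err <- 1e-10
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    score <- score +
      alpha * ifelse(predict(fit, dte, type = "class") == "1", 1, -1)
  }
  score
}

#' Fit a classifier on training data and score a test set
#'
#' Supported classifiers: `rf` (random forest, 500 trees, class
#' probability), `svm` (radial kernel, cost 1, bandwidth from the inverse
#' median squared pairwise distance, decision value), `adaboost` (discrete
#' AdaBoost.M1 over 200 decision stumps, additive margin), `lasso`
#' (l1-regularized logistic regression, penalty chosen by inner 5-fold CV,
#' linear predictor). Higher scores always favor class 1.
#'
#' @param Xtr,ytr training features and binary labels.
#' @param Xte test features.
#' @param classifier one of [classifier_names()].
#' @param seed RNG seed (forest resampling, inner CV folds).
#' @param params optional list of hyperparameter overrides
#'   (`n_trees`, `cost`, `n_stumps`, `inner_folds`).
#' @return numeric vector of test scores.
#' @export
fit_score <- function(Xtr, ytr, Xte, classifier = classifier_names(),
                      seed = 1L, params = list()) {
  classifier <- match.arg(classifier)
  if (length(unique(ytr)) < 2L) stop("training fold contains a single class")
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  if (classifier == "rf") {
    df <- data.frame(..y = factor(ytr, levels = c(0, 1)), Xtr,
                     check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = "..y", data = df,
                          num.trees = params$n_trees %||% 500L,
                          probability = TRUE, seed = seed, num.threads = 1L)
    pr <- predict(fit, data.frame(Xte, check.names = FALSE),
                  num.threads = 1L)$predictions
    return(pr[, "1"])
  }
  if (classifier == "svm") {
    d2 <- as.numeric(dist(Xtr))^2
    gamma <- 1 / max(stats::median(d2), 1e-8)
    fit <- e1071::svm(Xtr, factor(ytr, levels = c(0, 1)), kernel = "radial",
                      cost = params$cost %||% 1, gamma = gamma, scale = TRUE)
    dv <- attr(predict(fit, Xte, decision.values = TRUE), "decision.values")
    s <- as.numeric(dv[, 1])
    # decision values are positive for the class named first in "A/B"
    if (startsWith(colnames(dv)[1], "0")) s <- -s
    return(s)
  }
  if (classifier == "adaboost") {
    return(with_seed(seed, fit_adaboost_stumps(Xtr, ytr, Xte,
                                               params$n_stumps %||% 200L)))
  }
  # lasso-regularized logistic regression with inner CV for lambda
  if (ncol(Xtr) < 2L) {          # glmnet needs >= 2 columns
    Xtr <- cbind(Xtr, `..pad` = 0)
    Xte <- cbind(Xte, `..pad` = 0)
  }
  nf <- params$inner_folds %||% 5L
  foldid <- with_seed(seed, sample(rep_len(seq_len(nf), length(ytr))))
  fit <- glmnet::cv.glmnet(Xtr, factor(ytr, levels = c(0, 1)),
                           family = "binomial", nfolds = nf, foldid = foldid,
                           type.measure = "deviance")
  as.numeric(predict(fit, Xte, s = "lambda.min", type = "link"))
}
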