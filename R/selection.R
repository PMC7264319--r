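#' Welch two-sample t-test prefilter
#'
#' Tests every feature column for a class mean difference (Welch t, unequal
#' variances) and keeps those with p < alpha. If nothing survives, the single
#' smallest-p feature is kept so downstream selection always has input.
#'
#' @param X lesions x features matrix (or a `cohort_table`).
#' @param y binary labels (ignored when `X` is a `cohort_table`).
#' @param alpha significance level.
#' @return integer indices of surviving features, with the p-values as the
#'   `p` attribute.
#' @export
ttest_prefilter <- function(X, y = NULL, alpha = 0.05) {
  if (inherits(X, "cohort_table")) { y <- X$y; X <- X$X }
  g1 <- y == 1L; g0 <- !g1
  n1 <- sum(g1); n0 <- sum(g0)
  if (n1 < 2L || n0 < 2L) stop("both classes need >= 2 samples")
  # per-class first and second moments in two matrix products
  G <- cbind(as.numeric(g1), as.numeric(g0))
  cs <- crossprod(X, G)
  css <- crossprod(X * X, G)
  m1 <- cs[, 1] / n1; m0 <- cs[, 2] / n0
  v1 <- pmax(css[, 1] - n1 * m1^2, 0) / (n1 - 1)
  v0 <- pmax(css[, 2] - n0 * m0^2, 0) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(t), df)
  # zero-variance features: identical means -> p = 1; separated means -> 0
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m0[degen], 1, 0)
  p[!is.finite(p)] <- 1
  keep <- which(p < alpha)
  if (length(keep) == 0L) keep <- which.min(p)
  attr(keep, "p") <- p
  keep
}

ranking_result <- function(method, scores, decreasing = TRUE, seed = NA_integer_) {
  ord <- order(if (decreasing) -scores else scores, seq_along(scores))
  structure(list(method = method, order = ord, scores = scores, seed = seed),
            class = "ranking_result")
}

#' Random-forest permutation-importance ranking
#'
#' Fits a random forest and scores each feature by the out-of-bag accuracy
#' drop after permuting its column (permutation importance); features are
#' ranked by decreasing importance, ties broken by ascending index.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param n_trees number of trees.
#' @param seed RNG seed.
#' @return a `ranking_result`.
#' @export
rank_rf_importance <- function(X, y, n_trees = 500L, seed = 1L) {
  df <- data.frame(..y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = "..y", data = df,
                        num.trees = n_trees, importance = "permutation",
                        seed = seed, num.threads = 1L,
                        respect.unordered.factors = FALSE)
  ranking_result("rf", unname(fit$variable.importance), seed = seed)
}

# Tercile (default) equal-frequency discretization for mutual information.
discretize_cols <- function(X, n_bins = 3L) {
  apply(X, 2, function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                          names = FALSE))
    if (length(br) < 2L) return(rep(1L, length(v)))
    as.integer(cut(v, br, include.lowest = TRUE))
  })
}

# Plug-in mutual information (bits) of two small integer codes in
# 1..na / 1..nb; empty categories contribute nothing.
mutual_information <- function(a, b, na = max(a), nb = max(b)) {
  p <- tabulate((a - 1L) * nb + b, na * nb) / length(a)
  dim(p) <- c(nb, na)                 # b varies fastest
  pa <- colSums(p); pb <- rowSums(p)
  nz <- p > 0
  pp <- outer(pb, pa)
  sum(p[nz] * log2(p[nz] / pp[nz]))
}

#' Minimum-redundancy maximum-relevance (mRMR) ranking
#'
#' Greedy selection maximizing `I(f; y) - mean_s I(f; s)` over already
#' selected features `s`, with mutual information estimated by a plug-in
#' estimator on tercile-discretized features. The first pick is the
#' maximum-relevance feature. After `k` greedy picks the remaining features
#' are appended in relevance order, so the result is a full permutation.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param k number of greedy steps (capped at the feature count).
#' @return a `ranking_result` (`scores` = relevance `I(f;y)`).
#' @export
rank_mrmr <- function(X, y, k = 50L) {
  D <- discretize_cols(X)
  nb <- max(D)
  yc <- as.integer(factor(y))
  ny <- max(yc)
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j)
    mutual_information(D[, j], yc, nb, ny), numeric(1))
  k <- min(k, p)
  selected <- integer(0)
  remaining <- seq_len(p)
  red_sum <- numeric(p)
  for (step in seq_len(k)) {
    crit <- if (length(selected) == 0L) rel[remaining]
            else rel[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[order(-crit, remaining)[1]]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0L) {
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j)
          mutual_information(D[, j], D[, pick], nb, nb), numeric(1))
    }
  }
  ord <- c(selected, remaining[order(-rel[remaining], remaining)])
  structure(list(method = "mrmr", order = ord, scores = rel, seed = NA_integer_),
            class = "ranking_result")
}

#' ReliefF feature weighting
#'
#' For every instance, the k nearest same-class hits and k nearest
#' other-class misses (Euclidean distance on min-max scaled features) pull
#' each feature's weight down for hit differences and up for miss
#' differences (miss terms weighted by class priors). All instances are
#' used, so the ranking is deterministic.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param n_neighbors k nearest hits/misses.
#' @param seed recorded for provenance (algorithm itself is deterministic).
#' @return a `ranking_result`.
#' @export
rank_relieff <- function(X, y, n_neighbors = 10L, seed = 1L) {
  rngs <- apply(X, 2, function(v) diff(range(v)))
  rngs[rngs == 0] <- 1
  Xs <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rngs, "/")
  n <- nrow(Xs); p <- ncol(Xs)
  cls <- unique(y)
  k <- n_neighbors
  min_class <- min(table(y))
  if (min_class < k + 1L) {
    k <- max(1L, min_class - 1L)
    warning("reducing ReliefF neighbors to ", k)
  }
  Dm <- as.matrix(dist(Xs))
  diag(Dm) <- Inf
  prior <- table(factor(y, levels = cls)) / n
  W <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(y == y[i])
    hits <- same[order(Dm[i, same])][seq_len(min(k, length(same) - 1L))]
    W <- W - colSums(abs(Xs[hits, , drop = FALSE] -
                           matrix(Xs[i, ], length(hits), p, byrow = TRUE))) /
      (n * length(hits))
    for (c2 in cls[cls != y[i]]) {
      oth <- which(y == c2)
      miss <- oth[order(Dm[i, oth])][seq_len(min(k, length(oth)))]
      wgt <- prior[[as.character(c2)]] / (1 - prior[[as.character(y[i])]])
      W <- W + wgt *
        colSums(abs(Xs[miss, , drop = FALSE] -
                      matrix(Xs[i, ], length(miss), p, byrow = TRUE))) /
        (n * length(miss))
    }
  }
  ranking_result("relieff", W, seed = seed)
}

#' Laplacian-score ranking (unsupervised)
#'
#' Builds a k-nearest-neighbor heat-kernel affinity graph on standardized
#' samples and scores each feature by how well it respects the graph's local
#' structure: `L_r = (f' L f) / (f' D f)` with `f` centered under the degree
#' weighting. Smaller is better; constant features score worst. The score is
#' invariant to feature scaling.
#'
#' @param X feature matrix.
#' @param n_neighbors graph neighbors.
#' @param bandwidth heat-kernel bandwidth `t` (default: mean neighbor
#'   squared distance).
#' @return a `ranking_result` ranked ascending by score.
#' @export
rank_laplacian <- function(X, n_neighbors = 5L, bandwidth = NULL) {
  Xs <- scale(X)
  Xs[is.na(Xs)] <- 0
  n <- nrow(Xs)
  Dm <- as.matrix(dist(Xs))^2
  diag(Dm) <- Inf
  k <- min(n_neighbors, n - 1L)
  nn <- t(apply(Dm, 1, function(d) order(d)[seq_len(k)]))
  t_bw <- bandwidth %||% mean(Dm[cbind(rep(seq_len(n), k), as.vector(nn))])
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, nn[i, ]] <- exp(-Dm[i, nn[i, ]] / t_bw)
  W <- pmax(W, t(W))                       # symmetric kNN graph
  ddeg <- rowSums(W)
  score <- apply(X, 2, function(f) {
    fc <- f - sum(f * ddeg) / sum(ddeg)
    den <- sum(fc^2 * ddeg)
    if (den <= 0) return(Inf)
    (sum(fc^2 * ddeg) - as.numeric(t(fc) %*% W %*% fc)) / den
  })
  ranking_result("laplacian", score, decreasing = FALSE)
}

#' Infinite feature selection (Inf-FS) ranking
#'
#' Builds the feature-feature adjacency
#' `A = mixing * max(sigma_i, sigma_j) + (1 - mixing) * (1 - |rho_ij|)`
#' (standard deviations of min-max scaled features; Spearman correlation)
#' and scores each feature by the row sums of `(I - rA)^{-1} - I`, the
#' closed form of the sum over all weighted paths of every length, with the
#' damping factor set to `r_factor` divided by the spectral radius of `A`.
#'
#' @param X feature matrix.
#' @param mixing weight in `[0, 1]` between dispersion and anti-correlation.
#' @param r_factor fraction of `1/rho(A)` used for the path-damping factor.
#' @return a `ranking_result`.
#' @export
rank_inf_fs <- function(X, mixing = 0.5, r_factor = 0.9) {
  rngs <- apply(X, 2, function(v) diff(range(v)))
  rngs[rngs == 0] <- 1
  Xs <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rngs, "/")
  sig <- apply(Xs, 2, sd)
  rho <- suppressWarnings(cor(Xs, method = "spearman"))
  rho[is.na(rho)] <- 0
  A <- mixing * outer(sig, sig, pmax) + (1 - mixing) * (1 - abs(rho))
  sr <- max(abs(eigen(A, only.values = TRUE)$values))
  r <- if (sr > 0) r_factor / sr else 1
  S <- NULL
  while (is.null(S)) {
    S <- tryCatch(solve(diag(ncol(A)) - r * A) - diag(ncol(A)),
                  error = function(e) NULL)
    if (is.null(S)) { r <- r / 2; warning("reducing Inf-FS damping factor") }
  }
  ranking_result("inf_fs", rowSums(S))
}

#' Feature selection via concave minimization (FSV) ranking
#'
#' Drives a sparse linear separator by successively linearizing the concave
#' exponential suppression penalty `1 - exp(-a |w|)`: each round solves a
#' weighted-l1 logistic fit (via glmnet) with penalty factors proportional
#' to `exp(-a |w|)` from the previous round's weights, so established
#' features are penalized less and the rest are driven to zero. Features are
#' ranked by the final `|w|`; zeroed features fall back to the first-round
#' `|w|`, then index order.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param regularization l1 penalty strength (glmnet lambda).
#' @param alpha_conc concavity parameter `a`.
#' @param n_iter linearization rounds.
#' @return a `ranking_result`.
#' @export
rank_fsv <- function(X, y, regularization = 0.01, alpha_conc = 5,
                     n_iter = 5L) {
  p <- ncol(X)
  if (p < 2L)
    return(structure(list(method = "fsv", order = seq_len(p),
                          scores = rep(1, p), seed = NA_integer_),
                     class = "ranking_result"))
  pf <- rep(1, p)
  w1 <- NULL
  w <- rep(0, p)
  for (it in seq_len(n_iter)) {
    fit <- tryCatch(
      # alpha slightly below 1 keeps the weighted-l1 behavior but makes the
      # objective strictly convex, so duplicated features share weight
      glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                     lambda = regularization, penalty.factor = pf,
                     alpha = 0.95, standardize = TRUE),
      error = function(e) NULL)
    if (is.null(fit)) { warning("FSV fit failed; falling back to l1 fit"); break }
    w <- as.numeric(coef(fit))[-1]
    if (is.null(w1)) w1 <- w
    pf <- exp(-alpha_conc * abs(w))
    pf <- pf / mean(pf)
  }
  if (is.null(w1)) w1 <- w
  ord <- order(-abs(w), -abs(w1), seq_len(p))
  structure(list(method = "fsv", order = ord, scores = abs(w),
                 seed = NA_integer_), class = "ranking_result")
}

#' Approximate l0-norm minimization ranking
#'
#' Multiplicative-update approximation of the zero-norm linear separator:
#' iteratively fit a ridge-regularized linear margin on rescaled features,
#' multiply each feature's scale by its fitted `|w|`, and eliminate features
#' whose scale collapses below tolerance. Features are ranked by survival
#' (last eliminated = best); survivors are ordered by final scale.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param budget stop once at most this many features survive.
#' @param ridge ridge penalty of the inner solve.
#' @param tol elimination tolerance on the normalized scale.
#' @param max_iter iteration cap.
#' @return a `ranking_result` (`scores` = final scales, eliminated = 0).
#' @export
rank_l0 <- function(X, y, budget = 1L, ridge = 1e-2, tol = 1e-6,
                    max_iter = 50L) {
  Xs <- scale(X)
  Xs[is.na(Xs)] <- 0
  p <- ncol(Xs)
  yy <- ifelse(y == 1L, 1, -1)
  z <- rep(1, p)
  active <- seq_len(p)
  eliminated <- integer(0)
  for (it in seq_len(max_iter)) {
    Xa <- sweep(Xs[, active, drop = FALSE], 2, z[active], "*")
    A <- crossprod(Xa) + ridge * nrow(Xa) * diag(length(active))
    w <- solve(A, crossprod(Xa, yy))
    z[active] <- z[active] * abs(as.numeric(w))
    if (max(z[active]) > 0) z[active] <- z[active] / max(z[active])
    drop_now <- active[z[active] < tol]
    # deterministic elimination order: smallest scale first
    drop_now <- drop_now[order(z[drop_now], drop_now)]
    eliminated <- c(eliminated, drop_now)
    active <- setdiff(active, drop_now)
    if (length(active) <= max(1L, budget) || length(drop_now) == 0L && it > 5L)
      break
  }
  survivors <- active[order(-z[active], active)]
  ord <- c(survivors, rev(eliminated))
  scores <- numeric(p)
  scores[active] <- z[active]
  structure(list(method = "l0", order = ord, scores = scores,
                 seed = NA_integer_), class = "ranking_result")
}

#' Rank features with one of the seven selection algorithms
#'
#' Dispatcher over `rf`, `l0`, `inf_fs`, `fsv`, `mrmr`, `relieff`,
#' `laplacian`. Every result is a full permutation of the feature indices,
#' deterministic given `seed`; score ties are broken by ascending index.
#'
#' @param X feature matrix (typically the prefiltered training block).
#' @param y binary labels (`laplacian` and `inf_fs` ignore them).
#' @param method selector name.
#' @param seed RNG seed for the stochastic selectors.
#' @param ... passed to the specific ranker.
#' @return a `ranking_result`.
#' @export
rank_features <- function(X, y, method = c("rf", "l0", "inf_fs", "fsv",
                                           "mrmr", "relieff", "laplacian"),
                          seed = 1L, ...) {
  method <- match.arg(method)
  res <- switch(method,
    rf = rank_rf_importance(X, y, seed = seed, ...),
    l0 = rank_l0(X, y, ...),
    inf_fs = rank_inf_fs(X, ...),
    fsv = rank_fsv(X, y, ...),
    mrmr = rank_mrmr(X, y, ...),
    relieff = rank_relieff(X, y, seed = seed, ...),
    laplacian = rank_laplacian(X, ...))
  res$seed <- seed
  res
}

#' Names of the seven selection algorithms, in registry order
#' @return character vector of length 7.
#' @export
selector_names <- function()
  c("rf", "l0", "inf_fs", "fsv", "mrmr", "relieff", "laplacian")
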