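test_that("the t-test prefilter keeps discriminative features and controls type I error", {
  set.seed(21)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(perfect = y + rnorm(n, sd = 0.01),
             null = rnorm(n),
             flat = rep(1, n))
  keep <- ttest_prefilter(X, y, alpha = 0.05)
  expect_true(1 %in% keep)
  expect_false(3 %in% keep)        # identical means, zero variance
  # single-class input errors; nothing-survives fallback keeps the best
  expect_error(ttest_prefilter(X, rep(1L, n)), "classes")
  keep2 <- ttest_prefilter(matrix(rnorm(40), 20), rep(c(0L, 1L), 10),
                           alpha = 1e-12)
  expect_length(keep2, 1L)
})

test_that("every ranking is a full permutation and is reproducible", {
  tab <- make_informative_table(n = 60, p_info = 2, p_noise = 8, seed = 3)
  for (m in selector_names()) {
    r1 <- rank_features(tab$X, tab$y, m, seed = 11)
    r2 <- rank_features(tab$X, tab$y, m, seed = 11)
    expect_identical(sort(r1$order), seq_len(ncol(tab$X)))
    expect_identical(r1$order, r2$order)
  }
})

test_that("random-forest importance finds planted predictors", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 120
    y <- rep(c(0L, 1L), each = n / 2)
    X <- cbind(signal = y + rnorm(n, sd = 0.3), matrix(rnorm(n * 50), n, 50))
    r <- rank_rf_importance(X, y, n_trees = 300L, seed = s)
    hits <- hits + (r$order[1] == 1L)
  }
  expect_gte(hits, 9L)  # >= 95% expected; allow one failure in 10 seeds
  # all-noise features: importances centered on zero
  set.seed(5)
  Xn <- matrix(rnorm(150 * 30), 150, 30)
  rn <- rank_rf_importance(Xn, rep(c(0L, 1L), length.out = 150), seed = 2)
  se <- sd(rn$scores) / sqrt(length(rn$scores))
  expect_lt(abs(mean(rn$scores)), 2 * se + 1e-3)
})

test_that("mRMR prefers relevance and defers redundant copies", {
  set.seed(8)
  n <- 400
  y <- rep(c(0L, 1L), each = n / 2)
  best <- y + rnorm(n, sd = 0.4)
  X <- cbind(best = best, copy = best + rnorm(n, sd = 0.01),
             weak = y + rnorm(n, sd = 1.5))
  r <- rank_mrmr(X, y, k = 3L)
  expect_equal(r$order[1], 1L)        # max relevance first
  expect_equal(r$order[2], 3L)        # redundant copy deferred
  # k = 1 returns argmax I(f; y) first
  expect_equal(rank_mrmr(X, y, k = 1L)$order[1], 1L)
  # independent feature carries ~ no mutual information
  set.seed(9)
  Xi <- cbind(u = runif(500), v = rnorm(500))
  ri <- rank_mrmr(Xi, rep(c(0L, 1L), 250), k = 2L)
  expect_lt(max(ri$scores), 0.02)
})

test_that("ReliefF rewards label-aligned and interacting features", {
  set.seed(12)
  n <- 300
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(label = as.numeric(y), noise = rnorm(n))
  r <- rank_relieff(X, y, n_neighbors = 10L)
  expect_equal(r$order[1], 1L)
  expect_lt(abs(r$scores[2]), 0.05)
  # XOR pair outranks noise: Relief detects interactions marginal tests miss
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  yx <- as.integer(xor(a, b))
  Xx <- cbind(x1 = a + rnorm(n, sd = 0.05), x2 = b + rnorm(n, sd = 0.05),
              n1 = rnorm(n), n2 = rnorm(n))
  rx <- rank_relieff(Xx, yx, n_neighbors = 10L)
  expect_true(all(c(1L, 2L) %in% rx$order[1:2]))
  # neighbor reduction warning for small classes
  expect_warning(rank_relieff(X[c(1:3, 151:153), ], y[c(1:3, 151:153)],
                              n_neighbors = 10L), "neighbors")
})

test_that("the Laplacian score prefers locality-preserving features", {
  set.seed(14)
  n <- 100
  cluster <- rep(c(0, 1), each = n / 2)
  X <- cbind(smooth = cluster * 4 + rnorm(n, sd = 0.3), noise = rnorm(n))
  r <- rank_laplacian(X)
  expect_equal(r$order[1], 1L)
  expect_gt(r$scores[2], r$scores[1])
  # scale invariance of the score
  Xs <- X; Xs[, 1] <- X[, 1] * 100
  expect_equal(rank_laplacian(Xs)$scores, r$scores, tolerance = 1e-9)
})

test_that("Inf-FS matches its geometric-series closed form and symmetry", {
  set.seed(15)
  X <- matrix(rnorm(50 * 6), 50, 6)
  X[, 2] <- X[, 1]                     # perfectly correlated pair
  r <- rank_inf_fs(X, mixing = 0.5)
  expect_equal(r$scores[1], r$scores[2], tolerance = 1e-9)
  expect_identical(rank_inf_fs(matrix(rnorm(20), 20, 1))$order, 1L)

  # independent oracle: truncated path series vs the matrix-inverse energy
  rngs <- apply(X, 2, function(v) diff(range(v)))
  Xs <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rngs, "/")
  sig <- apply(Xs, 2, sd)
  rho <- cor(Xs, method = "spearman")
  A <- 0.5 * outer(sig, sig, pmax) + 0.5 * (1 - abs(rho))
  rr <- 0.5 / max(abs(eigen(A, only.values = TRUE)$values))
  S_series <- matrix(0, 6, 6); P <- diag(6)
  for (l in 1:100) { P <- P %*% (rr * A); S_series <- S_series + P }
  S_inv <- solve(diag(6) - rr * A) - diag(6)
  expect_lt(max(abs(S_series - S_inv)) / max(abs(S_inv)), 1e-6)
})

test_that("FSV drives irrelevant weights to zero, monotonically in the penalty", {
  set.seed(16)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(sep = ifelse(y == 1, 1, -1) + rnorm(n, sd = 0.05),
             junk = rnorm(n))
  r <- rank_fsv(X, y, regularization = 0.05)
  expect_equal(r$order[1], 1L)
  expect_lt(abs(r$scores[2]) / abs(r$scores[1]), 0.01)
  # stronger regularization never keeps more features
  nkeep <- function(lam) sum(rank_fsv(X, y, regularization = lam)$scores > 1e-8)
  expect_lte(nkeep(0.2), nkeep(0.01))
  # symmetric duplicates get equal weight in the convex base fit (the
  # concave refinement deliberately concentrates weight on one of them)
  Xd <- cbind(a = X[, 1], b = X[, 1])
  rd <- rank_fsv(Xd, y, regularization = 0.05, n_iter = 1L)
  expect_equal(rd$scores[1], rd$scores[2], tolerance = 0.05)
})

test_that("l0 elimination keeps predictive features and drops dead columns first", {
  surv <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 150
    y <- rep(c(0L, 1L), each = n / 2)
    X <- cbind(signal = ifelse(y == 1, 1, -1) + rnorm(n, sd = 0.3),
               matrix(rnorm(n * 20), n, 20))
    r <- rank_l0(X, y)
    surv <- surv + (r$order[1] == 1L)
  }
  expect_gte(surv, 9L)
  # an all-zero column is eliminated first (ranked last)
  set.seed(3)
  X0 <- cbind(matrix(rnorm(60 * 3), 60, 3), dead = rep(0, 60))
  r0 <- rank_l0(X0, rep(c(0L, 1L), 30))
  expect_equal(r0$order[4], 4L)
  expect_equal(r0$scores[4], 0)
})
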