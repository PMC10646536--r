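test_that("PLS recovers an exact linear relation with one predictor", {
  set.seed(1)
  x <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "x1"))
  y <- 3 * x[, 1]
  fit <- fit_pls(x, y, 1)
  expect_lt(max(abs(predict(fit, x) - y)), 1e-10)
  expect_equal(unname(vip_scores(fit)), 1)  # p = 1 forces VIP = 1
})

test_that("PLS at full rank reproduces OLS predictions", {
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(10:30, 1); p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n)
    colnames(X) <- paste0("x", 1:p)
    y <- rnorm(n)
    fit <- fit_pls(X, y, p)
    ols <- lm(y ~ X)
    expect_lt(max(abs(predict(fit, X) - fitted(ols))), 1e-8)
  }
})

test_that("a duplicated column does not change full-rank predictions", {
  set.seed(3)
  X <- matrix(rnorm(30 * 4), 30)
  colnames(X) <- paste0("x", 1:4)
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(30, 0, 0.2)
  Xdup <- cbind(X, x2dup = X[, 2])
  p1 <- predict(fit_pls(X, y, 4), X)
  p2 <- predict(fit_pls(Xdup, y, 4), Xdup)
  expect_lt(max(abs(p1 - p2)), 1e-8)
})

test_that("the VIP normalization identity holds for arbitrary fits", {
  set.seed(4)
  for (rep in 1:10) {
    n <- 40; p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n)
    y <- X %*% rnorm(p) + rnorm(n)
    A <- sample(seq_len(min(3, p)), 1)
    vip <- vip_scores(fit_pls(X, y, A))
    expect_equal(mean(vip^2), 1, tolerance = 1e-10)
    expect_true(all(vip >= 0))
  }
})

test_that("VIP singles out the informative marker", {
  set.seed(5)
  hits <- 0
  for (rep in 1:20) {
    X <- matrix(rnorm(300 * 10), 300)
    colnames(X) <- paste0("x", 1:10)
    y <- 2 * X[, 1] + rnorm(300, 0, 0.5)
    vip <- vip_scores(fit_pls(X, y, 2))
    hits <- hits + (names(which.max(vip)) == "x1")
  }
  expect_gte(hits / 20, 0.95)
})

test_that("ranking falls back to lexicographic order for a constant outcome", {
  X <- matrix(rnorm(60), 20, dimnames = list(NULL, c("b", "c", "a")))
  panel <- rank_variables(X, rep(2.5, 20))
  expect_equal(panel$marker, c("a", "b", "c"))
  expect_equal(panel$score, rep(1, 3))
})

test_that("ranking is invariant to affine rescaling of a column", {
  set.seed(6)
  X <- matrix(rnorm(80 * 5), 80)
  colnames(X) <- paste0("x", 1:5)
  y <- X[, 2] - X[, 4] + rnorm(80, 0, 0.5)
  p1 <- rank_variables(X, y, ncomp = 2)
  X2 <- X
  X2[, 2] <- 1000 * X2[, 2] + 7  # affine rescale; standardization undoes it
  p2 <- rank_variables(X2, y, ncomp = 2)
  expect_equal(p1$marker, p2$marker)
  expect_equal(p1$score, p2$score, tolerance = 1e-8)
})

test_that("zero-variance columns are rejected by name", {
  X <- cbind(x1 = rnorm(10), dead = rep(1, 10))
  expect_error(fit_pls(X, rnorm(10), 1), "dead")
})

test_that("merging disjoint top-k sets yields a permutation of the union", {
  set.seed(7)
  X <- matrix(rnorm(100 * 10), 100)
  colnames(X) <- paste0("x", 1:10)
  y <- X %*% runif(10, -1, 1) + rnorm(100)
  full <- rank_variables(X[, 1:5], y, ncomp = 2)
  expert <- rank_variables(X[, 6:10], y, ncomp = 2)
  merged <- merge_and_rerank(full, expert, X, y, k_full = 5, k_expert = 5,
                             m = 10, ncomp = 2)
  expect_setequal(merged$marker, colnames(X))
  expect_true(all(diff(merged$score) <= 1e-12))  # scores non-increasing
  expect_error(
    merge_and_rerank(full, expert, X, y, k_full = 5, k_expert = 5, m = 11,
                     ncomp = 2),
    "exceeds")
})

test_that("an informative expert-only marker survives the merge", {
  set.seed(8)
  survived <- 0
  for (rep in 1:10) {
    X <- matrix(rnorm(150 * 8), 150)
    colnames(X) <- paste0("x", 1:8)
    y <- 2 * X[, 8] + rnorm(150, 0, 1)   # x8 lives only in the expert set
    full <- rank_variables(X[, 1:6], y, ncomp = 1)
    expert <- rank_variables(X[, 7:8], y, ncomp = 1)
    merged <- merge_and_rerank(full, expert, X, y, k_full = 3, k_expert = 2,
                               m = 3, ncomp = 1)
    survived <- survived + ("x8" %in% merged$marker)
  }
  expect_gte(survived / 10, 0.9)
})
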