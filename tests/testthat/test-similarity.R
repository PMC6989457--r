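test_that("pearson correlation matches the direct-formula oracle", {
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(2, 4, 5, 9)),
               oracle_pearson(c(1, 2, 3, 4), c(2, 4, 5, 9)),
               tolerance = 1e-12)
  v <- c(0.2, -1, 3, 7, 0)
  expect_equal(pearson_cor(v, v), 1)
  expect_equal(pearson_cor(v, -v), -1)
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(pearson_cor(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
  expect_error(pearson_cor(1:3, 1:4), "equal length")
  expect_warning(r <- pearson_cor(rep(1, 5), rnorm(5)), "constant")
  expect_equal(r, 0)
  expect_error(pearson_cor(rep(1, 5), rnorm(5), on_constant = "error"),
               class = "foveanet_undefined_correlation")
})

test_that("symmetric similarity is exactly order-invariant and calibrated", {
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30)
  expect_identical(symmetric_similarity(a, b), symmetric_similarity(b, a))
  expect_equal(symmetric_similarity(a, a), 1)
  # independent random features: small correlation, near-zero mean
  rs <- replicate(300, symmetric_similarity(rnorm(50), rnorm(50)))
  expect_lt(abs(mean(rs)), 0.03)
  expect_lt(max(abs(rs)), 0.7)
})

test_that("asymmetric similarity selects the best stored channel", {
  set.seed(5)
  test <- rnorm(20)
  bank <- cbind(rnorm(20), test, rnorm(20))
  r <- asymmetric_similarity(bank, test, include_pooled = FALSE)
  expect_equal(r$similarity, 1)
  expect_equal(r$channel, 2L)
  # brute-force enumeration oracle on random 3-channel banks
  for (i in 1:20) {
    bank <- matrix(rnorm(60), 20, 3)
    tv <- rnorm(20)
    got <- asymmetric_similarity(bank, tv, include_pooled = FALSE)
    want <- oracle_best_channel(bank, tv)
    expect_equal(got$similarity, want$similarity, tolerance = 1e-12)
    expect_equal(got$channel, want$channel)
  }
})

test_that("asymmetric similarity reduces to symmetric for single channels", {
  set.seed(6)
  a <- rnorm(15); b <- rnorm(15)
  r <- asymmetric_similarity(matrix(a, ncol = 1), b)
  expect_equal(r$similarity, symmetric_similarity(a, b), tolerance = 1e-12)
  expect_equal(r$channel, 1L)
})

test_that("asymmetric similarity is not symmetric in presentation order", {
  set.seed(9)
  fa <- list(bank = matrix(rnorm(40), 20, 2))
  fa$pooled <- pmax(fa$bank[, 1], fa$bank[, 2])
  fb <- list(bank = matrix(rnorm(40), 20, 2))
  fb$pooled <- pmax(fb$bank[, 1], fb$bank[, 2])
  ab <- asymmetric_similarity(fa, fb)$similarity
  ba <- asymmetric_similarity(fb, fa)$similarity
  expect_false(isTRUE(all.equal(ab, ba)))
})

test_that("the stored pooled template makes identical presentations score 1", {
  set.seed(10)
  bank <- matrix(abs(rnorm(60)), 20, 3)
  pooled <- apply(bank, 1, max)
  f <- list(bank = bank, pooled = pooled)
  r <- asymmetric_similarity(f, pooled)
  expect_equal(r$similarity, 1)
  expect_equal(r$channel, 0L)
})

test_that("all-constant banks raise an undefined-correlation error", {
  bank <- matrix(1, 10, 3)
  expect_error(suppressWarnings(
    asymmetric_similarity(bank, rnorm(10), include_pooled = FALSE)),
    class = "foveanet_undefined_correlation")
})

test_that("optimal threshold handles separable, tied, and identical inputs", {
  r <- optimal_threshold(c(0.9, 0.8), c(0.3, 0.4))
  expect_equal(r$accuracy, 1)
  expect_gt(r$threshold, 0.4)
  expect_lt(r$threshold, 0.8)
  expect_equal(r$hit_rate, 1)
  expect_equal(r$fa_rate, 0)
  # a perfect tie: one of the two trials must be misclassified
  r2 <- optimal_threshold(0.6, 0.6)
  expect_equal(r2$accuracy, 0.5)
  # identical distributions cannot beat the brute-force bound
  s <- c(0.1, 0.5, 0.9)
  r3 <- optimal_threshold(s, s)
  expect_equal(r3$accuracy, oracle_threshold_accuracy(s, s))
  expect_error(optimal_threshold(numeric(0), 1), "non-empty")
})

test_that("optimal threshold equals the brute-force scan on random draws", {
  set.seed(123)
  for (i in 1:100) {
    ns <- sample(1:20, 1); nd <- sample(1:20, 1)
    same <- round(runif(ns, -1, 1), sample(c(1, 2, 7), 1))
    diff <- round(runif(nd, -1, 1), sample(c(1, 2, 7), 1))
    r <- optimal_threshold(same, diff)
    expect_equal(r$accuracy, oracle_threshold_accuracy(same, diff))
    # reported rates are consistent with the reported threshold
    expect_equal(r$accuracy,
                 (sum(same > r$threshold) + sum(diff <= r$threshold)) /
                   (ns + nd))
  }
})

test_that("d-prime follows standard-normal quantiles with edge correction", {
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(0.69146, 0.30854), 1.0, tolerance = 1e-4)
  for (r in c(0.2, 0.35, 0.77)) expect_equal(dprime(r, r), 0)
  # log-linear correction only engages at 0/1 and needs counts
  expect_equal(dprime(1, 0, n_same = 27, n_diff = 27),
               qnorm(27.5 / 28) - qnorm(0.5 / 28))
  expect_equal(dprime(0.75, 0.25), dprime(0.75, 0.25, 10, 10))
  expect_error(dprime(1, 0.2), "count")
})

test_that("global-threshold rescoring is consistent with the decision rule", {
  pairs <- make_novel_pairs(4, seed = 61)
  model <- new_model(tiny_enn_config())
  r <- run_condition(condition_spec(30), pairs, model, tiny_calib())
  g <- rescore_at_threshold(r, 0.5)
  expect_equal(g$threshold, 0.5)
  expect_equal(g$accuracy,
               (sum(r$similarities_same > 0.5) +
                  sum(r$similarities_diff <= 0.5)) / r$n_trials)
  expect_lte(g$accuracy, r$accuracy)   # optimum dominates any fixed threshold
  # rescoring at the optimal threshold reproduces the optimal accuracy
  expect_equal(rescore_at_threshold(r, r$threshold)$accuracy, r$accuracy)
})
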