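# independent one-way random-effects ICC oracle via stats::aov
icc_aov_oracle <- function(d1, d2) {
  vals <- c(d1, d2)
  subj <- factor(rep(seq_along(d1), 2))
  ms <- summary(stats::aov(vals ~ subj))[[1]]$`Mean Sq`
  (ms[1] - ms[2]) / (ms[1] + ms[2]) # k = 2
}

fm <- function(m, id = "d") feature_matrix(m, dataset_id = id)

test_that("ICC is 1 for perfectly repeated measurements", {
  x <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), ncol = 2)
  expect_equal(unname(feature_icc(fm(x), fm(x))), c(1, 1), tolerance = 1e-12)
})

test_that("ICC matches the ANOVA oracle on hand and random instances", {
  # anti-correlated hand instance
  f1 <- fm(matrix(c(1, 2, 3), ncol = 1))
  f2 <- fm(matrix(c(3, 2, 1), ncol = 1))
  expect_equal(unname(feature_icc(f1, f2)),
               icc_aov_oracle(c(1, 2, 3), c(3, 2, 1)), tolerance = 1e-10)
  # random 10-subject instances, several features
  withr::with_seed(41, {
    x1 <- matrix(rnorm(10 * 6), 10, 6)
    x2 <- matrix(rnorm(10 * 6), 10, 6)
  })
  icc <- feature_icc(fm(x1), fm(x2))
  for (e in 1:6) {
    expect_equal(unname(icc[e]), icc_aov_oracle(x1[, e], x2[, e]),
                 tolerance = 1e-10)
  }
})

test_that("ICC under the null centers on zero and flags degenerate features", {
  withr::with_seed(42, {
    x1 <- matrix(rnorm(200 * 50), 200, 50)
    x2 <- matrix(rnorm(200 * 50), 200, 50)
  })
  icc <- feature_icc(fm(x1), fm(x2))
  # null ICC has mean ~ -1/(2n - 1) ~ 0; SE over 50 features ~ 1/sqrt(50 n)
  expect_lt(abs(mean(icc)), 3 * 1 / sqrt(50 * 200) + 1 / (2 * 200 - 1))
  # constant feature -> NA
  x1c <- x1; x2c <- x2
  x1c[, 1] <- 5; x2c[, 1] <- 5
  expect_true(is.na(feature_icc(fm(x1c), fm(x2c))[1]))
})

test_that("ICC is invariant under a common affine transform", {
  withr::with_seed(43, {
    x1 <- matrix(rnorm(12 * 3), 12, 3)
    x2 <- x1 + matrix(rnorm(12 * 3, sd = 0.4), 12, 3)
  })
  base <- feature_icc(fm(x1), fm(x2))
  trans <- feature_icc(fm(3 * x1 - 7), fm(3 * x2 - 7))
  expect_equal(base, trans, tolerance = 1e-10)
})

test_that("group consistency equals the brute-force per-edge definition", {
  withr::with_seed(44, {
    x1 <- matrix(rnorm(3 * 5), 3, 5)
    x2 <- matrix(rnorm(3 * 5), 3, 5)
  })
  gc <- group_consistency(fm(x1), fm(x2))
  for (e in 1:5) {
    acc <- 0
    for (i in 1:3) {
      acc <- acc + (x1[i, e] / sqrt(sum(x1[i, ]^2))) *
        (x2[i, e] / sqrt(sum(x2[i, ]^2)))
    }
    expect_equal(unname(gc[e]), acc / 3, tolerance = 1e-12)
  }
  # a feature dominant for every subject maximizes consistency
  dom <- matrix(0.1, 4, 6); dom[, 3] <- 5
  gdom <- group_consistency(fm(dom), fm(dom + 0.01))
  expect_equal(unname(which.max(gdom)), 3L)
})

test_that("differential power equals an exhaustive double loop", {
  withr::with_seed(45, {
    x1 <- matrix(rnorm(3 * 4), 3, 4)
    x2 <- matrix(rnorm(3 * 4), 3, 4)
  })
  dp <- differential_power(fm(x1), fm(x2))
  p1 <- x1 / sqrt(rowSums(x1^2))
  p2 <- x2 / sqrt(rowSums(x2^2))
  n <- 3
  for (e in 1:4) {
    total <- 0
    for (i in 1:n) {
      cnt <- 0
      for (j in setdiff(1:n, i)) {
        if (p1[i, e] * p2[j, e] > p1[i, e] * p2[i, e] ||
            p1[j, e] * p2[i, e] > p1[i, e] * p2[i, e]) {
          cnt <- cnt + 1
        }
      }
      total <- total - log(max(cnt / (n - 1), 1 / (2 * (n - 1))))
    }
    expect_equal(unname(dp[e]), total, tolerance = 1e-12)
  }
})

test_that("differential power separates discriminative from exchangeable features", {
  withr::with_seed(46, {
    n <- 12
    # feature 1: strong stable subject differences; feature 2: exchangeable
    subj <- rnorm(n, sd = 3)
    x1 <- cbind(subj + rnorm(n, sd = 0.1), rnorm(n))
    x2 <- cbind(subj + rnorm(n, sd = 0.1), rnorm(n))
    # pad with neutral features so normalization is not degenerate
    x1 <- cbind(x1, matrix(rnorm(n * 4), n, 4))
    x2 <- cbind(x2, matrix(rnorm(n * 4), n, 4))
  })
  dp <- differential_power(fm(x1), fm(x2))
  # permutation oracle: null level for the exchangeable feature
  null_dp <- withr::with_seed(460, replicate(20, {
    perm <- sample(n)
    differential_power(fm(x1), fm(x2[perm, ]))[2]
  }))
  expect_gt(unname(dp[1]), unname(dp[2]))
  expect_lt(abs(unname(dp[2]) - mean(null_dp)),
            4 * stats::sd(null_dp) + 1e-9)
})

test_that("feature_reliability assembles the three metrics per feature", {
  withr::with_seed(47, {
    x1 <- matrix(rnorm(6 * 4), 6, 4)
    x2 <- matrix(rnorm(6 * 4), 6, 4)
  })
  rel <- feature_reliability(fm(x1), fm(x2))
  expect_named(rel, c("feature", "icc", "group_consistency",
                      "differential_power"))
  expect_equal(nrow(rel), 4)
  expect_false(anyNA(rel$icc))
})
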