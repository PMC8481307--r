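test_that("PLS of a block with itself is a perfect single LV", {
  withr::with_seed(51, x <- matrix(rnorm(30), ncol = 1))
  fit <- pls_fit(x, x)
  expect_equal(fit$singular_values[1], 1, tolerance = 1e-12) # correlation scale
  expect_equal(abs(fit$demographic_saliences[1, 1]), 1, tolerance = 1e-12)
  expect_equal(abs(fit$neural_saliences[1, 1]), 1, tolerance = 1e-12)
})

test_that("squared singular values sum to the cross-block Frobenius norm", {
  withr::with_seed(52, {
    x <- matrix(rnorm(40 * 3), 40, 3)
    y <- matrix(rnorm(40 * 7), 40, 7)
  })
  fit <- pls_fit(x, y)
  r <- crossprod(scale(x), scale(y)) / 39
  expect_equal(sum(fit$singular_values^2), sum(r^2), tolerance = 1e-10)
  # saliences are column-orthonormal per block
  expect_equal(crossprod(fit$demographic_saliences), diag(3),
               tolerance = 1e-10)
  expect_equal(crossprod(fit$neural_saliences), diag(3), tolerance = 1e-10)
})

test_that("2x2 toy decomposition matches the closed-form SVD", {
  withr::with_seed(53, {
    x <- matrix(rnorm(10), 5, 2)
    y <- matrix(rnorm(10), 5, 2)
  })
  fit <- pls_fit(x, y)
  r <- crossprod(scale(x), scale(y)) / 4
  # closed-form singular values of a 2x2 matrix
  g <- sqrt((r[1, 1]^2 + r[1, 2]^2 + r[2, 1]^2 + r[2, 2]^2)^2 -
              4 * (r[1, 1] * r[2, 2] - r[1, 2] * r[2, 1])^2)
  s2 <- (sum(r^2) + c(g, -g)) / 2
  expect_equal(fit$singular_values, sqrt(s2), tolerance = 1e-10)
})

test_that("constant columns are rejected by name", {
  x <- cbind(a = rnorm(10), b = rep(2, 10))
  y <- matrix(rnorm(20), 10, 2)
  expect_error(pls_fit(x, y), "b")
})

test_that("permutation p-values are reproducible, bounded away from zero", {
  withr::with_seed(54, {
    x <- matrix(rnorm(30 * 2), 30, 2)
    y <- matrix(rnorm(30 * 5), 30, 5)
  })
  fit <- pls_fit(x, y)
  p1 <- pls_permutation(fit, n_perm = 200, seed = 9)$p_perm
  p2 <- pls_permutation(fit, n_perm = 200, seed = 9)$p_perm
  expect_identical(p1, p2)
  expect_true(all(p1 >= 1 / 201))
  expect_true(all(p1 <= 1))
  p3 <- pls_permutation(fit, n_perm = 200, seed = 10)$p_perm
  expect_false(identical(p1, p3))
})

test_that("a strong planted coupling is detected by the permutation test", {
  withr::with_seed(55, {
    n <- 60
    latent <- rnorm(n)
    x <- cbind(latent + 0.3 * rnorm(n), rnorm(n))
    y <- cbind(latent + 0.3 * rnorm(n), matrix(rnorm(n * 5), n, 5))
  })
  fit <- pls_permutation(pls_fit(x, y), n_perm = 200, seed = 1)
  expect_lte(fit$p_perm[1], 0.01)
})

test_that("bootstrap aligns LVs and flags degenerate zero-noise ratios", {
  withr::with_seed(56, {
    n <- 40
    latent <- rnorm(n)
    x <- cbind(latent + 0.2 * rnorm(n), rnorm(n))
    y <- cbind(latent + 0.2 * rnorm(n), matrix(rnorm(n * 3), n, 3))
  })
  fit <- pls_bootstrap(pls_fit(x, y), n_boot = 200, seed = 2)
  expect_identical(dim(fit$bootstrap_ratio), dim(fit$neural_saliences))
  expect_identical(dim(fit$ci95)[1:2], dim(fit$demographic_saliences))
  # the planted feature has the dominant bootstrap ratio on LV1
  expect_equal(which.max(abs(fit$bootstrap_ratio[, 1])), 1L)
  expect_true(all(fit$ci95[, , "lo"] <= fit$ci95[, , "hi"]))
  # deterministic x<->y link: SE collapses, ratio capped and flagged
  z <- matrix(rnorm(20), ncol = 1)
  dfit <- pls_bootstrap(pls_fit(z, z), n_boot = 100, seed = 3)
  expect_true(all(dfit$ratio_capped))
})

test_that("demographics encoding centers binary codes and keeps numerics", {
  demo <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
                         age = c(20, 30, 40, 50),
                         sex = c(0L, 1L, 0L, 1L),
                         group = c("pat", "ctl", "ctl", "pat"))
  m <- encode_demographics(demo)
  expect_identical(colnames(m), c("age", "sex", "group"))
  expect_equal(sort(unique(m[, "group"])), c(-0.5, 0.5))
  expect_identical(m[, "age"], demo$age)
  demo$bad <- c("x", "y", "z", "x")
  expect_error(encode_demographics(dplyr::mutate(demo, bad = c("x", "y", "z", "w"))),
               "binary")
})
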