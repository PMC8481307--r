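toy_sim <- function(a, ids = NULL) {
  structure(
    list(A = a, subject_ids = ids %||% sprintf("s%02d", seq_len(nrow(a))),
         dataset_pair = c("d1", "d2")),
    class = "similarity_matrix")
}

test_that("similarity equals entry-by-entry hand correlation", {
  withr::with_seed(21, {
    x1 <- matrix(rnorm(12), 3, 4)
    x2 <- matrix(rnorm(12), 3, 4)
  })
  f1 <- feature_matrix(x1, dataset_id = "d1")
  f2 <- feature_matrix(x2, dataset_id = "d2")
  s <- similarity(f1, f2)
  for (i in 1:3) {
    for (j in 1:3) {
      expect_equal(s$A[i, j], pearson_oracle(x1[i, ], x2[j, ]),
                   tolerance = 1e-12)
    }
  }
  # same dataset twice: symmetric, unit diagonal
  ss <- similarity(f1, f1)
  expect_equal(ss$A, t(ss$A), tolerance = 1e-12)
  expect_equal(diag(ss$A), rep(1, 3), tolerance = 1e-12)
})

test_that("zero-variance feature rows become NA with a warning", {
  f1 <- feature_matrix(rbind(c(1, 2, 3), c(5, 5, 5)))
  f2 <- feature_matrix(rbind(c(2, 1, 3), c(1, 2, 4)))
  expect_warning(s <- similarity(f1, f2), "zero feature variance")
  expect_true(all(is.na(s$A[2, ])))
  expect_false(anyNA(s$A[1, ]))
})

test_that("identification follows the argmax rule in both directions", {
  r1 <- identify_subjects(toy_sim(matrix(c(0.9, 0.2, 0.3, 0.8), 2, byrow = TRUE)))
  expect_true(all(r1$correct))
  expect_equal(attr(r1, "accuracy"), 1)
  r0 <- identify_subjects(toy_sim(matrix(c(0.2, 0.9, 0.8, 0.3), 2, byrow = TRUE)))
  expect_false(any(r0$correct))
  expect_equal(attr(r0, "accuracy"), 0)
  # columns direction transposes the lookup
  a <- matrix(c(0.9, 0.8, 0.1, 0.5), 2, byrow = TRUE)
  rows <- identify_subjects(toy_sim(a), "rows")
  cols <- identify_subjects(toy_sim(a), "columns")
  expect_equal(attr(rows, "accuracy"), 1)   # argmax rows: 1->1, 2->2
  expect_equal(attr(cols, "accuracy"), 0.5) # column 2's max is row 1
})

test_that("ties break to the lowest index and are counted", {
  a <- matrix(c(0.5, 0.5, 0.2, 0.7), 2, byrow = TRUE)
  r <- identify_subjects(toy_sim(a))
  expect_equal(r$predicted_id[1], "s01")
  expect_true(r$tied[1])
  expect_equal(attr(r, "n_ties"), 1L)
})

test_that("all-missing probe rows are unidentifiable, not wrong", {
  a <- matrix(c(NA, NA, NA, 0.1, 0.9, 0.2, 0.3, 0.2, 0.8), 3, byrow = TRUE)
  r <- identify_subjects(toy_sim(a))
  expect_true(is.na(r$correct[1]))
  expect_equal(attr(r, "n_identifiable"), 2L)
  expect_equal(attr(r, "accuracy"), 1) # 2 of 2 identifiable correct
})

test_that("identify agrees with an exhaustive probe-vs-candidate loop", {
  for (seed in 1:25) {
    withr::with_seed(seed, a <- matrix(runif(25, -1, 1), 5, 5))
    r <- identify_subjects(toy_sim(a))
    brute <- vapply(1:5, function(i) {
      best <- 1L
      for (j in 2:5) if (a[i, j] > a[i, best]) best <- j
      as.integer(best)
    }, integer(1))
    expect_identical(r$predicted_id, sprintf("s%02d", brute))
  }
})

test_that("accuracy is invariant under a common subject permutation", {
  withr::with_seed(31, {
    x1 <- matrix(rnorm(60), 6, 10)
    x2 <- x1 + matrix(rnorm(60, sd = 0.5), 6, 10)
    perm <- sample(6)
  })
  acc <- function(m1, m2) {
    attr(identify_subjects(similarity(feature_matrix(m1), feature_matrix(m2))),
         "accuracy")
  }
  expect_equal(acc(x1, x2), acc(x1[perm, ], x2[perm, ]))
})

test_that("separated diagonal guarantees perfect accuracy in both directions", {
  withr::with_seed(32, a <- matrix(runif(49, -0.4, 0.4), 7, 7))
  diag(a) <- 0.9 # min diagonal > max off-diagonal
  for (dir in c("rows", "columns")) {
    expect_equal(attr(identify_subjects(toy_sim(a), dir), "accuracy"), 1)
  }
})

test_that("differentiability matches the worked z-score example", {
  a <- matrix(0, 4, 4)
  a[1, ] <- c(0.9, 0.5, 0.6, 0.4)
  a[2, ] <- c(0.1, 0.3, 0.1, 0.2)
  a[3, ] <- c(0.2, 0.1, 0.5, 0.3)
  a[4, ] <- c(0.3, 0.2, 0.1, 0.6)
  d <- differentiability(toy_sim(a))
  # row 1: self 0.9, others {0.5, 0.6, 0.4}: mu 0.5, sample sd 0.1 -> z = 4
  expect_equal(d$d_self[1], 4, tolerance = 1e-12)
  expect_equal(d$mu_others[1], 0.5, tolerance = 1e-12)
  expect_equal(d$sigma_others[1], 0.1, tolerance = 1e-12)
})

test_that("D_self is zero when self equals the off-diagonal level and is affine-stable", {
  a <- matrix(0.3, 5, 5)
  a[1, 2:5] <- c(0.2, 0.4, 0.25, 0.35)
  a[1, 1] <- mean(a[1, 2:5])
  d <- differentiability(toy_sim(a))
  expect_equal(d$d_self[1], 0, tolerance = 1e-12)

  withr::with_seed(33, a2 <- matrix(runif(36), 6, 6))
  d0 <- differentiability(toy_sim(a2))$d_self
  a_shift <- a2
  a_shift[2, ] <- a2[2, ] + 0.07 # additive shift of one row
  expect_equal(differentiability(toy_sim(a_shift))$d_self[2], d0[2],
               tolerance = 1e-10)
  a_scale <- a2
  a_scale[3, ] <- 0.2 + 3 * a2[3, ] # affine row transform preserves z
  expect_equal(differentiability(toy_sim(a_scale))$d_self[3], d0[3],
               tolerance = 1e-10)
})

test_that("inclusive-null variant includes the diagonal term", {
  a <- matrix(c(0.9, 0.5, 0.6, 0.4,
                0.5, 0.8, 0.3, 0.2,
                0.1, 0.2, 0.7, 0.3,
                0.2, 0.1, 0.3, 0.9), 4, 4, byrow = TRUE)
  d_ex <- differentiability(toy_sim(a))
  d_in <- differentiability(toy_sim(a), include_self_in_null = TRUE)
  expect_equal(d_in$mu_others[1], mean(a[1, ]), tolerance = 1e-12)
  expect_gt(d_ex$d_self[1], d_in$d_self[1])
})
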