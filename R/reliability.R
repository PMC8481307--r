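#' Per-feature intraclass correlation across two datasets
#'
#' One-way random-effects, single-rater ICC (ICC(1,1)) per feature, treating
#' subjects as targets and the two datasets as repeated measurements:
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)` with `k = 2`, from the one-way
#' ANOVA decomposition. Features with zero total variance get `NA`.
#'
#' @param f1,f2 [feature_matrix()] objects over the same subjects.
#' @return Numeric vector of ICCs, one per feature (named).
#' @export
feature_icc <- function(f1, f2) {
  check_matched(f1, f2)
  x1 <- f1$values
  x2 <- f2$values
  n <- nrow(x1)
  if (n < 3) abort("ICC needs at least 3 subjects.")
  k <- 2
  m <- (x1 + x2) / 2                     # subject means, n x p
  grand <- colMeans(m)
  ssb <- k * colSums(sweep(m, 2, grand)^2)
  ssw <- colSums((x1 - m)^2) + colSums((x2 - m)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  tot <- colSums(sweep(x1, 2, (colMeans(x1) + colMeans(x2)) / 2)^2) +
    colSums(sweep(x2, 2, (colMeans(x1) + colMeans(x2)) / 2)^2)
  icc[tot == 0 | !is.finite(icc)] <- NA_real_
  stats::setNames(icc, f1$feature_labels)
}

#' Group consistency of each feature
#'
#' Each subject's feature vector in each dataset is normalized to unit
#' Euclidean norm; a feature's group consistency is the cohort mean of the
#' product of its two normalized values,
#' `Phi(e) = mean_i phi1_i(e) * phi2_i(e)`. High values mark features that
#' are strong and stable across the whole cohort.
#'
#' @inheritParams feature_icc
#' @return Named numeric vector, one value per feature.
#' @export
group_consistency <- function(f1, f2) {
  check_matched(f1, f2)
  nrm <- unit_norm_rows(f1$values, f2$values)
  stats::setNames(colMeans(nrm$x1 * nrm$x2), f1$feature_labels)
}

#' Differential power of each feature
#'
#' With unit-norm feature vectors as in [group_consistency()], feature `e`'s
#' differential power is `DP(e) = sum_i -ln P_i(e)` where `P_i(e)` is the
#' empirical probability over all `j != i` that a cross-subject product
#' `phi1_i(e) phi2_j(e)` or `phi1_j(e) phi2_i(e)` exceeds the within-subject
#' product `phi1_i(e) phi2_i(e)`. `P` is clipped below at `1 / (2 (N - 1))`
#' so the logarithm stays finite. Large DP marks features whose within-
#' subject expression beats cross-subject matches for most of the cohort.
#'
#' @inheritParams feature_icc
#' @return Named numeric vector, one value per feature.
#' @export
differential_power <- function(f1, f2) {
  check_matched(f1, f2)
  nrm <- unit_norm_rows(f1$values, f2$values)
  x1 <- nrm$x1
  x2 <- nrm$x2
  n <- nrow(x1)
  if (n < 3) abort("Differential power needs at least 3 subjects.")
  p <- ncol(x1)
  within <- x1 * x2
  pmat <- matrix(0, n, p)
  for (i in seq_len(n)) {
    wi <- matrix(within[i, ], n, p, byrow = TRUE)
    m1 <- x2 * matrix(x1[i, ], n, p, byrow = TRUE) # phi1_i(e) phi2_j(e)
    m2 <- x1 * matrix(x2[i, ], n, p, byrow = TRUE) # phi1_j(e) phi2_i(e)
    cond <- (m1 > wi) | (m2 > wi)
    cond[i, ] <- FALSE
    pmat[i, ] <- colSums(cond) / (n - 1)
  }
  pmat <- pmax(pmat, 1 / (2 * (n - 1)))
  stats::setNames(colSums(-log(pmat)), f1$feature_labels)
}

#' Feature reliability map
#'
#' Combines the three edgewise contribution metrics — ICC, group
#' consistency, and differential power — into one tibble, one row per
#' feature.
#'
#' @inheritParams feature_icc
#' @return Tibble with `feature`, `icc`, `group_consistency`,
#'   `differential_power`.
#' @export
feature_reliability <- function(f1, f2) {
  tibble(
    feature = f1$feature_labels,
    icc = unname(feature_icc(f1, f2)),
    group_consistency = unname(group_consistency(f1, f2)),
    differential_power = unname(differential_power(f1, f2))
  )
}

check_matched <- function(f1, f2) {
  stopifnot(inherits(f1, "feature_matrix"), inherits(f2, "feature_matrix"))
  if (!identical(dim(f1$values), dim(f2$values)) ||
      !identical(f1$subject_ids, f2$subject_ids)) {
    abort("Feature matrices must cover the same subjects and features.")
  }
  invisible(TRUE)
}

unit_norm_rows <- function(x1, x2) {
  n1 <- sqrt(rowSums(x1^2))
  n2 <- sqrt(rowSums(x2^2))
  bad <- n1 == 0 | n2 == 0
  if (any(bad)) {
    warn(sprintf("%d subject(s) with zero-norm feature vectors excluded.",
                 sum(bad)))
    x1 <- x1[!bad, , drop = FALSE]
    x2 <- x2[!bad, , drop = FALSE]
    n1 <- n1[!bad]
    n2 <- n2[!bad]
  }
  list(x1 = x1 / n1, x2 = x2 / n2)
}
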