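#' Cross-dataset similarity matrix
#'
#' Entry `(i, j)` is the Pearson correlation between subject `i`'s feature
#' vector in the first dataset and subject `j`'s in the second. The matrix is
#' square and generally asymmetric; its diagonal holds each subject's
#' self-correlation across datasets. Feature columns that are `NA` for a
#' subject are dropped pairwise; a zero-variance feature row yields `NA`
#' correlations with a warning.
#'
#' @param f1,f2 [feature_matrix()] objects over the same subjects and
#'   feature space, in the same order.
#' @return A `similarity_matrix`: list with `A` (N x N), `subject_ids`,
#'   `dataset_pair`.
#' @export
similarity <- function(f1, f2) {
  stopifnot(inherits(f1, "feature_matrix"), inherits(f2, "feature_matrix"))
  if (!identical(dim(f1$values), dim(f2$values))) {
    abort("Feature matrices must have identical dimensions.")
  }
  if (!identical(f1$subject_ids, f2$subject_ids)) {
    abort("Feature matrices must cover the same subjects in the same order.")
  }
  x1 <- f1$values
  x2 <- f2$values
  ok1 <- apply(x1, 1, function(r) sd(r, na.rm = TRUE) > 0 && any(is.finite(r)))
  ok2 <- apply(x2, 1, function(r) sd(r, na.rm = TRUE) > 0 && any(is.finite(r)))
  if (!all(ok1 & ok2)) {
    warn(sprintf("%d subject row(s) have zero feature variance; correlations set to NA.",
                 sum(!(ok1 & ok2))))
  }
  a <- suppressWarnings(stats::cor(t(x1), t(x2), use = "pairwise.complete.obs"))
  a[!ok1, ] <- NA_real_
  a[, !ok2] <- NA_real_
  structure(
    list(
      A = a,
      subject_ids = f1$subject_ids,
      dataset_pair = c(f1$dataset_id, f2$dataset_id)
    ),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d (%s vs %s)\n",
              nrow(x$A), ncol(x$A), x$dataset_pair[1], x$dataset_pair[2]))
  invisible(x)
}

#' @describeIn similarity Long-format tibble: `subject_1`, `subject_2`, `r`.
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @export
tidy.similarity_matrix <- function(x, ...) {
  n <- nrow(x$A)
  tibble(
    subject_1 = rep(x$subject_ids, times = n),
    subject_2 = rep(x$subject_ids, each = n),
    r = as.vector(x$A)
  )
}

#' Correlational identification of cohort members
#'
#' For each probe subject, the predicted identity is the argmax of its row
#' (or column) of the similarity matrix: the cohort member whose features in
#' the other dataset correlate most with the probe. Ties are broken toward
#' the lowest index deterministically and counted. Subjects whose row is all
#' `NA` are marked unidentifiable and excluded from the accuracy denominator.
#'
#' @param sim A [similarity()] matrix.
#' @param direction `"rows"` (probe from dataset 1) or `"columns"` (probe
#'   from dataset 2).
#' @return A `fingerprint_result` tibble with columns `subject_id`,
#'   `predicted_id`, `correct`, `self_r`, `best_r`, `tied`; attributes
#'   `accuracy`, `n_ties`, `n_identifiable`, `direction`.
#' @export
identify_subjects <- function(sim, direction = c("rows", "columns")) {
  stopifnot(inherits(sim, "similarity_matrix"))
  direction <- match.arg(direction)
  a <- if (direction == "rows") sim$A else t(sim$A)
  n <- nrow(a)
  pred <- integer(n)
  tied <- logical(n)
  for (i in seq_len(n)) {
    row <- a[i, ]
    if (all(is.na(row))) {
      pred[i] <- NA_integer_
      next
    }
    m <- max(row, na.rm = TRUE)
    hits <- which(row == m)
    pred[i] <- hits[1]
    tied[i] <- length(hits) > 1
  }
  correct <- ifelse(is.na(pred), NA, pred == seq_len(n))
  n_ident <- sum(!is.na(pred))
  accuracy <- if (n_ident > 0) sum(correct, na.rm = TRUE) / n_ident else NA_real_
  out <- tibble(
    subject_id = sim$subject_ids,
    predicted_id = ifelse(is.na(pred), NA_character_, sim$subject_ids[pred]),
    correct = correct,
    self_r = diag(a),
    best_r = vapply(seq_len(n), function(i) {
      if (all(is.na(a[i, ]))) NA_real_ else max(a[i, ], na.rm = TRUE)
    }, numeric(1)),
    tied = tied
  )
  structure(
    out,
    class = c("fingerprint_result", class(out)),
    accuracy = accuracy,
    n_ties = sum(tied),
    n_identifiable = n_ident,
    direction = direction,
    dataset_pair = sim$dataset_pair
  )
}

#' @describeIn identify_subjects One-row summary: accuracy, counts, direction.
#' @param x A `fingerprint_result`.
#' @param ... Unused.
#' @export
glance.fingerprint_result <- function(x, ...) {
  tibble(
    accuracy = attr(x, "accuracy"),
    n_correct = sum(x$correct, na.rm = TRUE),
    n_identifiable = attr(x, "n_identifiable"),
    n_ties = attr(x, "n_ties"),
    direction = attr(x, "direction"),
    dataset_1 = attr(x, "dataset_pair")[1],
    dataset_2 = attr(x, "dataset_pair")[2]
  )
}

#' Per-participant differentiability score
#'
#' `D_self(i) = (A[i, i] - mu_i) / sigma_i`, the z-score of a participant's
#' self-correlation across the two datasets relative to their correlations
#' with everyone else: `mu_i` and `sigma_i` are the mean and sample standard
#' deviation of the off-diagonal entries of row `i`. Participants whose row
#' has zero spread get `NA` with no silent substitution.
#'
#' @param sim A [similarity()] matrix (needs at least 3 subjects).
#' @param include_self_in_null Include the diagonal term in `mu_i`/`sigma_i`
#'   (default `FALSE`: "all other individuals" reads exclusively).
#' @return Tibble with `subject_id`, `corr_self`, `mu_others`,
#'   `sigma_others`, `d_self`.
#' @export
#' @examples
#' a <- matrix(c(0.9, 0.5, 0.6, 0.4,
#'               0.5, 0.8, 0.3, 0.2,
#'               0.1, 0.2, 0.7, 0.3,
#'               0.2, 0.1, 0.3, 0.9), 4, 4, byrow = TRUE)
#' f <- feature_matrix(diag(4)) # placeholder container
#' s <- structure(list(A = a, subject_ids = paste0("s", 1:4),
#'                     dataset_pair = c("d1", "d2")),
#'                class = "similarity_matrix")
#' differentiability(s)
differentiability <- function(sim, include_self_in_null = FALSE) {
  stopifnot(inherits(sim, "similarity_matrix"))
  a <- sim$A
  n <- nrow(a)
  if (n < 3) abort("Differentiability needs at least 3 subjects.")
  res <- purrr::map_dfr(seq_len(n), function(i) {
    others <- if (include_self_in_null) a[i, ] else a[i, -i]
    mu <- mean(others, na.rm = TRUE)
    sig <- sd(others, na.rm = TRUE)
    d <- if (is.na(sig) || sig == 0) NA_real_ else (a[i, i] - mu) / sig
    tibble(
      subject_id = sim$subject_ids[i],
      corr_self = a[i, i],
      mu_others = mu,
      sigma_others = sig,
      d_self = d
    )
  })
  res
}
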