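#' Correlate differentiability with recording confounds
#'
#' Pearson correlation (two-sided t-test, n - 2 degrees of freedom) between
#' per-subject scores (typically `d_self`) and each candidate confound:
#' artifact RMS measures, scan duration, or any numeric per-subject
#' covariate. Pairs where either side has zero variance are reported as
#' undefined (`NA`) rather than dropped silently.
#'
#' @param scores Tibble with `subject_id` and one or more numeric score
#'   columns (e.g. the output of [differentiability()]).
#' @param confounds Tibble with `subject_id` and numeric confound columns.
#' @param score_cols Score columns to test (default `"d_self"`).
#' @param confound_cols Confound columns (default: all numeric columns).
#' @return Tibble with `score`, `confound`, `r`, `p`, `n`.
#' @export
confound_correlations <- function(scores, confounds, score_cols = "d_self",
                                  confound_cols = NULL) {
  stopifnot("subject_id" %in% names(scores), "subject_id" %in% names(confounds))
  joined <- dplyr::inner_join(scores, confounds, by = "subject_id")
  if (is.null(confound_cols)) {
    confound_cols <- setdiff(
      names(confounds)[vapply(confounds, is.numeric, logical(1))],
      "subject_id")
  }
  grid <- tidyr::expand_grid(score = score_cols, confound = confound_cols)
  purrr::pmap_dfr(grid, function(score, confound) {
    x <- joined[[score]]
    y <- joined[[confound]]
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]
    y <- y[keep]
    n <- length(x)
    if (n < 3 || sd(x) == 0 || sd(y) == 0) {
      return(tibble(score = score, confound = confound,
                    r = NA_real_, p = NA_real_, n = n))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble(score = score, confound = confound,
           r = unname(ct$estimate), p = ct$p.value, n = n)
  })
}
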