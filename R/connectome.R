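#' Amplitude-envelope-correlation connectome
#'
#' Builds the functional connectome of a set of ROI timeseries: each signal
#' is (optionally) band-pass filtered, Hilbert envelopes are extracted, and
#' every ROI pair's entry is the Pearson correlation between their envelopes.
#' The result is a symmetric matrix with unit diagonal. With
#' `orthogonalize = TRUE`, each pair of band-limited signals is
#' orthogonalized (symmetrically, regressing one out of the other in both
#' directions and averaging the two envelope correlations) before envelope
#' extraction, which suppresses zero-lag leakage.
#'
#' ROIs whose envelope has zero variance get `NA` correlations (flagged with
#' a warning), never a silent 0.
#'
#' @param roi_ts Numeric matrix, one ROI timeseries per row.
#' @param fs Sampling rate in Hz.
#' @param band Optional band (name, `c(f_lo, f_hi)`, or one-row band table);
#'   `NULL` or `"broadband"` skips filtering. Filtering here is identical to
#'   calling [bandpass()] first.
#' @param orthogonalize Apply pairwise leakage correction (default `FALSE`).
#' @param roi_labels Optional ROI labels.
#' @return A `connectome`: list with `values` (R x R), `roi_labels`, `band`.
#' @export
#' @examples
#' fs <- 200
#' x <- matrix(rnorm(4 * fs * 30), nrow = 4)
#' cn <- aec_connectome(x, fs, band = "alpha")
#' range(cn$values)
aec_connectome <- function(roi_ts, fs, band = NULL, orthogonalize = FALSE,
                           roi_labels = NULL) {
  x <- as.matrix(roi_ts)
  if (nrow(x) < 2) abort("Need at least 2 ROI timeseries.")
  stopifnot_finite(x, "roi_ts")
  band <- resolve_band(band)
  if (!is.null(band)) x <- bandpass(x, c(band$f_lo, band$f_hi), fs)
  r <- nrow(x)
  if (orthogonalize) {
    vals <- diag(1, r)
    env_all <- envelope(x)
    for (i in seq_len(r - 1)) {
      for (j in (i + 1):r) {
        vals[i, j] <- vals[j, i] <- aec_pair_orth(x[i, ], x[j, ])
      }
    }
  } else {
    env <- envelope(x)
    zero_var <- apply(env, 1, function(e) isTRUE(all.equal(var(e), 0)) || var(e) == 0)
    vals <- row_cor(env, env)
    if (any(zero_var)) {
      warn(sprintf("%d ROI(s) have constant envelopes; their correlations are NA.",
                   sum(zero_var)))
      vals[zero_var, ] <- NA_real_
      vals[, zero_var] <- NA_real_
    }
    diag(vals) <- 1
    vals <- (vals + t(vals)) / 2
  }
  structure(
    list(
      values = vals,
      roi_labels = roi_labels %||% paste0("roi", seq_len(r)),
      band = if (is.null(band)) "broadband" else band$name
    ),
    class = "connectome"
  )
}

# Symmetric pairwise orthogonalized envelope correlation: regress y out of x
# (and vice versa) at zero lag, correlate the residual envelope with the
# other signal's envelope, average the two directions.
aec_pair_orth <- function(x, y) {
  env_x <- envelope(x)
  env_y <- envelope(y)
  y_orth <- y - x * (sum(x * y) / sum(x * x))
  x_orth <- x - y * (sum(x * y) / sum(y * y))
  c1 <- suppressWarnings(cor(env_x, envelope(y_orth)))
  c2 <- suppressWarnings(cor(env_y, envelope(x_orth)))
  mean(c(c1, c2))
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d x %d AEC matrix, band = %s\n",
              nrow(x$values), ncol(x$values), x$band))
  invisible(x)
}

#' @describeIn aec_connectome Long-format tibble of unique edges:
#'   `roi_1`, `roi_2`, `aec`.
#' @param x A `connectome`.
#' @param ... Unused.
#' @export
tidy.connectome <- function(x, ...) {
  idx <- upper_tri_rowmajor(nrow(x$values))
  tibble(
    roi_1 = x$roi_labels[idx[, 1]],
    roi_2 = x$roi_labels[idx[, 2]],
    aec = x$values[idx]
  )
}

# Row-major (lexicographic i < j) upper-triangle index matrix.
upper_tri_rowmajor <- function(r) {
  idx <- which(upper.tri(matrix(0, r, r)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
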