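#' Feature matrix container
#'
#' A subject x feature numeric matrix for one dataset, with feature labels.
#' Rows are subjects in cohort order; columns are connectome edges or
#' ROI x frequency PSD bins.
#'
#' @param values Numeric matrix, one row per subject.
#' @param feature_labels Character vector, one label per column.
#' @param subject_ids Character vector, one id per row.
#' @param dataset_id Label of the dataset the features came from.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_labels = NULL, subject_ids = NULL,
                           dataset_id = "dataset") {
  values <- as.matrix(values)
  if (!all(is.finite(values))) {
    abort("Feature matrix contains non-finite entries.")
  }
  structure(
    list(
      values = values,
      feature_labels = feature_labels %||% paste0("f", seq_len(ncol(values))),
      subject_ids = subject_ids %||% sprintf("sub%03d", seq_len(nrow(values))),
      dataset_id = dataset_id
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> '%s': %d subjects x %d features\n",
              x$dataset_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as_tibble.feature_matrix <- function(x, ...) {
  out <- as_tibble(x$values, .name_repair = "minimal")
  names(out) <- x$feature_labels
  dplyr::bind_cols(tibble(subject_id = x$subject_ids), out)
}

#' Vectorize a connectome or PSD profile into a feature row
#'
#' Connectomes become their upper triangle (diagonal excluded) in row-major
#' lexicographic edge order `(1,2), (1,3), ..., (2,3), ...` — length
#' `R(R-1)/2` (2278 for 68 ROIs). PSD profiles become the concatenation of
#' per-ROI PSD bins (ROI-major); when `band` is given only the bins inside
#' the band are kept, and the full grid is used for broadband.
#'
#' @param features A `connectome` or `psd_profile`.
#' @param band Optional band restriction for PSD profiles.
#' @return Named numeric vector.
#' @export
vectorize_features <- function(features, band = NULL) {
  UseMethod("vectorize_features")
}

#' @export
vectorize_features.connectome <- function(features, band = NULL) {
  idx <- upper_tri_rowmajor(nrow(features$values))
  v <- features$values[idx]
  names(v) <- paste0(features$roi_labels[idx[, 1]], "--",
                     features$roi_labels[idx[, 2]])
  v
}

#' @export
vectorize_features.psd_profile <- function(features, band = NULL) {
  band <- resolve_band(band)
  vals <- features$values
  freqs <- features$freqs
  if (!is.null(band)) {
    sel <- freqs >= band$f_lo & freqs <= band$f_hi
    if (!any(sel)) {
      abort(sprintf("Band [%g, %g] Hz has no bins on the PSD grid.",
                    band$f_lo, band$f_hi))
    }
    vals <- vals[, sel, drop = FALSE]
    freqs <- freqs[sel]
  }
  v <- as.vector(t(vals)) # ROI-major: roi1 all bins, roi2 all bins, ...
  names(v) <- paste0(rep(features$roi_labels, each = length(freqs)), "@",
                     rep(freqs, times = nrow(vals)), "Hz")
  v
}

#' Rebuild a symmetric connectome matrix from an edge vector
#'
#' Inverse of [vectorize_features()] for connectomes (unit diagonal).
#'
#' @param edges Edge vector in row-major upper-triangle order.
#' @param n_roi Number of ROIs.
#' @return Symmetric `n_roi` x `n_roi` matrix.
#' @export
connectome_from_edges <- function(edges, n_roi) {
  if (length(edges) != n_roi * (n_roi - 1) / 2) {
    abort("Edge vector length does not match n_roi (n_roi * (n_roi - 1) / 2).")
  }
  m <- diag(1, n_roi)
  idx <- upper_tri_rowmajor(n_roi)
  m[idx] <- edges
  m[idx[, c(2, 1), drop = FALSE]] <- edges
  m
}

#' Extract fingerprinting features from a dataset
#'
#' Runs the feature-extraction path on every subject of a dataset:
#' `"connectome"` computes the band-limited AEC connectome and vectorizes its
#' upper triangle; `"spectral"` computes the Welch PSD profile and vectorizes
#' the (optionally band-restricted) ROI x frequency bins.
#'
#' @param dataset A `roi_dataset` from [segment_recording()].
#' @param type `"connectome"` or `"spectral"`.
#' @param band Band name, `c(f_lo, f_hi)`, `"broadband"`, or `NULL`.
#' @param orthogonalize Leakage correction for AEC (default `FALSE`).
#' @param log_psd Log-transform PSD features (default `FALSE`).
#' @param window_sec Welch window length in seconds (default 2).
#' @return A [feature_matrix()].
#' @export
extract_features <- function(dataset, type = c("connectome", "spectral"),
                             band = NULL, orthogonalize = FALSE,
                             log_psd = FALSE, window_sec = 2) {
  stopifnot(inherits(dataset, "roi_dataset"))
  type <- match.arg(type)
  d <- dim(dataset$data)
  rows <- vector("list", d[1])
  for (i in seq_len(d[1])) {
    x <- dataset$data[i, , , drop = FALSE]
    dim(x) <- d[2:3]
    if (type == "connectome") {
      cn <- aec_connectome(x, dataset$fs, band = band,
                           orthogonalize = orthogonalize,
                           roi_labels = dataset$roi_labels)
      rows[[i]] <- vectorize_features(cn)
    } else {
      psd <- welch_psd(x, dataset$fs, window_sec = window_sec,
                       roi_labels = dataset$roi_labels)
      v <- vectorize_features(psd, band = band)
      if (log_psd) v <- log(v + .Machine$double.eps)
      rows[[i]] <- v
    }
  }
  values <- do.call(rbind, rows)
  fm_vals <- values
  # NA feature entries (zero-variance envelopes) are kept explicit, not zeroed
  out <- structure(
    list(
      values = fm_vals,
      feature_labels = names(rows[[1]]),
      subject_ids = dataset$subject_ids,
      dataset_id = dataset$label
    ),
    class = "feature_matrix"
  )
  out
}
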