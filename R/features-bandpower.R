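#' Band-power feature matrix
#'
#' Summarizes each subject's Welch PSD into integrated band power per ROI
#' per band — the compact spectral feature set used for linking features to
#' demographics. Columns are ordered band-major (ROI fastest) and labelled
#' `"<roi>.<band>"`, matching the generator's planted-feature labels.
#'
#' @param dataset A `roi_dataset`.
#' @param bands Band table as from [meg_bands()].
#' @param log Log-transform powers (default `TRUE`; band power is
#'   approximately log-normal across subjects).
#' @param window_sec Welch window length in seconds.
#' @return A [feature_matrix()].
#' @export
bandpower_features <- function(dataset, bands = meg_bands(), log = TRUE,
                               window_sec = 2) {
  stopifnot(inherits(dataset, "roi_dataset"))
  d <- dim(dataset$data)
  rows <- vector("list", d[1])
  for (i in seq_len(d[1])) {
    x <- dataset$data[i, , , drop = FALSE]
    dim(x) <- d[2:3]
    psd <- welch_psd(x, dataset$fs, window_sec = window_sec,
                     roi_labels = dataset$roi_labels)
    bp <- band_power(psd, bands)
    v <- bp$power
    names(v) <- paste0(bp$roi, ".", bp$band)
    rows[[i]] <- if (log) base::log(v) else v
  }
  values <- do.call(rbind, rows)
  feature_matrix(values, feature_labels = names(rows[[1]]),
                 subject_ids = dataset$subject_ids,
                 dataset_id = paste0(dataset$label, "_bandpower"))
}
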