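#' Write / read a cohort recording as a directory container
#'
#' Persists a [cohort_recording()] as a hierarchical directory: one
#' delimited-text matrix (ROI x time, tab-separated) per subject x session
#' under `<dir>/<subject>/<session>.tsv`, plus `meta.json` carrying the
#' sampling rate and labels. This is the package's plain-text array
#' container; recordings of realistic size should normally be regenerated
#' from a config rather than stored.
#'
#' @param recording A `cohort_recording`.
#' @param dir Target directory (created if missing).
#' @return `dir` (write) or a `cohort_recording` (read).
#' @export
write_cohort_dir <- function(recording, dir) {
  stopifnot(inherits(recording, "cohort_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(recording$data)
  for (i in seq_len(d[1])) {
    sub_dir <- file.path(dir, recording$subject_ids[i])
    dir.create(sub_dir, showWarnings = FALSE)
    for (s in seq_len(d[2])) {
      m <- recording$data[i, s, , , drop = FALSE]
      dim(m) <- d[3:4]
      utils::write.table(
        m, file.path(sub_dir, paste0(recording$session_ids[s], ".tsv")),
        sep = "\t", row.names = FALSE, col.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(fs = recording$fs, subject_ids = recording$subject_ids,
         session_ids = recording$session_ids,
         roi_labels = recording$roi_labels),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort_dir
#' @export
read_cohort_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  n <- length(meta$subject_ids)
  s_n <- length(meta$session_ids)
  first <- as.matrix(utils::read.table(
    file.path(dir, meta$subject_ids[1],
              paste0(meta$session_ids[1], ".tsv")), sep = "\t"))
  data <- array(0, c(n, s_n, nrow(first), ncol(first)))
  for (i in seq_len(n)) {
    for (s in seq_len(s_n)) {
      m <- as.matrix(utils::read.table(
        file.path(dir, meta$subject_ids[i],
                  paste0(meta$session_ids[s], ".tsv")), sep = "\t"))
      data[i, s, , ] <- m
    }
  }
  cohort_recording(data, meta$fs, meta$subject_ids, meta$session_ids,
                   meta$roi_labels)
}

#' Write a feature matrix as labelled CSV
#'
#' Subjects x features with a header row of feature labels and a leading
#' `subject_id` column.
#'
#' @param fm A [feature_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  utils::write.csv(as.data.frame(as_tibble(fm)), path, row.names = FALSE)
  invisible(path)
}
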