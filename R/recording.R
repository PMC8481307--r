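#' Cohort recording container
#'
#' Wraps a subject x session x ROI x time array of ROI timeseries with its
#' sampling rate and labels. This is the package's entry container; the
#' synthetic generator produces it, and real source-imaged data can be
#' assembled into it from per-subject matrices.
#'
#' @param data 4-D numeric array `[subject, session, roi, time]`.
#' @param fs Sampling rate in Hz.
#' @param subject_ids,session_ids,roi_labels Optional dimension labels.
#' @return A `cohort_recording`.
#' @export
cohort_recording <- function(data, fs, subject_ids = NULL, session_ids = NULL,
                             roi_labels = NULL) {
  if (length(dim(data)) != 4) {
    abort("`data` must be a 4-D array [subject, session, roi, time].")
  }
  stopifnot_finite(fs, "fs")
  if (!all(is.finite(data))) abort("`data` contains non-finite values.")
  d <- dim(data)
  structure(
    list(
      data = data,
      fs = fs,
      subject_ids = subject_ids %||% sprintf("sub%03d", seq_len(d[1])),
      session_ids = session_ids %||% sprintf("ses%02d", seq_len(d[2])),
      roi_labels = roi_labels %||% sprintf("roi%03d", seq_len(d[3]))
    ),
    class = "cohort_recording"
  )
}

#' @export
print.cohort_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<cohort_recording> %d subjects x %d sessions x %d ROIs x %d samples (%.5g s at %g Hz)\n",
    d[1], d[2], d[3], d[4], d[4] / x$fs, x$fs))
  invisible(x)
}

#' @export
dim.cohort_recording <- function(x) dim(x$data)

# One dataset: subject x ROI x time slab cut from a recording.
roi_dataset <- function(data, fs, subject_ids, roi_labels, label) {
  structure(
    list(data = data, fs = fs, subject_ids = subject_ids,
         roi_labels = roi_labels, label = label),
    class = "roi_dataset"
  )
}

#' @export
print.roi_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<roi_dataset> '%s': %d subjects x %d ROIs x %d samples (%g Hz)\n",
              x$label, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Split a recording into fingerprinting datasets
#'
#' Cuts each session of a cohort recording into the datasets used by the
#' differentiation challenges: `"within_halves"` yields two equal
#' non-overlapping halves per session; `"segments_30s"` yields three
#' non-overlapping segments of `segment_sec` seconds per session, taken from
#' the start of the recording, discarding any leftover samples.
#'
#' @param recording A [cohort_recording()].
#' @param scheme `"within_halves"` or `"segments_30s"`.
#' @param segment_sec Segment length for the shortened scheme (default 30 s).
#' @param n_segments Number of segments for the shortened scheme (default 3).
#' @return Named list of `roi_dataset` objects, named
#'   `"<session>_h<half>"` or `"<session>_g<segment>"`.
#' @export
segment_recording <- function(recording, scheme = c("within_halves", "segments_30s"),
                              segment_sec = 30, n_segments = 3) {
  stopifnot(inherits(recording, "cohort_recording"))
  scheme <- match.arg(scheme)
  d <- dim(recording$data)
  n_time <- d[4]
  fs <- recording$fs
  out <- list()
  for (s in seq_len(d[2])) {
    ses <- recording$session_ids[s]
    slab <- recording$data[, s, , , drop = FALSE]
    dim(slab) <- d[c(1, 3, 4)]
    if (scheme == "within_halves") {
      half <- floor(n_time / 2)
      if (half < 1) abort("Recording too short to split in half.")
      out[[paste0(ses, "_h1")]] <- roi_dataset(
        slab[, , 1:half, drop = FALSE], fs,
        recording$subject_ids, recording$roi_labels, paste0(ses, "_h1"))
      out[[paste0(ses, "_h2")]] <- roi_dataset(
        slab[, , (half + 1):(2 * half), drop = FALSE], fs,
        recording$subject_ids, recording$roi_labels, paste0(ses, "_h2"))
    } else {
      seg_len <- round(segment_sec * fs)
      need <- seg_len * n_segments
      if (n_time < need) {
        abort(sprintf(
          "Recording too short for %d x %g s segments: %g s required, %g s available.",
          n_segments, segment_sec, need / fs, n_time / fs))
      }
      for (g in seq_len(n_segments)) {
        idx <- ((g - 1) * seg_len + 1):(g * seg_len)
        out[[paste0(ses, "_g", g)]] <- roi_dataset(
          slab[, , idx, drop = FALSE], fs,
          recording$subject_ids, recording$roi_labels, paste0(ses, "_g", g))
      }
    }
  }
  out
}
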