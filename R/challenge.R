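#' Run a differentiation challenge over all dataset pairs
#'
#' Enumerates the dataset pairs of a challenge, extracts features for each
#' dataset once, and runs similarity -> identification (both probe
#' directions) -> differentiability for every pair:
#'
#' * `"within"`: the two halves of each session.
#' * `"within_short"`: all unordered pairs of the three 30 s segments of
#'   each session.
#' * `"between"`: full sessions, all session pairs.
#' * `"between_short"`: all 3 x 3 cross-session segment pairs.
#'
#' @param recording A [cohort_recording()].
#' @param challenge Challenge type.
#' @param type Feature type, `"connectome"` or `"spectral"`.
#' @param band Band name, `c(f_lo, f_hi)`, or `"broadband"`/`NULL`.
#' @param orthogonalize,log_psd,window_sec Passed to [extract_features()].
#' @param include_self_in_null Passed to [differentiability()].
#' @param segment_sec,n_segments Shortened-challenge segmentation.
#' @return A `challenge_result`: list with `accuracies` (tibble: one row per
#'   pair x direction), `d_self` (tibble: per pair x subject),
#'   `accuracy_mean` (sample mean across pairs and directions),
#'   `accuracy_headline` (first pair, rows direction), and run metadata.
#' @export
run_challenge <- function(recording,
                          challenge = c("within", "between",
                                        "within_short", "between_short"),
                          type = c("connectome", "spectral"),
                          band = NULL, orthogonalize = FALSE, log_psd = FALSE,
                          window_sec = 2, include_self_in_null = FALSE,
                          segment_sec = 30, n_segments = 3) {
  stopifnot(inherits(recording, "cohort_recording"))
  challenge <- match.arg(challenge)
  type <- match.arg(type)
  d <- dim(recording$data)
  n_sessions <- d[2]
  if (challenge %in% c("between", "between_short") && n_sessions < 2) {
    abort(sprintf("Challenge '%s' needs at least 2 sessions; recording has %d.",
                  challenge, n_sessions))
  }

  scheme <- if (challenge %in% c("within", "between")) "within_halves" else "segments_30s"
  datasets <- if (challenge == "between") {
    # full sessions: rebuild one dataset per session without halving
    full <- list()
    for (s in seq_len(n_sessions)) {
      slab <- recording$data[, s, , , drop = FALSE]
      dim(slab) <- d[c(1, 3, 4)]
      ses <- recording$session_ids[s]
      full[[ses]] <- roi_dataset(slab, recording$fs, recording$subject_ids,
                                 recording$roi_labels, ses)
    }
    full
  } else {
    segment_recording(recording, scheme, segment_sec = segment_sec,
                      n_segments = n_segments)
  }

  pairs <- challenge_pairs(challenge, recording$session_ids, n_segments)
  used <- unique(unlist(pairs))
  feats <- purrr::map(datasets[used], extract_features, type = type,
                      band = band, orthogonalize = orthogonalize,
                      log_psd = log_psd, window_sec = window_sec)

  acc_rows <- list()
  dself_rows <- list()
  for (p in pairs) {
    sim <- similarity(feats[[p[1]]], feats[[p[2]]])
    for (dir in c("rows", "columns")) {
      res <- identify_subjects(sim, dir)
      acc_rows[[length(acc_rows) + 1]] <- glance(res)
    }
    ds <- differentiability(sim, include_self_in_null = include_self_in_null)
    ds$dataset_1 <- p[1]
    ds$dataset_2 <- p[2]
    dself_rows[[length(dself_rows) + 1]] <- ds
  }
  accuracies <- dplyr::bind_rows(acc_rows)
  d_self <- dplyr::bind_rows(dself_rows)

  structure(
    list(
      accuracies = accuracies,
      d_self = d_self,
      accuracy_mean = mean(accuracies$accuracy, na.rm = TRUE),
      accuracy_headline = accuracies$accuracy[1],
      challenge = challenge,
      type = type,
      band = if (is.null(band)) "broadband" else resolve_band(band)$name %||% "broadband",
      n_subjects = d[1]
    ),
    class = "challenge_result"
  )
}

# Ordered list of dataset-name pairs for each challenge.
challenge_pairs <- function(challenge, session_ids, n_segments = 3) {
  pairs <- list()
  if (challenge == "within") {
    for (ses in session_ids) {
      pairs[[length(pairs) + 1]] <- c(paste0(ses, "_h1"), paste0(ses, "_h2"))
    }
  } else if (challenge == "within_short") {
    for (ses in session_ids) {
      for (g1 in seq_len(n_segments - 1)) {
        for (g2 in (g1 + 1):n_segments) {
          pairs[[length(pairs) + 1]] <-
            c(paste0(ses, "_g", g1), paste0(ses, "_g", g2))
        }
      }
    }
  } else if (challenge == "between") {
    n <- length(session_ids)
    for (s1 in seq_len(n - 1)) {
      for (s2 in (s1 + 1):n) {
        pairs[[length(pairs) + 1]] <- c(session_ids[s1], session_ids[s2])
      }
    }
  } else { # between_short
    n <- length(session_ids)
    for (s1 in seq_len(n - 1)) {
      for (s2 in (s1 + 1):n) {
        for (g1 in seq_len(n_segments)) {
          for (g2 in seq_len(n_segments)) {
            pairs[[length(pairs) + 1]] <-
              c(paste0(session_ids[s1], "_g", g1),
                paste0(session_ids[s2], "_g", g2))
          }
        }
      }
    }
  }
  pairs
}

#' @export
print.challenge_result <- function(x, ...) {
  cat(sprintf(
    "<challenge_result> %s / %s / %s: mean accuracy %.3f over %d pair-directions (N = %d)\n",
    x$challenge, x$type, x$band, x$accuracy_mean, nrow(x$accuracies),
    x$n_subjects))
  invisible(x)
}

#' @describeIn run_challenge Per-pair accuracies as a tibble.
#' @param x A `challenge_result`.
#' @param ... Unused.
#' @export
tidy.challenge_result <- function(x, ...) {
  dplyr::mutate(x$accuracies, challenge = x$challenge, type = x$type,
                band = x$band)
}

#' @describeIn run_challenge One-row summary with the mean and headline
#'   accuracy.
#' @export
glance.challenge_result <- function(x, ...) {
  tibble(
    challenge = x$challenge,
    type = x$type,
    band = x$band,
    accuracy_mean = x$accuracy_mean,
    accuracy_headline = x$accuracy_headline,
    n_pairs = nrow(x$accuracies),
    n_subjects = x$n_subjects,
    mean_d_self = mean(x$d_self$d_self, na.rm = TRUE)
  )
}
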