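#' Welch power spectral density per ROI
#'
#' Estimates one-sided power spectral densities with Welch's method: Hann
#' windows of `window_sec` seconds with 50% overlap, periodograms averaged
#' per ROI, density scaling (power per Hz). With the default 2 s window the
#' frequency resolution is 0.5 Hz, and the grid spans 0 Hz to `f_max`
#' (capped at the Nyquist frequency).
#'
#' @param roi_ts Numeric matrix, one ROI timeseries per row (a vector is
#'   treated as a single ROI).
#' @param fs Sampling rate in Hz.
#' @param window_sec Window length in seconds (default 2).
#' @param overlap Fractional window overlap (default 0.5).
#' @param f_max Upper edge of the reported grid in Hz (default 150).
#' @param roi_labels Optional ROI labels.
#' @return A `psd_profile`: list with `values` (ROI x frequency matrix),
#'   `freqs` (Hz), `roi_labels`, `fs`.
#' @export
#' @examples
#' fs <- 300
#' x <- rnorm(fs * 20)
#' p <- welch_psd(x, fs)
#' # white noise: flat density ~ var/(fs/2) per Hz
#' mean(p$values) * (fs / 2)
welch_psd <- function(roi_ts, fs, window_sec = 2, overlap = 0.5,
                      f_max = 150, roi_labels = NULL) {
  vec <- is.null(dim(roi_ts))
  x <- if (vec) matrix(roi_ts, nrow = 1) else as.matrix(roi_ts)
  stopifnot_finite(x, "roi_ts")
  n <- ncol(x)
  nwin <- round(window_sec * fs)
  if (n < nwin) {
    abort(sprintf(
      "Recording too short for Welch PSD: %g s available, %g s window required.",
      n / fs, window_sec))
  }
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / nwin) # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  n_keep <- floor(nwin / 2) + 1L
  acc <- matrix(0, nrow(x), n_keep)
  for (st in starts) {
    seg <- x[, st:(st + nwin - 1L), drop = FALSE]
    seg <- seg * rep(w, each = nrow(seg))
    sf <- stats::mvfft(t(seg))[seq_len(n_keep), , drop = FALSE]
    acc <- acc + t(Mod(sf)^2)
  }
  psd <- acc * (scale / length(starts))
  # one-sided: double all bins except DC and (for even nwin) Nyquist
  dbl <- rep(2, n_keep)
  dbl[1] <- 1
  if (nwin %% 2 == 0) dbl[n_keep] <- 1
  psd <- psd * rep(dbl, each = nrow(psd))
  freqs <- (seq_len(n_keep) - 1) * fs / nwin
  keep <- freqs <= min(f_max, fs / 2) + 1e-9
  structure(
    list(
      values = psd[, keep, drop = FALSE],
      freqs = freqs[keep],
      roi_labels = roi_labels %||% paste0("roi", seq_len(nrow(x))),
      fs = fs
    ),
    class = "psd_profile"
  )
}

#' @export
print.psd_profile <- function(x, ...) {
  cat(sprintf("<psd_profile> %d ROI(s) x %d frequency bins (%.1f-%.1f Hz, df = %.2g Hz)\n",
              nrow(x$values), length(x$freqs), min(x$freqs), max(x$freqs),
              diff(x$freqs[1:2])))
  invisible(x)
}

#' @describeIn welch_psd Long-format tibble: `roi`, `freq`, `psd`.
#' @param x A `psd_profile`.
#' @param ... Unused.
#' @export
tidy.psd_profile <- function(x, ...) {
  tibble(
    roi = rep(x$roi_labels, times = length(x$freqs)),
    freq = rep(x$freqs, each = length(x$roi_labels)),
    psd = as.vector(x$values)
  )
}

#' Integrated band power from a PSD profile
#'
#' Integrates the PSD over each requested band (trapezoid-free bin sum times
#' bin width), returning one power value per ROI per band.
#'
#' @param psd A `psd_profile` from [welch_psd()].
#' @param bands Band table as from [meg_bands()].
#' @return Tibble with columns `roi`, `band`, `power`.
#' @export
band_power <- function(psd, bands = meg_bands()) {
  stopifnot(inherits(psd, "psd_profile"))
  df <- diff(psd$freqs[1:2])
  purrr::pmap_dfr(bands, function(name, f_lo, f_hi) {
    sel <- psd$freqs >= f_lo & psd$freqs <= f_hi
    if (!any(sel)) abort(sprintf("Band '%s' has no bins on the PSD grid.", name))
    tibble(
      roi = psd$roi_labels,
      band = name,
      power = rowSums(psd$values[, sel, drop = FALSE]) * df
    )
  })
}
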