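#' Amplitude envelope via the analytic signal
#'
#' Returns the magnitude of the analytic signal (Hilbert envelope) of one or
#' more timeseries, computed in the frequency domain: negative frequencies
#' are zeroed, positive frequencies doubled, DC and Nyquist left unchanged.
#'
#' @param x Numeric vector, or matrix with one timeseries per row.
#' @return Nonnegative envelope with the same shape as `x`.
#' @export
#' @examples
#' fs <- 200
#' x <- 2 * sin(2 * pi * 20 * seq(0, 5, by = 1 / fs))
#' mean(envelope(x)) # about 2, the tone amplitude
envelope <- function(x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  stopifnot_finite(xm, "x")
  n <- ncol(xm)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  xf <- t(stats::mvfft(t(xm)))
  analytic <- t(stats::mvfft(t(xf * rep(h, each = nrow(xm))), inverse = TRUE)) / n
  out <- Mod(analytic)
  if (vec) drop(out) else out
}
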