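# Shared fixtures: small cohort configs used across tests. fs = 300 Hz keeps
# the 0.5 Hz Welch grid and the five bands below 150 Hz while staying fast;
# the high-gamma band needs fs >= 600 and is exercised separately.

test_bands <- function() meg_bands()[1:5, ]

small_config <- function(n_subjects = 8, n_sessions = 1, n_rois = 4,
                         duration = 40, fs = 300, seed = 1L,
                         bands = test_bands(), ...) {
  synth_config(n_subjects = n_subjects, n_sessions = n_sessions,
               n_rois = n_rois, fs = fs, duration = duration,
               bands = bands, seed = seed, ...)
}

# High-reliability regime: strong stable subject structure, little session
# drift, rich coupling. Uses the theta-gamma bands: broadband AEC estimates
# from short segments are then not dominated by slow delta envelopes, whose
# few effective samples would swamp the coupling signal at test durations.
highrel_config <- function(n_subjects = 12, n_rois = 12, duration = 90,
                           seed = 1L, ...) {
  synth_config(n_subjects = n_subjects, n_sessions = 2, n_rois = n_rois,
               fs = 300, duration = duration, bands = meg_bands()[2:5, ],
               sigma_between = 1, sigma_within = 0.02,
               n_latents = 12, coupling_sd = 1.5, noise_sd = 0.1,
               seed = seed, ...)
}

# concatenate two [subject, session, roi, time] arrays along time
abind_time <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1:3], d[4] + dim(b)[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}

# brute-force Pearson correlation from the definition (oracle helper)
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  num / den
}

# independent analytic-signal envelope oracle: explicit FFT weighting
envelope_oracle <- function(x) {
  n <- length(x)
  xf <- fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(xf * w, inverse = TRUE) / n)
}
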