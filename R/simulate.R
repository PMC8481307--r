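#' Configuration for the synthetic cohort generator
#'
#' Collects the generative parameters for [simulate_cohort()] and
#' [simulate_empty_room()]. The generator plants the statistical structure
#' the fingerprinting analysis assumes in real resting-state MEG source
#' data: subject-specific band-limited power topographies, subject-specific
#' inter-ROI coupling through shared band-limited latent carriers,
#' session-to-session drift of both, an individual alpha peak frequency,
#' additive sensor noise, and demographics linearly coupled to a planted
#' subset of band-power features.
#'
#' `sigma_between` and `sigma_within` are log-amplitude standard deviations
#' (between subjects, and between sessions within a subject) and may be one
#' value per band. `demographic_effect` scales the planted linear coupling
#' between demographics and features (0 = no coupling).
#'
#' @param n_subjects,n_sessions Cohort dimensions (no defaults; open MEG
#'   archives typically offer on the order of 150 participants with a
#'   ~50-participant subset scanned on two days).
#' @param n_rois Number of ROIs (default 68, Desikan-Killiany size).
#' @param fs Sampling rate in Hz (default 600; covers the 150 Hz analysis
#'   ceiling with margin).
#' @param duration Seconds per session (default 300, ~5 min).
#' @param bands Band table as from [meg_bands()]; may be empty.
#' @param band_log_mean Mean log-amplitude per band; default gives a
#'   1/f-like power profile centred on the alpha band.
#' @param sigma_between,sigma_within Log-amplitude SDs per band (recycled).
#' @param n_latents Number of shared band-limited latent carriers.
#' @param coupling_sd SD of subject-specific latent coupling weights.
#' @param noise_sd Additive white-noise SD.
#' @param alpha_peak_mean,alpha_peak_sd Individual alpha peak frequency
#'   distribution (Hz).
#' @param demographic_effect Planted demographics-feature coupling strength.
#' @param n_planted Number of features carrying the planted coupling.
#' @param seed Integer seed; identical (config, seed) is bit-reproducible.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_subjects, n_sessions = 2, n_rois = 68, fs = 600,
                         duration = 300, bands = meg_bands(),
                         band_log_mean = NULL,
                         sigma_between = 0.5, sigma_within = 0.1,
                         n_latents = 5, coupling_sd = 0.5, noise_sd = 0.5,
                         alpha_peak_mean = 10, alpha_peak_sd = 1,
                         demographic_effect = 0, n_planted = 10, seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, n_sessions = n_sessions, n_rois = n_rois,
    fs = fs, duration = duration, bands = bands,
    band_log_mean = band_log_mean, sigma_between = sigma_between,
    sigma_within = sigma_within, n_latents = n_latents,
    coupling_sd = coupling_sd, noise_sd = noise_sd,
    alpha_peak_mean = alpha_peak_mean, alpha_peak_sd = alpha_peak_sd,
    demographic_effect = demographic_effect, n_planted = n_planted,
    seed = seed
  )
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  num_fields <- c("n_subjects", "n_sessions", "n_rois", "fs", "duration",
                  "sigma_between", "sigma_within", "n_latents", "coupling_sd",
                  "noise_sd", "alpha_peak_mean", "alpha_peak_sd",
                  "demographic_effect", "n_planted", "seed")
  for (f in num_fields) {
    if (!is.numeric(cfg[[f]]) || !all(is.finite(cfg[[f]]))) {
      abort(sprintf("Config field `%s` must be finite numeric.", f))
    }
  }
  for (f in c("n_subjects", "n_sessions", "n_rois", "n_latents", "n_planted",
              "seed")) {
    if (!is_count(cfg[[f]])) abort(sprintf("Config field `%s` must be a count.", f))
  }
  if (cfg$n_subjects < 2) abort("Config field `n_subjects` must be at least 2.")
  if (cfg$n_sessions < 1) abort("Config field `n_sessions` must be at least 1.")
  b <- nrow(cfg$bands)
  if (b > 0 && any(cfg$bands$f_lo >= cfg$bands$f_hi)) {
    abort("Config field `bands`: every band needs f_lo < f_hi.")
  }
  if (b > 0 && any(cfg$bands$f_hi >= cfg$fs / 2)) {
    abort(sprintf(
      "Config field `bands`: band '%s' reaches the Nyquist frequency %g Hz; raise `fs` or drop the band.",
      cfg$bands$name[which(cfg$bands$f_hi >= cfg$fs / 2)[1]], cfg$fs / 2))
  }
  for (f in c("sigma_between", "sigma_within", "coupling_sd", "noise_sd",
              "alpha_peak_sd")) {
    if (any(cfg[[f]] < 0)) abort(sprintf("Config field `%s` must be >= 0.", f))
  }
  n_time <- cfg$duration * cfg$fs
  if (abs(n_time - round(n_time)) > 1e-8) {
    abort("Config fields `duration` x `fs` must give an integer sample count.")
  }
  if (b > 0) {
    cfg$sigma_between <- rep_len(cfg$sigma_between, b)
    cfg$sigma_within <- rep_len(cfg$sigma_within, b)
    if (is.null(cfg$band_log_mean)) {
      fc <- sqrt(cfg$bands$f_lo * cfg$bands$f_hi)
      cfg$band_log_mean <- -0.5 * log(fc / 10) # 1/f-like power profile
    } else {
      cfg$band_log_mean <- rep_len(cfg$band_log_mean, b)
    }
  } else {
    cfg$sigma_between <- numeric(0)
    cfg$sigma_within <- numeric(0)
    cfg$band_log_mean <- numeric(0)
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d subjects x %d sessions x %d ROIs, %g s at %g Hz, %d band(s), seed %d\n",
    x$n_subjects, x$n_sessions, x$n_rois, x$duration, x$fs,
    nrow(x$bands), x$seed))
  invisible(x)
}

# Band edges for subject i's carrier in band b: the alpha band is a narrow
# +/-1 Hz band around the subject's individual peak; other bands use their
# nominal edges.
carrier_edges <- function(cfg, b, alpha_peak = NULL) {
  name <- cfg$bands$name[b]
  if (identical(name, "alpha") && !is.null(alpha_peak)) {
    c(alpha_peak - 1, alpha_peak + 1)
  } else {
    c(cfg$bands$f_lo[b], cfg$bands$f_hi[b])
  }
}

#' Simulate a cohort of ROI recordings with planted subject structure
#'
#' Per subject `i`, ROI `r`, band `b`, the log-amplitude is
#' `a = band_log_mean_b + u` with `u ~ N(0, sigma_between_b)`; each session
#' adds an independent `N(0, sigma_within_b)` perturbation. The session
#' signal is the sum over bands of `exp(a)` times an independent
#' band-limited white-noise carrier (the alpha carrier is a narrow band
#' around the subject's alpha peak), plus subject-weighted shared
#' band-limited latent carriers (weights `N(0, coupling_sd)`, drifting
#' between sessions), plus white noise. Band carriers are filtered with the
#' same [bandpass()] bank the analysis uses.
#'
#' Demographics: all four variables load one shared planted latent — a
#' linear combination of `n_planted` randomly chosen (ROI, band)
#' log-amplitude features — scaled by `demographic_effect`, plus unit
#' noise; sex, handedness and clinical status are binarized by quantile
#' cuts. Artifact RMS values are drawn independently of identity.
#'
#' @param config A [synth_config()].
#' @return A `synthetic_cohort` list: `recording` ([cohort_recording()]),
#'   `demographics` (tibble), `artifacts` (tibble), `subject_params`
#'   (true log-amplitudes, alpha peaks, couplings), `planted` (true
#'   demographics-feature coupling direction and labels).
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_synth_config(config)
  n <- cfg$n_subjects
  s_n <- cfg$n_sessions
  r_n <- cfg$n_rois
  t_n <- as.integer(round(cfg$duration * cfg$fs))
  b_n <- nrow(cfg$bands)
  k_n <- if (b_n > 0) cfg$n_latents else 0L

  # subject-level structure
  sub <- withr::with_seed(child_seed(cfg$seed, 1), {
    u <- array(0, c(n, r_n, b_n))
    if (b_n > 0) {
      for (b in seq_len(b_n)) {
        u[, , b] <- rnorm(n * r_n, 0, cfg$sigma_between[b])
      }
    }
    alpha_peak <- pmin(pmax(rnorm(n, cfg$alpha_peak_mean, cfg$alpha_peak_sd),
                            2), cfg$fs / 2 - 2)
    w0 <- if (k_n > 0) {
      array(rnorm(n * r_n * k_n, 0, cfg$coupling_sd), c(n, r_n, k_n))
    } else {
      array(0, c(n, r_n, 0))
    }
    list(u = u, alpha_peak = alpha_peak, w0 = w0)
  })

  drift_rel <- if (b_n > 0) mean(cfg$sigma_within) else 0
  lat_band <- if (k_n > 0) ((seq_len(k_n) - 1) %% b_n) + 1 else integer(0)

  data <- array(0, c(n, s_n, r_n, t_n))
  counter <- 0L
  for (i in seq_len(n)) {
    for (s in seq_len(s_n)) {
      counter <- counter + 1L
      slab <- withr::with_seed(child_seed(cfg$seed, 1000 + counter), {
        x <- matrix(0, r_n, t_n)
        u_is <- sub$u[i, , , drop = FALSE]
        dim(u_is) <- c(r_n, b_n)
        if (b_n > 0) {
          for (b in seq_len(b_n)) {
            u_is[, b] <- u_is[, b] + rnorm(r_n, 0, cfg$sigma_within[b])
          }
        }
        w_is <- sub$w0[i, , , drop = FALSE]
        dim(w_is) <- c(r_n, k_n)
        if (k_n > 0) {
          w_is <- w_is + rnorm(r_n * k_n, 0, cfg$coupling_sd * drift_rel)
        }
        if (b_n > 0) {
          for (b in seq_len(b_n)) {
            edges <- carrier_edges(cfg, b, sub$alpha_peak[i])
            carrier <- bandpass(matrix(rnorm(r_n * t_n), r_n, t_n),
                                edges, cfg$fs) / band_gain(edges, cfg$fs)
            amp <- exp(cfg$band_log_mean[b] + u_is[, b])
            x <- x + amp * carrier
          }
        }
        if (k_n > 0) {
          lat <- matrix(rnorm(k_n * t_n), k_n, t_n)
          for (k in seq_len(k_n)) {
            edges <- carrier_edges(cfg, lat_band[k], sub$alpha_peak[i])
            # latent carriers scale with their band's mean amplitude, so the
            # coupled share of band power is comparable across bands
            lat[k, ] <- bandpass(lat[k, ], edges, cfg$fs) /
              band_gain(edges, cfg$fs) *
              exp(cfg$band_log_mean[lat_band[k]])
          }
          x <- x + w_is %*% lat
        }
        if (cfg$noise_sd > 0) {
          x <- x + cfg$noise_sd * matrix(rnorm(r_n * t_n), r_n, t_n)
        }
        x
      })
      data[i, s, , ] <- slab
    }
  }

  feature_labels <- if (b_n > 0) {
    paste0(rep(sprintf("roi%03d", seq_len(r_n)), times = b_n), ".",
           rep(cfg$bands$name, each = r_n))
  } else {
    character(0)
  }

  demo <- withr::with_seed(child_seed(cfg$seed, 2), {
    n_feat <- r_n * b_n
    beta <- numeric(n_feat)
    z <- numeric(n)
    if (n_feat > 0 && cfg$n_planted > 0) {
      planted_idx <- sample.int(n_feat, min(cfg$n_planted, n_feat))
      beta[planted_idx] <- rnorm(length(planted_idx))
      feat <- sub$u
      dim(feat) <- c(n, n_feat)
      raw <- as.numeric(feat %*% beta)
      if (sd(raw) > 0) z <- as.numeric(scale(raw))
    }
    mk <- function() cfg$demographic_effect * z + rnorm(n)
    raw_age <- mk(); raw_sex <- mk(); raw_hand <- mk(); raw_clin <- mk()
    tibble(
      subject_id = sprintf("sub%03d", seq_len(n)),
      age = 45 + 14 * as.numeric(scale(raw_age)),
      sex = as.integer(raw_sex > median(raw_sex)),
      handedness = as.integer(raw_hand > quantile(raw_hand, 0.85)),
      clinical_status = as.integer(raw_clin > quantile(raw_clin, 0.7))
    ) -> d
    list(table = d, beta = beta, latent = z)
  })

  artifacts <- withr::with_seed(child_seed(cfg$seed, 3), {
    tibble(
      subject_id = sprintf("sub%03d", seq_len(n)),
      rms_cardiac = stats::rlnorm(n, log(50), 0.3),
      rms_ocular = stats::rlnorm(n, log(30), 0.4),
      rms_motion = stats::rlnorm(n, log(1), 0.5),
      scan_duration = cfg$duration * runif(n, 0.9, 1.1)
    )
  })

  structure(
    list(
      recording = cohort_recording(data, cfg$fs),
      demographics = demo$table,
      artifacts = artifacts,
      subject_params = list(log_amp = sub$u, alpha_peak = sub$alpha_peak,
                            coupling = sub$w0),
      planted = list(direction = demo$beta, feature_labels = feature_labels,
                     latent = demo$latent),
      config = cfg
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  print(x$recording)
  cat(sprintf("  demographics: %d x %d; artifacts: %d x %d; demographic_effect = %g\n",
              nrow(x$demographics), ncol(x$demographics),
              nrow(x$artifacts), ncol(x$artifacts),
              x$config$demographic_effect))
  invisible(x)
}

#' Simulate empty-room analog recordings
#'
#' One pseudo-recording per subject and session with the cohort's average
#' spectral profile but no subject-specific structure: every pseudo-subject
#' uses the same deterministic per-band amplitude, set so that expected band
#' power equals the cohort mean — the root-mean-square amplitude
#' `exp(band_log_mean + sigma_between^2 + sigma_within^2)` plus the latent
#' carriers' per-band power contribution folded in (no coupling structure
#' is generated, so no recording carries any identity information). The
#' alpha carrier sits at the population mean peak. The output has the same
#' shape as the cohort recording and is processed identically downstream.
#'
#' @param config A [synth_config()].
#' @return A [cohort_recording()] of the same shape as the cohort's.
#' @export
simulate_empty_room <- function(config) {
  cfg <- validate_synth_config(config)
  n <- cfg$n_subjects
  s_n <- cfg$n_sessions
  r_n <- cfg$n_rois
  t_n <- as.integer(round(cfg$duration * cfg$fs))
  b_n <- nrow(cfg$bands)
  k_n <- if (b_n > 0) cfg$n_latents else 0L
  drift_rel <- if (b_n > 0) mean(cfg$sigma_within) else 0
  lat_band <- if (k_n > 0) ((seq_len(k_n) - 1) %% b_n) + 1 else integer(0)
  amp_er <- if (b_n > 0) {
    # cohort mean band power: E[exp(2a)] for the log-normal amplitude plus
    # the per-band latent contribution (n latents in the band x weight
    # variance including session drift)
    m_b <- tabulate(lat_band, nbins = b_n)
    w_var <- cfg$coupling_sd^2 * (1 + drift_rel^2)
    exp(cfg$band_log_mean) *
      sqrt(exp(2 * (cfg$sigma_between^2 + cfg$sigma_within^2)) + m_b * w_var)
  } else {
    numeric(0)
  }

  data <- array(0, c(n, s_n, r_n, t_n))
  counter <- 0L
  for (i in seq_len(n)) {
    for (s in seq_len(s_n)) {
      counter <- counter + 1L
      slab <- withr::with_seed(child_seed(cfg$seed, 500000 + counter), {
        x <- matrix(0, r_n, t_n)
        if (b_n > 0) {
          for (b in seq_len(b_n)) {
            edges <- carrier_edges(cfg, b, cfg$alpha_peak_mean)
            carrier <- bandpass(matrix(rnorm(r_n * t_n), r_n, t_n),
                                edges, cfg$fs) / band_gain(edges, cfg$fs)
            x <- x + amp_er[b] * carrier
          }
        }
        if (cfg$noise_sd > 0) {
          x <- x + cfg$noise_sd * matrix(rnorm(r_n * t_n), r_n, t_n)
        }
        x
      })
      data[i, s, , ] <- slab
    }
  }
  cohort_recording(data, cfg$fs,
                   subject_ids = sprintf("empty%03d", seq_len(n)))
}
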