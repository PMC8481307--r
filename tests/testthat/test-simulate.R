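test_that("identical config and seed reproduce bit-identical output", {
  cfg <- small_config(n_subjects = 3, n_rois = 3, duration = 8, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$artifacts, b$artifacts)
  e1 <- simulate_empty_room(cfg)
  e2 <- simulate_empty_room(cfg)
  expect_identical(e1$data, e2$data)
  # a different seed changes the data
  cfg2 <- small_config(n_subjects = 3, n_rois = 3, duration = 8, seed = 100)
  expect_false(identical(simulate_cohort(cfg2)$recording$data,
                         a$recording$data))
})

test_that("config validation names the offending field", {
  expect_error(small_config(n_subjects = 1), "n_subjects")
  expect_error(small_config(noise_sd = -1), "noise_sd")
  expect_error(small_config(fs = NA_real_), "fs")
  expect_error(small_config(duration = 10.0001), "integer sample count")
  expect_error(synth_config(n_subjects = 4, fs = 300), "Nyquist")
  bad_bands <- tibble::tibble(name = "x", f_lo = 10, f_hi = 5)
  expect_error(small_config(bands = bad_bands), "f_lo < f_hi")
})

test_that("zero between-subject variance gives identical subject parameters", {
  cfg <- small_config(n_subjects = 4, n_rois = 3, duration = 8,
                      sigma_between = 0, coupling_sd = 0, noise_sd = 0,
                      alpha_peak_sd = 0, seed = 5)
  cohort <- simulate_cohort(cfg)
  u <- cohort$subject_params$log_amp
  expect_true(all(u == 0)) # no between-subject amplitude deviations
  expect_true(all(cohort$subject_params$coupling == 0))
  expect_equal(length(unique(cohort$subject_params$alpha_peak)), 1L)
})

test_that("no carriers and no noise give an all-zero empty room", {
  cfg <- synth_config(n_subjects = 2, n_sessions = 1, n_rois = 2, fs = 100,
                      duration = 4, bands = meg_bands()[0, ],
                      n_latents = 0, coupling_sd = 0, noise_sd = 0, seed = 1)
  er <- simulate_empty_room(cfg)
  expect_true(all(er$data == 0))
  co <- simulate_cohort(cfg)
  expect_true(all(co$recording$data == 0))
})

test_that("demographics and artifacts tables are complete and in range", {
  cfg <- small_config(n_subjects = 10, n_rois = 3, duration = 8, seed = 6)
  cohort <- simulate_cohort(cfg)
  d <- cohort$demographics
  expect_equal(nrow(d), 10)
  expect_false(anyNA(d))
  expect_true(all(d$sex %in% 0:1))
  expect_true(all(d$handedness %in% 0:1))
  expect_true(all(d$clinical_status %in% 0:1))
  a <- cohort$artifacts
  expect_true(all(a$rms_cardiac >= 0 & a$rms_ocular >= 0 & a$rms_motion >= 0))
  expect_true(all(a$scan_duration > 0))
})

test_that("planted coupling direction is returned and scales with effect", {
  cfg0 <- small_config(n_subjects = 20, n_rois = 4, duration = 8,
                       demographic_effect = 0, seed = 7)
  cfg2 <- small_config(n_subjects = 20, n_rois = 4, duration = 8,
                       demographic_effect = 3, seed = 7)
  c0 <- simulate_cohort(cfg0)
  c2 <- simulate_cohort(cfg2)
  expect_length(c2$planted$direction, 4 * nrow(test_bands()))
  expect_identical(c0$planted$direction, c2$planted$direction)
  # with a strong effect the continuous demographic tracks the latent
  expect_gt(abs(cor(c2$demographics$age, c2$planted$latent)), 0.8)
  expect_lt(abs(cor(c0$demographics$age, c0$planted$latent)), 0.5)
})

test_that("empty-room band power matches the cohort mean profile", {
  cfg <- synth_config(n_subjects = 12, n_sessions = 1, n_rois = 4, fs = 300,
                      duration = 60, bands = test_bands(),
                      sigma_between = 0.1, sigma_within = 0.05,
                      coupling_sd = 0.5, noise_sd = 0.3, seed = 8)
  cohort <- simulate_cohort(cfg)
  er <- simulate_empty_room(cfg)
  bp_of <- function(rec) {
    d <- dim(rec$data)
    out <- matrix(0, d[1], nrow(test_bands()) * d[3])
    for (i in seq_len(d[1])) {
      x <- rec$data[i, 1, , ]
      p <- welch_psd(x, rec$fs)
      bp <- band_power(p, test_bands())
      out[i, ] <- bp$power
    }
    band_lab <- rep(test_bands()$name, each = d[3])
    tapply(colMeans(out), band_lab, mean)[test_bands()$name]
  }
  cohort_bp <- bp_of(cohort$recording)
  er_bp <- bp_of(er)
  rel_err <- abs(er_bp - cohort_bp) / cohort_bp
  expect_true(all(rel_err < 0.1))
})
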