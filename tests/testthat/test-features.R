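test_that("connectome vectorization gives row-major upper triangle", {
  r <- 68
  m <- matrix(0, r, r)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  m[idx] <- seq_len(nrow(idx))
  m <- m + t(m)
  diag(m) <- 1
  cn <- structure(list(values = m, roi_labels = paste0("r", 1:r),
                       band = "broadband"), class = "connectome")
  v <- vectorize_features(cn)
  expect_length(v, 68 * 67 / 2) # 2278
  expect_identical(names(v)[1], "r1--r2")
  expect_identical(names(v)[r - 1], "r1--r68")
  expect_identical(names(v)[r], "r2--r3")
  # round trip restores the matrix exactly
  expect_identical(connectome_from_edges(unname(v), r), m)
})

test_that("PSD vectorization concatenates per-ROI bins and respects bands", {
  freqs <- seq(0, 150, by = 0.5)
  p <- structure(
    list(values = matrix(seq_len(68 * 301), 68, 301, byrow = TRUE),
         freqs = freqs, roi_labels = paste0("r", 1:68), fs = 600),
    class = "psd_profile")
  v <- vectorize_features(p)
  expect_length(v, 68 * 301) # 20468
  expect_equal(as.numeric(v[1:301]), as.numeric(1:301), ignore_attr = TRUE)
  va <- vectorize_features(p, band = "alpha")
  expect_length(va, 68 * sum(freqs >= 8 & freqs <= 13))
  expect_error(vectorize_features(p, band = c(200, 220)), "no bins")
})

test_that("segmentation schemes produce the documented datasets", {
  fs <- 100
  rec <- cohort_recording(array(rnorm(2 * 1 * 3 * fs * 300),
                                c(2, 1, 3, fs * 300)), fs)
  halves <- segment_recording(rec, "within_halves")
  expect_named(halves, c("ses01_h1", "ses01_h2"))
  expect_equal(dim(halves[[1]]$data)[3], fs * 150)
  segs <- segment_recording(rec, "segments_30s")
  expect_named(segs, c("ses01_g1", "ses01_g2", "ses01_g3"))
  expect_equal(dim(segs[[2]]$data)[3], fs * 30)
  # segments tile the start of the recording; the rest is discarded
  expect_equal(segs[[1]]$data[1, 1, ], rec$data[1, 1, 1, 1:(fs * 30)])
  expect_equal(segs[[3]]$data[1, 1, ], rec$data[1, 1, 1, (fs * 60 + 1):(fs * 90)])

  short <- cohort_recording(array(rnorm(2 * 1 * 3 * fs * 89),
                                  c(2, 1, 3, fs * 89)), fs)
  expect_error(segment_recording(short, "segments_30s"), "90 s required")
})

test_that("extract_features returns labelled per-subject rows", {
  fs <- 300
  rec <- cohort_recording(array(rnorm(3 * 1 * 4 * fs * 10),
                                c(3, 1, 4, fs * 10)), fs)
  ds <- segment_recording(rec, "within_halves")[[1]]
  fc <- extract_features(ds, "connectome", band = "alpha")
  expect_s3_class(fc, "feature_matrix")
  expect_identical(dim(fc$values), c(3L, 6L))
  fp <- extract_features(ds, "spectral")
  expect_identical(nrow(fp$values), 3L)
  expect_identical(ncol(fp$values), length(fp$feature_labels))
  # spectral row equals the direct welch_psd + vectorize path
  x <- rec$data[2, 1, , 1:(fs * 5)]
  expect_equal(unname(fp$values[2, ]),
               unname(vectorize_features(
                 welch_psd(x, fs, roi_labels = ds$roi_labels))),
               tolerance = 1e-12)
})
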