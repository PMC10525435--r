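test_that("subject exclusion follows the age and missing-label rules", {
  mk <- function(id, age, miss_frac) {
    n_rr <- 20
    mask <- rep(FALSE, n_rr)
    if (miss_frac > 0) mask[seq_len(round(miss_frac * n_rr))] <- TRUE
    subject_record(id, "capnobase", age, rnorm(20 * 125), rnorm(20 * 125),
                   125, rep(15, n_rr), 1,
                   rr_missing_mask = if (any(mask)) mask else NULL)
  }
  recs <- list(mk("age5", 5.0, 0), mk("age6", 6.0, 0),
               mk("miss80", 40, 0.80), mk("miss75", 40, 0.75))
  kept <- exclude_subjects(recs, preprocess_params())
  expect_identical(vapply(kept, `[[`, "", "subject_id"), c("age6", "miss75"))
  expect_identical(exclude_subjects(list(), preprocess_params()), list())
})

test_that("resampling preserves length arithmetic, identity, and tone frequency", {
  x <- sin(2 * pi * 0.3 * seq(0, 8 - 1 / 300, by = 1 / 300))
  expect_length(x, 2400)
  y <- resample_signal(x, 300, 125)
  expect_length(y, 1000)
  expect_identical(resample_signal(x, 300, 300), x)
  # FFT peak still within one bin of 0.3 Hz, >= 95% amplitude retained
  spec <- Mod(stats::fft(y))[2:(length(y) / 2)]
  expect_lt(abs(which.max(spec) / 8 - 0.3), 1 / 8 + 1e-9)
  expect_gt(max(abs(y[100:900])), 0.95)
  expect_error(resample_signal(c(1, NaN), 300, 125), class = "transrr_data_error")
})

test_that("the respiratory band-pass rejects DC and keeps its passband contract", {
  p <- preprocess_params()
  fs <- 125
  t <- seq(0, 480 - 1 / fs, by = 1 / fs)
  const <- rep(2.5, length(t))
  expect_lt(max(abs(bandpass_respiratory(const, fs, p))), 1e-6 * 2.5)
  inner <- (60 * fs):(420 * fs)
  g03 <- max(abs(bandpass_respiratory(sin(2 * pi * 0.3 * t), fs, p)[inner]))
  expect_gte(g03, 0.9)
  expect_lte(g03, 1.1)
  g12 <- max(abs(bandpass_respiratory(sin(2 * pi * 1.2 * t), fs, p)[inner]))
  expect_lt(g12, 0.1)
  expect_length(bandpass_respiratory(sin(t), fs, p), length(t))
  expect_error(bandpass_respiratory(sin(t), fs, preprocess_params(band = c(0.1, 70))),
               class = "transrr_parameter_error")
})

test_that("VMD reconstructs a two-tone signal and drops the artifact-bearing mode", {
  fs <- 125
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  set.seed(8)
  x <- sin(2 * pi * 0.3 * t) + 0.8 * sin(2 * pi * 0.5 * t) + rnorm(length(t), 0, 0.02)
  dec <- vmd_decompose(x, K = 5, alpha = 2000)
  expect_equal(dim(dec$modes), c(length(x), 5))
  expect_false(is.unsorted(dec$omega))
  resid <- sqrt(sum((x - rowSums(dec$modes))^2) / sum(x^2))
  expect_lt(resid, 0.05)
  # denoising keeps length and strictly improves correlation with the
  # clean respiratory component under a high-frequency artifact
  clean <- sin(2 * pi * 0.3 * t)
  noisy <- clean + 0.5 * sin(2 * pi * 20 * t)
  den <- vmd_denoise(noisy, preprocess_params())
  expect_length(den, length(noisy))
  expect_gt(cor(den, clean), cor(noisy, clean))
  expect_error(vmd_decompose(c(1, 2, 3), K = 5), class = "transrr_parameter_error")
})

test_that("z-scoring uses the population convention and is idempotent", {
  expect_equal(zscore(c(1, 2, 3)), c(-sqrt(3 / 2), 0, sqrt(3 / 2)))
  set.seed(2)
  x <- rnorm(500, 7, 3)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  expect_equal(zscore(z), z)
  expect_error(zscore(rep(4, 10), subject_id = "s9"), "s9",
               class = "transrr_degenerate_signal_error")
})

test_that("window counts follow the stride formula across durations and overlaps", {
  p <- preprocess_params()
  mk <- function(dur) {
    n <- round(dur * 125)
    subject_record("w", "synthetic", 30, rnorm(n), rnorm(n), 125,
                   rep(15, round(dur)), 1)
  }
  expect_equal(n_segments(segment_subject(mk(480), p)), 233)
  expect_equal(n_segments(segment_subject(mk(32), p)), 9)
  expect_equal(n_segments(segment_subject(mk(8), p)), 0)
  # property: formula vs brute-force enumeration of admissible start times
  for (dur in c(16, 17, 30, 61.5, 100)) {
    for (ov in c(0, 0.5, 0.875)) {
      pp <- preprocess_params(overlap = ov)
      stride <- pp$window_s * (1 - ov)
      brute <- sum((seq(0, 1000, by = stride) + pp$window_s) <= dur + 1e-9)
      expect_equal(n_segments(segment_subject(mk(dur), pp)), brute,
                   info = sprintf("dur=%g overlap=%g", dur, ov))
    }
  }
})

test_that("window labels average the covered RR samples and skip missing stretches", {
  n <- 40 * 125
  rr <- rep(c(10, 20), each = 20)     # 10 b/m for 20 s then 20 b/m
  rec <- subject_record("lab", "synthetic", 30, rnorm(n), rnorm(n), 125, rr, 1)
  segs <- segment_subject(rec, preprocess_params())
  expect_equal(n_segments(segs), 13)
  expect_equal(segs$rr_label[1], 10)         # window fully inside the 10 b/m half
  expect_equal(ncol(segs$ecg), 250)
  # the window covering seconds 4..20 mixes 4 tens and 12 twenties... check one
  expect_equal(segs$rr_label[3], mean(rr[(4 + 1):(4 + 16)]))
  # a missing RR sample knocks out every window covering it
  mask <- rep(FALSE, 40); mask[25] <- TRUE
  rec2 <- subject_record("lab2", "synthetic", 30, rec$ecg, rec$ppg, 125, rr, 1,
                         rr_missing_mask = mask)
  segs2 <- segment_subject(rec2, preprocess_params())
  covered <- vapply(seq_len(13), function(i) {
    start <- (i - 1) * 2
    24 >= start && 24 < start + 16     # second index 24 = sample 25
  }, logical(1))
  expect_equal(n_segments(segs2), sum(!covered))
})

test_that("RR range filtering keeps the strict interior of (5, 30)", {
  s <- segment_set(matrix(0, 6, 10), matrix(0, 6, 10),
                   c(5.0, 30.0, 5.1, 29.9, 4, 18), rep("x", 6), "")
  kept <- filter_rr_range(s, preprocess_params())
  expect_equal(kept$rr_label, c(5.1, 29.9, 18))
  s2 <- segment_set(matrix(0, 4, 10), matrix(0, 4, 10), c(4, 12, 18, 31),
                    rep("x", 4), "")
  expect_equal(n_segments(filter_rr_range(s2, preprocess_params())), 2)
})

test_that("the full pipeline is deterministic, excludes minors, and recovers fixed RR labels", {
  cfg <- synthetic_config(n_subjects = 2, duration_s = 120, rr_drift_sd = 0,
                          rr_range = c(15, 15), noise_sd = 0.02, seed = 31)
  cohort <- generate_cohort(cfg)
  cohort[[2]]$age <- 4          # should contribute nothing
  p <- preprocess_params()
  set1 <- preprocess_dataset(cohort, p)
  set2 <- preprocess_dataset(cohort, p)
  expect_identical(set1, set2)
  expect_equal(n_segments(set1), 53)   # one 120 s subject
  expect_identical(unique(set1$subject_id), "syn_000")
  expect_true(all(abs(set1$rr_label - 15) < 0.5))
  # per-subject per-channel moments after the pipeline's z-score
  cohort1 <- cohort[1]
  rec <- cohort1[[1]]
  cleaned <- zscore(vmd_denoise(bandpass_respiratory(rec$ecg, 125, p), p))
  expect_lt(abs(mean(cleaned)), 1e-9)
  expect_lt(abs(sqrt(mean((cleaned - mean(cleaned))^2)) - 1), 1e-9)
})

test_that("reference RR traces at other rates are resampled to the 1 Hz grid", {
  cfg <- synthetic_config(n_subjects = 1, duration_s = 120, rr_drift_sd = 0,
                          rr_range = c(15, 15), noise_sd = 0, seed = 17)
  rec <- generate_cohort(cfg)[[1]]
  # re-express the exact 1 Hz reference on a 2 Hz grid
  rec2 <- rec
  rec2$rr_ref <- rep(rec$rr_ref, each = 2)
  rec2$fs_rr <- 2
  set1 <- preprocess_dataset(list(rec), preprocess_params())
  set2 <- preprocess_dataset(list(rec2), preprocess_params())
  expect_equal(n_segments(set2), n_segments(set1))
  expect_equal(set2$rr_label, set1$rr_label, tolerance = 1e-9)
})

test_that("the no-zscore ablation leaves window amplitudes unnormalized", {
  cfg <- synthetic_config(n_subjects = 1, duration_s = 120, rr_drift_sd = 0,
                          rr_range = c(15, 15), noise_sd = 0, seed = 13)
  coh <- generate_cohort(cfg)
  with_z <- preprocess_dataset(coh, preprocess_params())
  without_z <- preprocess_dataset(coh, preprocess_params(zscore = FALSE))
  expect_equal(n_segments(with_z), n_segments(without_z))
  expect_false(isTRUE(all.equal(sd(with_z$ecg[1, ]), sd(without_z$ecg[1, ]))))
})
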