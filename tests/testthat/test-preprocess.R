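# Recording harmonization and the RMS artifact mask.

test_that("read_recording rejects unusable files with structured reasons", {
  h <- hypnogram(rep("N2", 10))
  hp <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram_csv(h, hp)
  p <- withr::local_tempfile(fileext = ".edf")

  write_edf(p, list(C3 = rnorm(3000), M2 = rnorm(3000)), fs = 10)
  err <- tryCatch(read_recording(p, hp), condition = function(c) c)
  expect_s3_class(err, "unusable_recording")
  expect_match(conditionMessage(err), "C4")

  write_edf(p, list(C3 = rnorm(3000), C3 = rnorm(3000), C4 = rnorm(3000),
                    M1 = rnorm(3000), M2 = rnorm(3000)), fs = 10)
  expect_error(read_recording(p, hp), "duplicate")

  # invalid stage labels in the annotation are a parse error
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(epoch_index = 1:3, stage = c("W", "N9", "R")),
                   bad, row.names = FALSE)
  write_edf(p, list(C3 = rnorm(3000), C4 = rnorm(3000),
                    M1 = rnorm(3000), M2 = rnorm(3000)), fs = 10)
  expect_error(read_recording(p, bad), "invalid stage")
})

test_that("contralateral re-reference equals the element-wise difference", {
  set.seed(4)
  n <- 1000
  ch <- list(C3 = rnorm(n), C4 = rnorm(n), M1 = rnorm(n), M2 = rnorm(n))
  rec <- eeg_recording(ch, 100)
  rr <- rereference_contralateral(rec)
  expect_named(rr$channels, c("C3", "C4"))
  # brute-force oracle
  c3 <- numeric(n); c4 <- numeric(n)
  for (i in seq_len(n)) {
    c3[i] <- ch$C3[i] - ch$M2[i]
    c4[i] <- ch$C4[i] - ch$M1[i]
  }
  expect_equal(rr$channels$C3, c3)
  expect_equal(rr$channels$C4, c4)

  rec2 <- eeg_recording(list(C3 = rep(5, n), C4 = rnorm(n),
                             M1 = rnorm(n), M2 = rep(2, n)), 100)
  expect_equal(unique(rereference_contralateral(rec2)$channels$C3), 3)
  expect_error(rereference_contralateral(
    eeg_recording(list(C3 = rnorm(n), C4 = rnorm(n), M1 = rnorm(n)), 100)),
    "M2")
})

test_that("resample_to_target passes 200 Hz through and doubles 100 Hz", {
  rec <- tone_recording(10, 50, fs = 200, dur_s = 10)
  expect_identical(resample_to_target(rec, 200), rec)
  rec100 <- tone_recording(10, 50, fs = 100, dur_s = 10)
  up <- resample_to_target(rec100, 200)
  expect_equal(up$fs, 200)
  expect_length(up$channels$C3, 2 * length(rec100$channels$C3))
  expect_equal(fft_amp(up$channels$C3, 200, 10), 50, tolerance = 0.5)
  expect_error(resample_to_target(rec, -1), "positive")
})

test_that("high-pass removes DC and drift but preserves the passband", {
  fs <- 200
  t <- seq_len(fs * 60) / fs
  rec <- eeg_recording(
    list(C3 = 100 + 30 * sin(2 * pi * 0.1 * t) + 50 * sin(2 * pi * 10 * t)),
    fs)
  hp <- highpass_filter(rec, 0.5)
  x <- hp$channels$C3[(10 * fs):(50 * fs)]  # avoid edge transients
  expect_lt(abs(mean(x)), 1)
  expect_equal(fft_amp(x, fs, 10), 50, tolerance = 50 * 0.12)  # 1 dB
  expect_lt(fft_amp(x, fs, 0.1), 30 * 10^(-20 / 20))           # >= 20 dB
  expect_error(highpass_filter(rec, 150), "Nyquist")
})

test_that("preprocess_recording enforces the fixed pipeline order and flag", {
  set.seed(8)
  raw <- noise_recording(rms = 30, dur_s = 30)
  rec <- preprocess_recording(raw)
  expect_true(rec$preprocessed)
  expect_named(rec$channels, c("C3", "C4"))
  expect_equal(rec$fs, 200)
  # downstream consumers refuse un-preprocessed input
  expect_error(multitaper_band_powers(raw), "preprocess_recording")
  expect_error(window_band_powers_3s(raw), "preprocess_recording")
  expect_error(prepare_signal(raw), "preprocess_recording")
  # content above the 50 Hz band limit is gone
  n <- length(rec$channels$C3)
  sp <- Mod(stats::fft(rec$channels$C3))[seq_len(n %/% 2)]
  fr <- (seq_len(n %/% 2) - 1) * 200 / n
  expect_lt(mean(sp[fr > 60]) / mean(sp[fr > 5 & fr < 45]), 0.01)
  expect_error(preprocess_recording(noise_recording(fs = 50)), ">= 100")
})

test_that("rms_artifact_mask flags exactly the out-of-range segments", {
  set.seed(5)
  rec <- eeg_recording(list(C3 = rep(0, 3000)), 100)
  m <- rms_artifact_mask(rec)
  expect_true(all(m$flagged))                       # RMS 0 <= 1
  expect_equal(ncol(m$flagged), 10)

  rec2 <- eeg_recording(list(C3 = 50 * rnorm(30000)), 100)
  m2 <- rms_artifact_mask(rec2)
  expect_false(any(m2$flagged))                     # physiological range
  expect_equal(m2$fraction_flagged, 0)

  x <- 50 * rnorm(30000)
  x[601:900] <- 400 * rnorm(300)                    # segment 3 of 3-s grid
  m3 <- rms_artifact_mask(eeg_recording(list(C3 = x), 100))
  expect_identical(which(m3$flagged[1, ]), 3L)

  # idempotent and hypnogram-independent: same input, same mask
  expect_identical(m3$flagged,
                   rms_artifact_mask(eeg_recording(list(C3 = x), 100))$flagged)
})

test_that("injected artifacts are recovered by the mask (ground truth)", {
  set.seed(6)
  rec <- eeg_recording(list(C3 = 50 * rnorm(12000), C4 = 50 * rnorm(12000)),
                       100)
  inj <- inject_artifacts(rec, n_flat = 2, n_high = 3, seed = 9)
  m <- rms_artifact_mask(inj$recording)
  flagged_segs <- which(apply(m$flagged, 2, any))
  planted_segs <- inj$intervals$start_s / 3 + 1
  expect_setequal(flagged_segs, planted_segs)
  # flat segments really are flat
  fl <- inj$intervals[inj$intervals$type == "flat", ][1, ]
  idx <- (fl$start_s * 100 + 1):(fl$end_s * 100)
  expect_lte(sqrt(mean(inj$recording$channels$C3[idx]^2)), 1)
  # identity when no artifacts requested
  same <- inject_artifacts(rec, 0, 0)
  expect_identical(same$recording$channels, rec$channels)
  expect_error(inject_artifacts(rec, 100, 100), "too short")
})
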