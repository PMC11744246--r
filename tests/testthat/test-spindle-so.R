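# Spindle and slow-oscillation detection against planted ground truth and
# closed-form oracles.

test_that("prepare_signal outputs 128 Hz with a 35 Hz band limit", {
  rec10 <- tone_recording(10, 50, fs = 200, dur_s = 30, preprocessed = TRUE)
  p10 <- prepare_signal(rec10)
  expect_equal(p10$fs, 128)
  expect_equal(fft_amp(p10$channels$C3, 128, 10), 50, tolerance = 50 * 0.12)
  rec45 <- tone_recording(45, 50, fs = 200, dur_s = 30, preprocessed = TRUE)
  p45 <- prepare_signal(rec45)
  expect_lt(fft_amp(p45$channels$C3, 128, 45), 50 * 10^(-20 / 20))
})

test_that("delta artifact mask rejects only strong delta outliers", {
  set.seed(31)
  n <- 128 * 30 * 15
  x <- 30 * rnorm(n)
  rec <- eeg_recording(list(C3 = x), 128, preprocessed = TRUE)
  h <- hypnogram(rep("N2", 15))
  expect_false(any(delta_artifact_epoch_mask(rec, h)))  # homogeneous

  t <- seq_len(n) / 128
  burst <- 10 * 30 * sin(2 * pi * 2 * t) *
    (t > 8 * 30 & t <= 9 * 30)                          # epoch 9, 10x delta
  rec2 <- eeg_recording(list(C3 = x + burst), 128, preprocessed = TRUE)
  rej <- delta_artifact_epoch_mask(rec2, h)
  expect_true(rej[9])
  expect_equal(sum(rej), 1)
})

test_that("spindle detector recovers planted bursts (recall/precision)", {
  fx <- n2_fixture(n_epochs = 60, seed = 11)
  sf <- spindle_features(fx$rec, fx$h)
  for (ch in c("C3", "C4")) {
    sc <- detection_scores(sf$spindles[sf$spindles$channel == ch, ],
                           fx$gt$spindles[fx$gt$spindles$channel == ch, ])
    expect_gte(sc$recall, 0.9)
    expect_gte(sc$precision, 0.9)
  }
})

test_that("merge and rejection rules behave on constructed bursts", {
  fs <- 200
  make_rec <- function(bursts) {
    t <- seq_len(fs * 90) / fs
    x <- 3 * rnorm(length(t))
    for (b in bursts) {
      on <- t >= b[1] & t < b[2]
      x[on] <- x[on] + 30 * sin(2 * pi * 13.5 * t[on])
    }
    eeg_recording(list(C3 = x), fs, preprocessed = TRUE)
  }
  h <- hypnogram(rep("N2", 3))
  set.seed(32)
  # two bursts separated by 0.4 s -> one merged event
  rec <- make_rec(list(c(30, 31), c(31.4, 32.4)))
  prep <- prepare_signal(rec)
  ev <- detect_spindles(prep, h, n2_epochs = 1:3)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$start_s, 30.5)
  expect_gt(ev$end_s, 32)

  # a continuous 3.5-s burst -> rejected entirely
  rec2 <- make_rec(list(c(30, 33.5)))
  ev2 <- detect_spindles(prepare_signal(rec2), h, n2_epochs = 1:3)
  expect_equal(nrow(ev2), 0)

  # isolated 1-s burst at 6x background -> exactly one event, >= 80% overlap
  rec3 <- make_rec(list(c(45, 46)))
  ev3 <- detect_spindles(prepare_signal(rec3), h, n2_epochs = 1:3)
  expect_equal(nrow(ev3), 1)
  expect_gte(interval_overlap(45, 46, ev3$start_s, ev3$end_s), 0.8)
  expect_true(ev3$peak_s >= ev3$start_s && ev3$peak_s <= ev3$end_s)

  expect_warning(out <- detect_spindles(prep, h, integer(0)), "no accepted")
  expect_equal(nrow(out), 0)
})

test_that("emitted events always satisfy the duration invariants", {
  set.seed(33)
  for (seed in c(41, 42)) {
    fx <- n2_fixture(n_epochs = 20, spindle_density = 4, so_rate = 5,
                     seed = seed)
    sf <- spindle_features(fx$rec, fx$h)
    if (nrow(sf$spindles)) {
      dur <- sf$spindles$end_s - sf$spindles$start_s
      expect_true(all(dur >= 0.3 & dur <= 3))
      expect_true(all(sf$spindles$peak_s >= sf$spindles$start_s &
                        sf$spindles$peak_s <= sf$spindles$end_s))
    }
    if (nrow(sf$sos)) {
      sdur <- sf$sos$end_s - sf$sos$start_s
      expect_true(all(sdur >= 0.8 & sdur <= 2))
    }
  }
})

test_that("SO detection matches sinusoid zero-crossing arithmetic", {
  fs <- 200
  h <- hypnogram(rep("N2", 2))
  mk <- function(f) {
    t <- seq_len(fs * 60) / fs
    eeg_recording(list(C3 = 75 * sin(2 * pi * f * t)), fs,
                  preprocessed = TRUE)
  }
  so1 <- detect_slow_oscillations(prepare_signal(mk(1)), h, 1:2)
  expect_gt(nrow(so1), 50)   # ~one per cycle inside N2
  expect_equal(unique(round(so1$end_s - so1$start_s, 2)), 1.00)
  # 3 Hz: cycles of 0.33 s -> too short; 0.4 Hz: 2.5 s -> too long
  expect_equal(nrow(detect_slow_oscillations(prepare_signal(mk(3)), h, 1:2)),
               0)
  expect_equal(nrow(detect_slow_oscillations(prepare_signal(mk(0.4)), h,
                                             1:2)), 0)
})

test_that("so_phase_at_peak is the linear map to degrees", {
  expect_equal(so_phase_at_peak(10, 10, 11.5), 0)
  expect_equal(so_phase_at_peak(10.75, 10, 11.5), 180)
  expect_equal(so_phase_at_peak(10.375, 10, 11.5), 90)
  expect_true(is.na(so_phase_at_peak(12, 10, 11.5)))
})

test_that("spindle_feature_set computes density, dispersion and phases", {
  # one spindle per epoch -> density 2/min, dispersion 0
  n2 <- 1:10
  sp <- data.frame(channel = "C3", start_s = (n2 - 1) * 30 + 10,
                   end_s = (n2 - 1) * 30 + 11,
                   peak_s = (n2 - 1) * 30 + 10.5,
                   class = "fast", peak_freq = 13.5,
                   stringsAsFactors = FALSE)
  so <- data.frame(channel = character(), start_s = numeric(),
                   end_s = numeric(), stringsAsFactors = FALSE)
  fs <- spindle_feature_set(sp, so, n2, channels = "C3")
  expect_equal(fs$value[fs$feature == "spindle_density_C3"], 2)
  expect_equal(fs$value[fs$feature == "spindle_dispersion_C3"], 0)

  # Poisson counts -> Fano factor ~ 1 (+- 0.15 at 500 epochs)
  set.seed(34)
  n2b <- 1:500
  counts <- stats::rpois(500, 1.5)
  spb <- do.call(rbind, lapply(n2b[counts > 0], function(e) {
    k <- counts[e]
    data.frame(channel = "C3",
               start_s = (e - 1) * 30 + seq_len(k) * 2,
               end_s = (e - 1) * 30 + seq_len(k) * 2 + 1,
               peak_s = (e - 1) * 30 + seq_len(k) * 2 + 0.5,
               class = "fast", peak_freq = 13.5, stringsAsFactors = FALSE)
  }))
  fsb <- spindle_feature_set(spb, so, n2b, channels = "C3")
  expect_equal(fsb$value[fsb$feature == "spindle_dispersion_C3"], 1,
               tolerance = 0.15)

  # zero spindles: density 0, dispersion and phases missing
  fs0 <- spindle_feature_set(sp[0, ], so, n2, channels = "C3")
  expect_equal(fs0$value[fs0$feature == "spindle_density_C3"], 0)
  expect_true(all(is.na(fs0$value[-1])))
  expect_error(spindle_feature_set(sp, so, integer(0)), "N2")
})

test_that("planted coupling phase is recovered by the phase features", {
  fx <- n2_fixture(n_epochs = 60, coupling_phase = 180, seed = 51)
  sf <- spindle_features(fx$rec, fx$h)
  ph <- sf$features$value[grepl("so_phase_fast", sf$features$feature)]
  ph <- ph[!is.na(ph)]
  expect_gt(length(ph), 0)
  expect_true(all(abs(ph - 180) < 25))
})
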