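# Shared fixtures: tone recordings, synthetic N2 nights, event-overlap
# scoring. Everything is generated in code at test time.

# Single- or multi-channel recording holding pure tones (uV amplitudes).
tone_recording <- function(freqs, amps, fs = 200, dur_s = 30,
                           channel = "C3", preprocessed = FALSE) {
  t <- seq_len(fs * dur_s) / fs
  x <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  eeg_recording(stats::setNames(list(x), channel), fs,
                preprocessed = preprocessed)
}

# Amplitude of frequency component f in a signal (FFT bin picking).
fft_amp <- function(x, fs, f) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  fr <- (seq_len(n %/% 2) - 1) * fs / n
  2 * sp[which.min(abs(fr - f))] / n
}

# Raw 4-channel recording (C3, C4, M1, M2) of white noise at a given RMS.
noise_recording <- function(rms = 50, fs = 200, dur_s = 60) {
  n <- fs * dur_s
  eeg_recording(list(C3 = rms * rnorm(n), C4 = rms * rnorm(n),
                     M1 = 5 * rnorm(n), M2 = 5 * rnorm(n)), fs)
}

# Fraction of the shorter interval covered by the overlap.
interval_overlap <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0)) / pmin(a1 - a0, b1 - b0)
}

# Recall/precision of detected against planted events at >= 50% overlap.
detection_scores <- function(detected, planted) {
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    any(interval_overlap(planted$start_s[i], planted$end_s[i],
                         detected$start_s, detected$end_s) >= 0.5)
  }, TRUE)
  fp <- vapply(seq_len(nrow(detected)), function(i) {
    any(interval_overlap(detected$start_s[i], detected$end_s[i],
                         planted$start_s, planted$end_s) >= 0.5)
  }, TRUE)
  list(recall = mean(hit), precision = mean(fp))
}

# Synthesized all-N2 night, preprocessed, with ground truth.
n2_fixture <- function(n_epochs = 60, spindle_density = 3, so_rate = 4,
                       coupling_phase = 250, seed = 11, ...) {
  h <- hypnogram(rep("N2", n_epochs))
  sy <- synthesize_recording(h, spindle_density = spindle_density,
                             so_rate = so_rate,
                             coupling_phase = coupling_phase,
                             sample_rate = 200, seed = seed, ...)
  list(h = h, raw = sy$recording, gt = sy$ground_truth,
       rec = preprocess_recording(sy$recording))
}
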