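# Sleep-spindle and slow-oscillation detection in N2 (Luna-convention
# thresholds) and the eight per-channel density/dispersion/phase features.

#' Prepare a recording for spindle analysis
#'
#' Resamples to 128 Hz and low-pass filters at 35 Hz (the global 0.5 Hz
#' high-pass from preprocessing is retained).
#'
#' @param rec preprocessed [eeg_recording()]
#' @param target_rate spindle-analysis rate (Hz, default 128)
#' @param lp_cutoff low-pass cutoff (Hz, default 35)
#' @return [eeg_recording()] at 128 Hz
#' @export
prepare_signal <- function(rec, target_rate = 128, lp_cutoff = 35) {
  if (!rec$preprocessed) {
    stop("recording must come from preprocess_recording()")
  }
  out <- resample_to_target(rec, target_rate)
  lowpass_filter(out, lp_cutoff, trans_hz = 8)
}

# Sample index range of one 30-s epoch (1-based, relative to lights-off).
epoch_samples <- function(e, fs, epoch_length = 30, offset_s = 0) {
  s0 <- round(((e - 1) * epoch_length + offset_s) * fs)
  seq.int(s0 + 1L, s0 + round(epoch_length * fs))
}

# Per-epoch delta-band power (periodogram integral over 0.5-4 Hz).
epoch_delta_power <- function(x, fs, n_epochs, offset_s = 0) {
  vapply(seq_len(n_epochs), function(e) {
    idx <- epoch_samples(e, fs, offset_s = offset_s)
    idx <- idx[idx <= length(x)]
    seg <- x[idx]
    n <- length(seg)
    p <- Mod(stats::fft(seg))^2 / (n * fs)
    f <- seq(0, by = fs / n, length.out = n %/% 2 + 1)
    sel <- f >= 0.5 & f < 4
    2 * sum(p[seq_len(n %/% 2 + 1)][sel]) * fs / n
  }, 0)
}

#' Delta-power artifact mask for spindle analysis
#'
#' Rejects an epoch iff its delta (0.5-4 Hz) power exceeds 2.5 times the
#' mean delta power over the centred 15-epoch sliding window (strict
#' inequality; window truncated at record edges). Computed per channel and
#' combined with OR.
#'
#' @param rec prepared [eeg_recording()] (see [prepare_signal()])
#' @param h a [hypnogram()]
#' @param ratio rejection ratio (default 2.5)
#' @param window sliding window length in epochs (default 15)
#' @return logical vector, `TRUE` = epoch rejected
#' @export
delta_artifact_epoch_mask <- function(rec, h, ratio = 2.5, window = 15L) {
  n_epochs <- h$lights_on - h$lights_off
  rejected <- rep(FALSE, n_epochs)
  half <- window %/% 2
  for (ch in rec$channels) {
    dp <- epoch_delta_power(ch, rec$fs, n_epochs, offset_s = rec$lights_off)
    for (e in seq_len(n_epochs)) {
      win <- max(1, e - half):min(n_epochs, e + half)
      if (dp[e] > ratio * mean(dp[win])) rejected[e] <- TRUE
    }
  }
  rejected
}

# Runs of TRUE in a logical vector -> matrix of (start, end) sample indices.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect sleep spindles in accepted N2 epochs
#'
#' A 13.5 Hz complex Morlet wavelet is convolved over the signal and its
#' magnitude smoothed with a 0.1-s sliding window; thresholds apply to the
#' power scale (the squared smoothed magnitude), the scale the flank rule is
#' stated on. Candidate cores are runs of at least `min_core_s` seconds with
#' power above `core_mult` times the mean power over all accepted N2 epochs;
#' over the 0.5-s window centred on the core, power must average (default)
#' or stay (`flank_stat = "min"`) at or above `flank_mult` times that mean.
#' Event boundaries are then expanded outwards to the `flank_mult` power
#' contour. Candidates separated by at most `merge_gap_s` are merged; merged
#' events longer than `max_dur_s` are rejected. The event peak is the
#' smoothed-magnitude maximum. Events are classified `slow` (dominant
#' frequency < 13 Hz) or `fast` (>= 13 Hz).
#'
#' @param rec prepared [eeg_recording()] at 128 Hz
#' @param h a [hypnogram()]
#' @param n2_epochs integer epoch indices (lights-window-relative) of
#'   accepted N2 epochs
#' @param wavelet_freq Morlet centre frequency (Hz)
#' @param n_cycles Morlet width in cycles
#' @param core_mult,flank_mult power-threshold multipliers (4.5 / 2)
#' @param min_core_s minimum core duration (s)
#' @param merge_gap_s maximum merge gap (s)
#' @param max_dur_s maximum merged duration (s)
#' @param flank_stat statistic over the 0.5-s flank window: `"mean"`
#'   (default) or `"min"`
#' @return data.frame of events: `channel`, `start_s`, `end_s`, `peak_s`
#'   (seconds from lights-off), `class`, `peak_freq`
#' @export
detect_spindles <- function(rec, h, n2_epochs, wavelet_freq = 13.5,
                            n_cycles = 7, core_mult = 4.5, flank_mult = 2,
                            min_core_s = 0.3, merge_gap_s = 0.5,
                            max_dur_s = 3, flank_stat = c("mean", "min")) {
  flank_stat <- match.arg(flank_stat)
  if (!length(n2_epochs)) {
    warning("no accepted N2 epochs; returning empty event list")
    return(empty_events())
  }
  fs <- rec$fs
  out <- list()
  n2_idx <- unlist(lapply(n2_epochs, epoch_samples, fs = fs,
                          offset_s = rec$lights_off))
  for (ci in seq_along(rec$channels)) {
    x <- rec$channels[[ci]]
    n2_idx_c <- n2_idx[n2_idx <= length(x)]
    mag <- moving_average(morlet_magnitude(x, fs, wavelet_freq, n_cycles),
                          round(0.1 * fs))
    pow <- mag^2
    n2_mean <- mean(pow[n2_idx_c])
    in_n2 <- rep(FALSE, length(x)); in_n2[n2_idx_c] <- TRUE
    core <- pow > core_mult * n2_mean & in_n2
    runs <- logical_runs(core)
    if (nrow(runs) == 0) next
    keep <- (runs[, "end"] - runs[, "start"] + 1L) >= round(min_core_s * fs)
    runs <- runs[keep, , drop = FALSE]
    if (nrow(runs) == 0) next
    half_win <- round(0.25 * fs)
    above_flank <- pow >= flank_mult * n2_mean
    ok <- vapply(seq_len(nrow(runs)), function(i) {
      ctr <- (runs[i, "start"] + runs[i, "end"]) %/% 2L
      lo <- max(1L, ctr - half_win)
      hi <- min(length(x), ctr + half_win)
      stat <- if (flank_stat == "min") min(pow[lo:hi]) else mean(pow[lo:hi])
      stat >= flank_mult * n2_mean
    }, TRUE)
    runs <- runs[ok, , drop = FALSE]
    if (nrow(runs) == 0) next
    # expand event boundaries outwards to the lower-threshold contour
    for (i in seq_len(nrow(runs))) {
      a <- runs[i, "start"]
      while (a > 1L && above_flank[a - 1L]) a <- a - 1L
      b <- runs[i, "end"]
      while (b < length(x) && above_flank[b + 1L]) b <- b + 1L
      runs[i, "start"] <- a
      runs[i, "end"] <- b
    }
    merged <- merge_runs(runs, round(merge_gap_s * fs))
    dur <- (merged[, "end"] - merged[, "start"] + 1L) / fs
    merged <- merged[dur <= max_dur_s, , drop = FALSE]
    if (nrow(merged) == 0) next
    ev <- lapply(seq_len(nrow(merged)), function(i) {
      a <- merged[i, "start"]; b <- merged[i, "end"]
      pk <- a + which.max(mag[a:b]) - 1L
      pf <- dominant_frequency(x[a:b], fs)
      data.frame(channel = names(rec$channels)[ci],
                 start_s = (a - 1) / fs, end_s = b / fs,
                 peak_s = (pk - 1) / fs,
                 class = if (pf < 13) "slow" else "fast",
                 peak_freq = pf, stringsAsFactors = FALSE)
    })
    out <- c(out, ev)
  }
  if (!length(out)) return(empty_events())
  do.call(rbind, out)
}

empty_events <- function() {
  data.frame(channel = character(), start_s = numeric(), end_s = numeric(),
             peak_s = numeric(), class = character(), peak_freq = numeric(),
             stringsAsFactors = FALSE)
}

# Merge runs whose gap (samples) is <= max_gap.
merge_runs <- function(runs, max_gap) {
  runs <- runs[order(runs[, "start"]), , drop = FALSE]
  out <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs[i, "start"] - out[nrow(out), "end"] - 1L
      if (gap <= max_gap) {
        out[nrow(out), "end"] <- max(out[nrow(out), "end"], runs[i, "end"])
      } else {
        out <- rbind(out, runs[i, , drop = FALSE])
      }
    }
  }
  out
}

# Peak frequency of a segment's periodogram within the sigma range.
dominant_frequency <- function(seg, fs, lo = 9, hi = 16) {
  n <- length(seg)
  nfft <- max(stats::nextn(n, 2L), 512L)
  p <- Mod(stats::fft(c(seg - mean(seg), numeric(nfft - n))))^2
  f <- seq(0, by = fs / nfft, length.out = nfft %/% 2 + 1)
  sel <- which(f >= lo & f <= hi)
  f[sel[which.max(p[sel])]]
}

#' Detect slow oscillations within accepted N2 epochs
#'
#' Low-pass filters the entire signal at 4.5 Hz, then marks every interval
#' between consecutive positive-to-negative zero-crossings whose length is
#' within `[0.8, 2]` s. SOs fully inside accepted N2 epochs are retained.
#'
#' @param rec prepared [eeg_recording()]
#' @param h a [hypnogram()]
#' @param n2_epochs accepted N2 epoch indices
#' @param lp_cutoff SO low-pass cutoff (Hz)
#' @param min_dur_s,max_dur_s SO duration bounds (s)
#' @return data.frame: `channel`, `start_s`, `end_s` (seconds from
#'   lights-off)
#' @export
detect_slow_oscillations <- function(rec, h, n2_epochs, lp_cutoff = 4.5,
                                     min_dur_s = 0.8, max_dur_s = 2) {
  fs <- rec$fs
  n2_idx <- unlist(lapply(n2_epochs, epoch_samples, fs = fs,
                          offset_s = rec$lights_off))
  out <- list()
  for (ci in seq_along(rec$channels)) {
    x <- filt_zero_phase(rec$channels[[ci]],
                         fir_kaiser(lp_cutoff, fs, "low", trans_hz = 2))
    pn <- which(x[-length(x)] > 0 & x[-1] <= 0)   # positive-to-negative
    if (length(pn) < 2) next
    dur <- diff(pn) / fs
    ok <- which(dur >= min_dur_s & dur <= max_dur_s)
    n2_set <- rep(FALSE, length(x)); n2_set[n2_idx[n2_idx <= length(x)]] <- TRUE
    for (i in ok) {
      a <- pn[i]; b <- pn[i + 1]
      if (all(n2_set[a:b])) {
        out[[length(out) + 1]] <- data.frame(
          channel = names(rec$channels)[ci],
          start_s = (a - 1) / fs, end_s = (b - 1) / fs,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(channel = character(), start_s = numeric(),
                      end_s = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' SO phase at a spindle peak
#'
#' Linear map of the spindle peak position within the slow oscillation to
#' an angle: `360 * (peak - so_start) / (so_end - so_start)` degrees.
#'
#' @param peak_s spindle peak time (s)
#' @param so_start,so_end SO bounds (s)
#' @return degrees in `[0, 360)`, or `NA` when the peak lies outside the SO
#' @export
so_phase_at_peak <- function(peak_s, so_start, so_end) {
  if (is.na(peak_s) || peak_s < so_start || peak_s > so_end) return(NA_real_)
  ph <- 360 * (peak_s - so_start) / (so_end - so_start)
  ph %% 360
}

# Circular mean of angles in degrees, in [0, 360).
circular_mean_deg <- function(deg) {
  if (!length(deg)) return(NA_real_)
  rad <- deg * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}

#' The eight per-channel spindle features
#'
#' Per channel (C3, C4): spindle density (events per accepted N2 minute),
#' dispersion (variance of per-epoch counts divided by their mean; a Fano
#' factor), and the circular-mean SO phase at spindle peak for fast and for
#' slow spindles. Spindles are assigned to the epoch containing their peak;
#' a spindle contributes a phase only when its peak falls inside a detected
#' SO on the same channel.
#'
#' @param spindles data.frame from [detect_spindles()]
#' @param sos data.frame from [detect_slow_oscillations()]
#' @param n2_epochs accepted N2 epoch indices
#' @param channels channel labels (default `c("C3","C4")`)
#' @param epoch_length epoch length (s)
#' @return data.frame: `channel`, `feature`, `value` (8 rows; phase features
#'   `NA` when no coupled spindle of that class exists)
#' @export
spindle_feature_set <- function(spindles, sos, n2_epochs,
                                channels = c("C3", "C4"), epoch_length = 30) {
  if (!length(n2_epochs)) stop("need >= 1 accepted N2 epoch")
  n2_min <- length(n2_epochs) * epoch_length / 60
  rows <- list()
  for (ch in channels) {
    sp <- spindles[spindles$channel == ch, , drop = FALSE]
    so <- sos[sos$channel == ch, , drop = FALSE]
    density <- nrow(sp) / n2_min
    counts <- vapply(n2_epochs, function(e) {
      sum(sp$peak_s >= (e - 1) * epoch_length & sp$peak_s < e * epoch_length)
    }, 0L)
    dispersion <- if (nrow(sp) == 0) NA_real_ else
      stats::var(counts) / mean(counts)
    phase <- c(fast = NA_real_, slow = NA_real_)
    if (nrow(sp) && nrow(so)) {
      ph <- vapply(seq_len(nrow(sp)), function(i) {
        j <- which(so$start_s <= sp$peak_s[i] & so$end_s >= sp$peak_s[i])
        if (!length(j)) return(NA_real_)
        so_phase_at_peak(sp$peak_s[i], so$start_s[j[1]], so$end_s[j[1]])
      }, 0)
      for (cl in c("fast", "slow")) {
        phase[cl] <- circular_mean_deg(ph[sp$class == cl & !is.na(ph)])
      }
    }
    rows[[ch]] <- data.frame(
      channel = ch,
      feature = paste0("spindle_", c("density", "dispersion",
                                     "so_phase_fast", "so_phase_slow"),
                       "_", ch),
      value = c(density, dispersion, phase[["fast"]], phase[["slow"]]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' End-to-end spindle/SO features for one preprocessed recording
#'
#' @param rec preprocessed [eeg_recording()]
#' @param h a [hypnogram()]
#' @param ... passed to [detect_spindles()]
#' @return list with `features` (8-row data.frame), `spindles`, `sos`,
#'   `accepted_n2` (epoch indices)
#' @export
spindle_features <- function(rec, h, ...) {
  prep <- prepare_signal(rec)
  rejected <- delta_artifact_epoch_mask(prep, h)
  s <- lights_window_stages(h)
  n2 <- which(s == "N2" & !rejected)
  if (!length(n2)) {
    # no usable N2: all 8 features missing, no events
    feats <- data.frame(
      channel = rep(names(rec$channels), each = 4),
      feature = paste0("spindle_",
                       rep(c("density", "dispersion", "so_phase_fast",
                             "so_phase_slow"), length(rec$channels)),
                       "_", rep(names(rec$channels), each = 4)),
      value = NA_real_, stringsAsFactors = FALSE)
    return(list(features = feats, spindles = empty_events(),
                sos = empty_events()[, 1:3], accepted_n2 = integer()))
  }
  spn <- detect_spindles(prep, h, n2, ...)
  sos <- detect_slow_oscillations(prep, h, n2)
  list(features = spindle_feature_set(spn, sos, n2,
                                      channels = names(rec$channels)),
       spindles = spn, sos = sos, accepted_n2 = n2)
}
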