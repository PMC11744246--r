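# Recording harmonization: contralateral mastoid re-reference, polyphase
# resampling to 200 Hz, 0.5 Hz high-pass, 50 Hz band limit, and the 3-s RMS
# artifact mask.

#' Construct an EEG recording
#'
#' @param channels named list of equal-length numeric vectors (uV); expected
#'   labels among `C3, C4, M1, M2` before re-referencing, `C3, C4` after
#' @param fs sampling rate (Hz)
#' @param start_time POSIXct start (optional)
#' @param lights_off,lights_on analysis window in seconds from start
#' @param preprocessed internal flag set by [preprocess_recording()]
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(channels, fs, start_time = NULL,
                          lights_off = 0,
                          lights_on = length(channels[[1]]) / fs,
                          preprocessed = FALSE) {
  stopifnot(is.list(channels), length(channels) >= 1, fs > 0)
  if (length(unique(lengths(channels))) != 1) {
    stop("all channels must have equal length")
  }
  if (is.null(names(channels)) || any(names(channels) == "")) {
    stop("channels must be named")
  }
  if (!(lights_off < lights_on &&
        lights_on <= length(channels[[1]]) / fs + 1e-9)) {
    stop("lights window must satisfy lights_off < lights_on <= duration")
  }
  structure(list(channels = channels, fs = fs, start_time = start_time,
                 lights_off = lights_off, lights_on = lights_on,
                 preprocessed = isTRUE(preprocessed)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %s | %.4g Hz | %.1f min%s\n",
              paste(names(x$channels), collapse = ", "), x$fs,
              length(x$channels[[1]]) / x$fs / 60,
              if (x$preprocessed) " | preprocessed" else ""))
  invisible(x)
}

rec_duration <- function(rec) length(rec$channels[[1]]) / rec$fs

unusable_recording <- function(reason) {
  structure(class = c("unusable_recording", "error", "condition"),
            list(message = paste("unusable recording:", reason),
                 call = sys.call(-1)))
}

#' Read a recording and its hypnogram from disk
#'
#' Rejects files missing any of the required channels (C3, C4, M1, M2),
#' carrying duplicate channel labels, or with corrupt (non-finite) signal
#' data, raising a structured `unusable_recording` condition naming the
#' reason.
#'
#' @param path EDF file path
#' @param annotation_path hypnogram CSV path (see [read_hypnogram_csv()])
#' @return list with `recording` ([eeg_recording()]) and `hypnogram`
#' @export
read_recording <- function(path, annotation_path) {
  e <- read_edf(path)
  labs <- names(e$channels)
  required <- c("C3", "C4", "M1", "M2")
  if (anyDuplicated(labs)) {
    stop(unusable_recording(paste("duplicate channel(s):",
                                  paste(unique(labs[duplicated(labs)]),
                                        collapse = ", "))))
  }
  missing_ch <- setdiff(required, labs)
  if (length(missing_ch)) {
    stop(unusable_recording(paste("missing channel(s):",
                                  paste(missing_ch, collapse = ", "))))
  }
  if (!all(vapply(e$channels[required], function(x) all(is.finite(x)), TRUE))) {
    stop(unusable_recording("corrupt signal data (non-finite samples)"))
  }
  h <- read_hypnogram_csv(annotation_path)
  rec <- eeg_recording(e$channels[required], e$fs, start_time = e$start_time)
  list(recording = rec, hypnogram = h)
}

#' Re-reference central channels to the contralateral mastoid
#'
#' Output channels are `C3 - M2` and `C4 - M1` (labelled C3, C4); mastoids
#' are dropped.
#'
#' @param rec an [eeg_recording()] with C3, C4, M1, M2
#' @return re-referenced [eeg_recording()]
#' @export
rereference_contralateral <- function(rec) {
  need <- c("C3", "M2", "C4", "M1")
  missing_ch <- setdiff(need, names(rec$channels))
  if (length(missing_ch)) {
    stop(unusable_recording(paste("missing channel(s) for re-reference:",
                                  paste(missing_ch, collapse = ", "))))
  }
  eeg_recording(
    list(C3 = rec$channels$C3 - rec$channels$M2,
         C4 = rec$channels$C4 - rec$channels$M1),
    rec$fs, rec$start_time, rec$lights_off, rec$lights_on)
}

#' Resample a recording to a target rate
#'
#' Polyphase low-pass FIR resampling with a Kaiser window. Up-sampling adds
#' no content above the original Nyquist frequency.
#'
#' @param rec an [eeg_recording()]
#' @param target target rate in Hz (default 200)
#' @return resampled [eeg_recording()]
#' @export
resample_to_target <- function(rec, target = 200) {
  if (target <= 0) stop("target rate must be positive")
  if (abs(rec$fs - target) < 1e-9) return(rec)
  ch <- lapply(rec$channels, function(x) resample_poly(x, rec$fs, target)$x)
  eeg_recording(ch, target, rec$start_time, rec$lights_off,
                min(rec$lights_on, length(ch[[1]]) / target),
                preprocessed = rec$preprocessed)
}

#' Zero-phase high-pass filter
#'
#' Kaiser-window FIR high-pass applied with exact group-delay compensation,
#' so event timestamps are unshifted. Attenuates DC and sub-cutoff drift by
#' >= 60 dB while leaving the passband (> 2 x cutoff) within 1 dB of unity.
#'
#' @param rec an [eeg_recording()]
#' @param cutoff cutoff in Hz (default 0.5)
#' @return filtered [eeg_recording()]
#' @export
highpass_filter <- function(rec, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= rec$fs / 2) {
    stop("cutoff must lie in (0, Nyquist)")
  }
  h <- fir_kaiser(cutoff, rec$fs, "high", trans_hz = cutoff, atten_db = 60)
  ch <- lapply(rec$channels, filt_zero_phase, h = h)
  eeg_recording(ch, rec$fs, rec$start_time, rec$lights_off, rec$lights_on,
                preprocessed = rec$preprocessed)
}

#' Zero-phase low-pass filter (band limit)
#'
#' @param rec an [eeg_recording()]
#' @param cutoff cutoff in Hz (default 50, the band limit all downstream
#'   consumers assume)
#' @param trans_hz transition width in Hz
#' @return filtered [eeg_recording()]
#' @export
lowpass_filter <- function(rec, cutoff = 50, trans_hz = cutoff * 0.2) {
  if (cutoff <= 0 || cutoff >= rec$fs / 2) {
    stop("cutoff must lie in (0, Nyquist)")
  }
  h <- fir_kaiser(cutoff, rec$fs, "low", trans_hz = trans_hz, atten_db = 60)
  ch <- lapply(rec$channels, filt_zero_phase, h = h)
  eeg_recording(ch, rec$fs, rec$start_time, rec$lights_off, rec$lights_on,
                preprocessed = rec$preprocessed)
}

#' Full preprocessing pipeline
#'
#' The only public entry point for harmonization; the order is fixed:
#' contralateral re-reference, polyphase resample to 200 Hz, 0.5 Hz
#' high-pass, then the 50 Hz band limit. Returns a recording flagged
#' `preprocessed`, which downstream feature modules require.
#'
#' @param rec raw [eeg_recording()] with C3, C4, M1, M2
#' @param target_rate resample target (Hz)
#' @param hp_cutoff high-pass cutoff (Hz)
#' @param band_limit low-pass band limit (Hz)
#' @return preprocessed [eeg_recording()] with channels C3, C4
#' @export
preprocess_recording <- function(rec, target_rate = 200, hp_cutoff = 0.5,
                                 band_limit = 50) {
  if (rec$fs < 100) stop("sample_rate must be >= 100 Hz")
  out <- rereference_contralateral(rec)
  out <- resample_to_target(out, target_rate)
  out <- highpass_filter(out, hp_cutoff)
  out <- lowpass_filter(out, band_limit)
  out$preprocessed <- TRUE
  out
}

#' RMS artifact mask over 3-s segments
#'
#' Flags each consecutive 3-s segment whose RMS amplitude is `<= low` or
#' `>= high` microvolts. The segment grid is anchored at lights-off and a
#' partial trailing segment is dropped. Masking is independent of the
#' hypnogram and idempotent.
#'
#' @param rec an [eeg_recording()]
#' @param segment segment length in seconds (default 3)
#' @param low low RMS threshold in uV (default 1)
#' @param high high RMS threshold in uV (default 250)
#' @return object of class `artifact_mask`: list with `flagged`
#'   (channel x segment logical matrix), `segment` (s), `fraction_flagged`
#'   (scalar: fraction of segments flagged on any channel)
#' @export
rms_artifact_mask <- function(rec, segment = 3, low = 1, high = 250) {
  spseg <- round(segment * rec$fs)
  off <- round(rec$lights_off * rec$fs)
  avail <- length(rec$channels[[1]]) - off
  nseg <- avail %/% spseg
  if (nseg < 1) stop("recording shorter than one segment")
  flagged <- matrix(FALSE, length(rec$channels), nseg,
                    dimnames = list(names(rec$channels), NULL))
  for (i in seq_along(rec$channels)) {
    x <- rec$channels[[i]][seq.int(off + 1L, off + nseg * spseg)]
    m <- matrix(x, nrow = spseg)
    rms <- sqrt(colMeans(m^2))
    flagged[i, ] <- rms <= low | rms >= high
  }
  structure(list(flagged = flagged, segment = segment,
                 fraction_flagged = mean(apply(flagged, 2, any))),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("artifact_mask: %d x %d-s segments, %.2f%% flagged\n",
              ncol(x$flagged), x$segment, 100 * x$fraction_flagged))
  invisible(x)
}
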