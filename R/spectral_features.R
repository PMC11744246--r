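# Multitaper band-power estimation and the 20 per-stage relative-power
# features (5 stages x 4 bands, log-transformed mean relative power).

#' Multitaper band powers on a 2-s / 1-s-hop window grid
#'
#' Computes, per channel and per 2-s window (1-s hop, grid anchored at
#' lights-off), the integrated spectral power in the delta, theta, alpha and
#' beta bands from a DPSS multitaper spectrum. Windows overlapping any 3-s
#' segment flagged on any channel of the artifact mask are marked invalid.
#'
#' @param rec preprocessed [eeg_recording()]
#' @param mask an `artifact_mask` from [rms_artifact_mask()], or `NULL`
#' @param window_s window length (s)
#' @param hop_s hop between window starts (s)
#' @param nw multitaper time-bandwidth product
#' @param k number of DPSS tapers
#' @param bands band definition list, see [eeg_bands()]
#' @return object of class `band_power_series`: list with `times` (window
#'   start, s from lights-off), `valid` (logical), `power` (named list per
#'   channel of band x window matrices, uV^2), `window_s`, `fs`
#' @export
multitaper_band_powers <- function(rec, mask = NULL, window_s = 2, hop_s = 1,
                                   nw = 2, k = 3, bands = eeg_bands()) {
  if (!rec$preprocessed) {
    stop("recording must come from preprocess_recording()")
  }
  fs <- rec$fs
  nwin_s <- round(window_s * fs)
  hop <- round(hop_s * fs)
  off <- round(rec$lights_off * fs)
  n <- length(rec$channels[[1]]) - off
  n_windows <- if (n >= nwin_s) (n - nwin_s) %/% hop + 1L else 0L
  times <- (seq_len(n_windows) - 1L) * hop_s
  if (n_windows == 0L) {
    return(structure(list(times = numeric(0), valid = logical(0),
                          power = lapply(rec$channels, function(x)
                            matrix(0, length(bands), 0,
                                   dimnames = list(names(bands), NULL))),
                          window_s = window_s, fs = fs),
                     class = "band_power_series"))
  }
  valid <- rep(TRUE, n_windows)
  if (!is.null(mask)) {
    seg_any <- apply(mask$flagged, 2, any)
    bad_seg <- which(seg_any)
    if (length(bad_seg)) {
      for (s in bad_seg) {
        s0 <- (s - 1) * mask$segment
        s1 <- s * mask$segment
        valid[times < s1 & (times + window_s) > s0] <- FALSE
      }
    }
  }
  idx <- outer(seq_len(nwin_s), (seq_len(n_windows) - 1L) * hop, `+`) + off
  power <- vector("list", length(rec$channels))
  names(power) <- names(rec$channels)
  chunk <- 4096L
  for (ci in seq_along(rec$channels)) {
    x <- rec$channels[[ci]]
    bp <- matrix(NA_real_, length(bands), n_windows,
                 dimnames = list(names(bands), NULL))
    for (st in seq.int(1L, n_windows, by = chunk)) {
      en <- min(st + chunk - 1L, n_windows)
      xw <- matrix(x[idx[, st:en]], nrow = nwin_s)
      mt <- multitaper_psd(xw, fs, nw = nw, k = k)
      bp[, st:en] <- band_power(mt$freq, mt$psd, bands)
    }
    power[[ci]] <- bp
  }
  structure(list(times = times, valid = valid, power = power,
                 window_s = window_s, fs = fs),
            class = "band_power_series")
}

#' Per-30-s-epoch relative band powers
#'
#' For each hypnogram epoch: valid 2-s windows (those whose start falls in
#' the epoch) are averaged per band and channel, the averages are summed
#' across C3 and C4, and each band is divided by the four-band sum. Epochs
#' with no valid window are `NA`.
#'
#' @param series a `band_power_series`
#' @param h a [hypnogram()]
#' @return matrix (epochs x bands) of relative powers; attribute
#'   `n_valid_windows` gives the per-epoch valid-window count
#' @export
relative_band_powers <- function(series, h) {
  n_epochs <- h$lights_on - h$lights_off
  bands <- rownames(series$power[[1]])
  out <- matrix(NA_real_, n_epochs, length(bands),
                dimnames = list(NULL, bands))
  nval <- integer(n_epochs)
  epoch_of <- floor(series$times / h$epoch_length) + 1L
  for (e in seq_len(n_epochs)) {
    w <- which(epoch_of == e & series$valid)
    nval[e] <- length(w)
    if (!length(w)) next
    summed <- Reduce(`+`, lapply(series$power, function(p)
      rowMeans(p[, w, drop = FALSE])))
    out[e, ] <- summed / sum(summed)
  }
  attr(out, "n_valid_windows") <- nval
  out
}

#' Aggregate relative powers to per-stage spectral features
#'
#' The natural log of the mean relative power across each stage's
#' non-missing epochs, for every stage x band combination: 20 features when
#' all five stages are present. Absent stages yield `NA`.
#'
#' @param relatives epoch x band matrix from [relative_band_powers()]
#' @param h a [hypnogram()]
#' @return data.frame with columns `stage`, `band`, `feature`, `value`
#' @export
stage_aggregate <- function(relatives, h) {
  s <- lights_window_stages(h)
  stopifnot(length(s) == nrow(relatives))
  bands <- colnames(relatives)
  grid <- expand.grid(band = bands, stage = sleep_stages(),
                      stringsAsFactors = FALSE)[, 2:1]
  grid$feature <- paste0("spec_", grid$stage, "_", grid$band)
  grid$value <- NA_real_
  for (i in seq_len(nrow(grid))) {
    ep <- which(s == grid$stage[i] & !is.na(relatives[, grid$band[i]]))
    if (length(ep)) {
      grid$value[i] <- log(mean(relatives[ep, grid$band[i]]))
    }
  }
  grid
}

#' End-to-end spectral features for one preprocessed recording
#'
#' Convenience wrapper: artifact mask, multitaper band powers, per-epoch
#' relative powers, per-stage aggregation.
#'
#' @param rec preprocessed [eeg_recording()]
#' @param h a [hypnogram()]
#' @param ... passed to [multitaper_band_powers()]
#' @return data.frame as in [stage_aggregate()]
#' @export
spectral_features <- function(rec, h, ...) {
  mask <- rms_artifact_mask(rec)
  series <- multitaper_band_powers(rec, mask, ...)
  stage_aggregate(relative_band_powers(series, h), h)
}
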