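# Signal-processing primitives: Kaiser FIR design, zero-phase filtering,
# polyphase resampling, DPSS tapers and multitaper band power.

#' Kaiser window
#'
#' @param n window length (samples)
#' @param beta Kaiser shape parameter
#' @return numeric vector of length `n`
#' @keywords internal
kaiser_window <- function(n, beta) {
  if (n == 1) return(1)
  k <- seq_len(n) - 1
  r <- 2 * k / (n - 1) - 1
  besselI(beta * sqrt(pmax(0, 1 - r^2)), 0) / besselI(beta, 0)
}

# Kaiser beta for a target stopband attenuation (dB), standard empirical fit.
kaiser_beta <- function(atten_db) {
  if (atten_db > 50) {
    0.1102 * (atten_db - 8.7)
  } else if (atten_db > 21) {
    0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  } else {
    0
  }
}

# Number of taps for attenuation (dB) and transition width (Hz) at fs; odd.
kaiser_ntaps <- function(atten_db, trans_hz, fs) {
  dw <- 2 * pi * trans_hz / fs
  n <- ceiling((atten_db - 7.95) / (2.285 * dw)) + 1
  if (n %% 2 == 0) n <- n + 1
  as.integer(max(n, 11L))
}

#' Design a linear-phase FIR filter with a Kaiser window
#'
#' Low-pass filters are windowed-sinc designs; high-pass filters are obtained
#' by spectral inversion of the complementary low-pass, so the taps stay
#' symmetric (exactly linear phase).
#'
#' @param cutoff_hz cutoff frequency in Hz (half-amplitude point)
#' @param fs sampling rate in Hz
#' @param type `"low"` or `"high"`
#' @param trans_hz transition-band width in Hz
#' @param atten_db stopband attenuation in dB
#' @return numeric vector of filter taps (odd length, symmetric)
#' @keywords internal
fir_kaiser <- function(cutoff_hz, fs, type = c("low", "high"),
                       trans_hz = cutoff_hz / 2, atten_db = 60) {
  type <- match.arg(type)
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2)
  n <- kaiser_ntaps(atten_db, trans_hz, fs)
  m <- (n - 1) / 2
  k <- seq_len(n) - 1 - m
  fc <- cutoff_hz / fs                      # cycles per sample
  h <- 2 * fc * sinc(2 * fc * k) * kaiser_window(n, kaiser_beta(atten_db))
  h <- h / sum(h)                           # unit DC gain
  if (type == "high") {
    h <- -h
    h[m + 1] <- h[m + 1] + 1                # spectral inversion
  }
  h
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Linear convolution via FFT.
fft_conv <- function(x, h) {
  nx <- length(x); nh <- length(h)
  nfft <- stats::nextn(nx + nh - 1L, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - nx))) *
                       stats::fft(c(h, numeric(nfft - nh))), inverse = TRUE)) / nfft
  y[seq_len(nx + nh - 1L)]
}

#' Zero-phase FIR filtering
#'
#' Applies a symmetric (linear-phase) FIR filter and compensates the group
#' delay exactly, so event timestamps are not shifted. Edges are handled by
#' zero padding; the first/last `(length(h)-1)/2` samples carry edge
#' transients.
#'
#' @param x signal
#' @param h symmetric odd-length FIR taps
#' @return filtered signal, same length as `x`
#' @keywords internal
filt_zero_phase <- function(x, h) {
  stopifnot(length(h) %% 2 == 1)
  m <- (length(h) - 1) / 2
  y <- fft_conv(x, h)
  y[seq.int(m + 1L, m + length(x))]
}

#' Rational-rate polyphase resampling
#'
#' Resamples by the rational factor `p/q` (reduced internally) with a
#' Kaiser-window low-pass FIR anti-aliasing/anti-imaging filter applied in the
#' upsampled domain, delay-compensated so the output grid aligns with sample
#' one of the input.
#'
#' @param x signal
#' @param fs_in input sampling rate (Hz)
#' @param fs_out requested output sampling rate (Hz)
#' @param atten_db filter stopband attenuation
#' @return list with `x` (resampled signal) and `fs` (= fs_out)
#' @keywords internal
resample_poly <- function(x, fs_in, fs_out, atten_db = 60) {
  r <- rational_ratio(fs_out / fs_in)
  p <- r[1]; q <- r[2]
  if (p == q) return(list(x = x, fs = fs_out))
  n_in <- length(x)
  fs_up <- fs_in * p
  # anti-alias/anti-image cutoff: the smaller of the two Nyquists
  fc <- min(fs_in, fs_out) / 2
  h <- fir_kaiser(fc * 0.9, fs_up, "low", trans_hz = fc * 0.2,
                  atten_db = atten_db) * p
  xu <- numeric(n_in * p)
  xu[seq.int(1L, by = p, length.out = n_in)] <- x
  y <- filt_zero_phase(xu, h)
  n_out <- ceiling(n_in * p / q)
  idx <- seq.int(1L, by = q, length.out = n_out)
  idx <- idx[idx <= length(y)]
  list(x = y[idx], fs = fs_out)
}

rational_ratio <- function(ratio, max_den = 1000L) {
  # continued-fraction approximation, exact for the rates used here
  best <- c(1L, 1L); err <- Inf
  for (den in seq_len(max_den)) {
    num <- round(ratio * den)
    if (num < 1) next
    e <- abs(ratio - num / den)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(num), den) }
    if (err < 1e-12) break
  }
  g <- gcd_int(best[1], best[2])
  c(best[1] %/% g, best[2] %/% g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, as eigenvectors of the standard symmetric tridiagonal matrix;
#' tapers are unit-energy.
#'
#' @param n taper length (samples)
#' @param nw time-bandwidth product
#' @param k number of tapers
#' @return `n` x `k` matrix, one taper per column
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  stopifnot(n >= 8, nw > 0, k >= 1, k <= n)
  key <- paste(n, nw, k, sep = "_")
  cached <- .dpss_cache[[key]]
  if (!is.null(cached)) return(cached)
  w <- nw / n
  t <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off_v <- t[-1] * (n - t[-1]) / 2
  A <- matrix(0, n, n)
  A[cbind(t + 1, t + 1)] <- diag_v
  A[cbind(2:n, 1:(n - 1))] <- off_v
  A[cbind(1:(n - 1), 2:n)] <- off_v
  eg <- eigen(A, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (sum(v[, j]) < 0) v[, j] <- -v[, j]   # sign convention
  }
  .dpss_cache[[key]] <- v
  v
}

.dpss_cache <- new.env(parent = emptyenv())

#' Multitaper power spectral density of signal windows
#'
#' @param xw matrix of windowed signal segments, one window per column
#' @param fs sampling rate (Hz)
#' @param nw time-bandwidth product
#' @param k number of tapers
#' @return list with `freq` (Hz, one-sided) and `psd`
#'   (frequency x window matrix, uV^2/Hz)
#' @export
multitaper_psd <- function(xw, fs, nw = 2, k = 3) {
  xw <- as.matrix(xw)
  n <- nrow(xw)
  v <- dpss_tapers(n, nw, k)
  nf <- n %/% 2 + 1
  acc <- matrix(0, nf, ncol(xw))
  for (j in seq_len(k)) {
    ft <- stats::mvfft(xw * v[, j])
    p <- Mod(ft[seq_len(nf), , drop = FALSE])^2 / fs
    acc <- acc + p
  }
  psd <- acc / k
  # one-sided: double everything but DC (and Nyquist when n even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  psd <- psd * dbl
  list(freq = seq(0, by = fs / n, length.out = nf), psd = psd)
}

#' Integrate a PSD over frequency bands
#'
#' Bands are half-open `[low, high)` except the last, which closes at its
#' upper edge, so adjacent bands never double-count a bin.
#'
#' @param freq frequency grid (Hz)
#' @param psd frequency x window PSD matrix
#' @param bands named list of `c(low, high)` pairs, in ascending order
#' @return band x window matrix of band powers (uV^2)
#' @export
band_power <- function(freq, psd, bands = eeg_bands()) {
  psd <- as.matrix(psd)
  df <- freq[2] - freq[1]
  out <- matrix(NA_real_, length(bands), ncol(psd),
                dimnames = list(names(bands), NULL))
  hi_edge <- max(vapply(bands, `[`, numeric(1), 2))
  for (b in seq_along(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    sel <- if (hi == hi_edge) freq >= lo & freq <= hi else freq >= lo & freq < hi
    out[b, ] <- colSums(psd[sel, , drop = FALSE]) * df
  }
  out
}

#' Canonical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30 Hz.
#' @return named list of band edges
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}

#' Complex Morlet wavelet magnitude
#'
#' Convolves the signal with a complex Morlet wavelet and returns the
#' magnitude envelope, delay-compensated.
#'
#' @param x signal
#' @param fs sampling rate (Hz)
#' @param freq centre frequency (Hz)
#' @param n_cycles wavelet width in cycles
#' @return magnitude envelope, same length as `x`
#' @keywords internal
morlet_magnitude <- function(x, fs, freq = 13.5, n_cycles = 7) {
  sd_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(4 * sd_t * fs)
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sd_t^2)) * exp(1i * 2 * pi * freq * t)
  w <- w / sum(Mod(w))
  nx <- length(x); nw <- length(w)
  nfft <- stats::nextn(nx + nw - 1L, 2L)
  y <- stats::fft(stats::fft(c(x, numeric(nfft - nx))) *
                    stats::fft(c(w, complex(real = numeric(nfft - nw)))),
                  inverse = TRUE) / nfft
  Mod(y[seq.int(half + 1L, half + nx)])
}

# Centered moving average over a window of `n` samples (shrinks at edges).
moving_average <- function(x, n) {
  if (n <= 1) return(x)
  cs <- cumsum(c(0, x))
  half <- n %/% 2
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
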