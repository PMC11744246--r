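# Synthetic PSG cohort generation: Markov hypnograms with group-dependent
# transition matrices, stage-shaped EEG (band-limited Gaussian noise mixed to
# requested band fractions), planted spindle bursts coupled to planted slow
# oscillations, artifact injection, and a fast feature-level cohort
# simulator used for statistical calibration at desk scale.

#' Cohort generation configuration
#'
#' Defaults mirror the published cohort where the source states values:
#' ages normal with mean 56 (insomnia) / 50 (control), SD 14, truncated at
#' 18; sex Bernoulli with P(female) 0.66 / 0.50; insomnia effects in the
#' reported directions (higher probability of transitioning to Wake, higher
#' relative alpha in Wake and N1, lower spindle density). Sites are assigned
#' round-robin.
#'
#' @param n_insomnia,n_control group sizes
#' @param recording_duration minutes (whole number of 30-s epochs)
#' @param sample_rate Hz (>= 100)
#' @param seed integer seed
#' @param effect_sizes named list of planted group differences:
#'   `p_to_wake` (absolute increase of each row's to-Wake probability),
#'   `rel_alpha_wake`, `rel_alpha_n1` (absolute relative-power shifts),
#'   `spindle_density` (absolute change, spindles/min), `wesi_logit`
#'   (logit-scale shift of per-stage WESI means, fast path only)
#' @param n_sites number of recording sites
#' @param age_mean named `c(insomnia=, control=)` means, `age_sd`, sex
#'   probabilities `p_female`
#' @param signal if `TRUE`, synthesize full EEG per subject (slow); if
#'   `FALSE`, hypnograms + ground truth only
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n_insomnia = 20, n_control = 20,
                          recording_duration = 480, sample_rate = 200,
                          seed = 1L,
                          effect_sizes = list(p_to_wake = 0.05,
                                              rel_alpha_wake = 0.0345,
                                              rel_alpha_n1 = 0.0164,
                                              spindle_density = -0.37,
                                              wesi_logit = 0.28),
                          n_sites = 4,
                          age_mean = c(insomnia = 56, control = 50),
                          age_sd = 14,
                          p_female = c(insomnia = 0.66, control = 0.50),
                          signal = FALSE) {
  stopifnot(n_insomnia >= 0, n_control >= 0, sample_rate >= 100,
            recording_duration %% 0.5 == 0, n_sites >= 1)
  defaults <- list(p_to_wake = 0, rel_alpha_wake = 0, rel_alpha_n1 = 0,
                   spindle_density = 0, wesi_logit = 0)
  defaults[names(effect_sizes)] <- effect_sizes
  structure(list(n_insomnia = n_insomnia, n_control = n_control,
                 recording_duration = recording_duration,
                 sample_rate = sample_rate, seed = as.integer(seed),
                 effect_sizes = defaults, n_sites = n_sites,
                 age_mean = age_mean, age_sd = age_sd, p_female = p_female,
                 signal = isTRUE(signal)),
            class = "cohort_config")
}

#' Baseline stage-dependent transition matrices
#'
#' Row-stochastic 5x5 matrices (order W, N1, N2, N3, R). The two group
#' matrices were calibrated so that simulated whole-night hypnograms land
#' near the published cohort descriptives (control sleep efficiency near
#' 92%, insomnia near 63% with long sleep latency and WASO well above the
#' objective PSG thresholds).
#'
#' @param group `"insomnia"` or `"control"`
#' @param p_to_wake extra absolute probability of transitioning to Wake from
#'   each non-Wake stage (taken from the diagonal)
#' @return 5x5 row-stochastic matrix
#' @export
default_transition_matrix <- function(group = c("control", "insomnia"),
                                      p_to_wake = 0) {
  group <- match.arg(group)
  st <- sleep_stages()
  m <- if (group == "control") {
    matrix(c(
      0.800, 0.140, 0.050, 0.002, 0.008,  # W
      0.045, 0.500, 0.420, 0.005, 0.030,  # N1
      0.010, 0.030, 0.890, 0.045, 0.025,  # N2
      0.003, 0.004, 0.110, 0.880, 0.003,  # N3
      0.012, 0.030, 0.030, 0.002, 0.926   # R
    ), 5, 5, byrow = TRUE, dimnames = list(st, st))
  } else {
    matrix(c(
      0.880, 0.060, 0.045, 0.002, 0.013,  # W
      0.140, 0.460, 0.360, 0.005, 0.035,  # N1
      0.038, 0.040, 0.848, 0.044, 0.030,  # N2
      0.012, 0.005, 0.090, 0.888, 0.005,  # N3
      0.050, 0.040, 0.030, 0.002, 0.878   # R
    ), 5, 5, byrow = TRUE, dimnames = list(st, st))
  }
  if (p_to_wake != 0) {
    for (r in 2:5) {
      shift <- min(p_to_wake, m[r, r] - 0.01)
      m[r, "W"] <- m[r, "W"] + shift
      m[r, r] <- m[r, r] - shift
    }
  }
  m
}

#' Baseline stage band-power fractions
#'
#' Wake fractions follow the published control means (delta ~45%, theta
#' ~17%, alpha ~17%); sleep stages follow standard qualitative profiles
#' (delta rising with NREM depth).
#'
#' @return named list stage -> named fraction vector (sums to 1)
#' @export
default_stage_spectra <- function() {
  list(
    W  = c(delta = 0.45, theta = 0.17, alpha = 0.17, beta = 0.21),
    N1 = c(delta = 0.55, theta = 0.20, alpha = 0.12, beta = 0.13),
    N2 = c(delta = 0.65, theta = 0.17, alpha = 0.09, beta = 0.09),
    N3 = c(delta = 0.82, theta = 0.10, alpha = 0.05, beta = 0.03),
    R  = c(delta = 0.55, theta = 0.22, alpha = 0.12, beta = 0.11)
  )
}

# Shift one band's fraction by `delta_abs`, renormalizing the others.
shift_band_fraction <- function(frac, band, delta_abs) {
  target <- min(max(frac[band] + delta_abs, 0.01), 0.97)
  others <- setdiff(names(frac), band)
  frac[others] <- frac[others] * (1 - target) / sum(frac[others])
  frac[band] <- target
  frac / sum(frac)
}

#' Generate a Markov-chain hypnogram
#'
#' First-order Markov chain over the five AASM stages, starting in Wake.
#'
#' @param transition_matrix 5x5 row-stochastic matrix (order W, N1, N2, N3,
#'   R; each row must sum to 1 within 1e-9)
#' @param n_epochs number of 30-s epochs (>= 2)
#' @param seed integer seed (optional; uses the current RNG state if `NULL`)
#' @return a [hypnogram()]
#' @export
generate_hypnogram <- function(transition_matrix, n_epochs, seed = NULL) {
  if (!is.matrix(transition_matrix) || !all(dim(transition_matrix) == 5) ||
      any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    stop("transition_matrix must be 5x5 row-stochastic (rows sum to 1)")
  }
  if (n_epochs < 2) stop("n_epochs must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  st <- sleep_stages()
  cum <- t(apply(transition_matrix, 1, cumsum))
  s <- integer(n_epochs)
  s[1] <- 1L                               # start in W
  u <- stats::runif(n_epochs - 1)
  for (e in 2:n_epochs) {
    s[e] <- findInterval(u[e - 1], cum[s[e - 1], ], left.open = TRUE) + 1L
  }
  hypnogram(st[s])
}

# Unit-variance Gaussian noise band-limited to [lo, hi) Hz (FFT shaping).
bandlimited_noise <- function(n, fs, lo, hi) {
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f <- pmin(f, fs - f)                     # two-sided frequency magnitude
  spec <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  spec[!(f >= lo & f < hi)] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthesize an EEG recording for a hypnogram
#'
#' Each stage's epochs carry a sum of four band-limited Gaussian noise
#' processes scaled so the variance fractions match the requested stage
#' band-power fractions (total RMS `background_rms`). N2 epochs additionally
#' receive planted 13.5 Hz Hann-windowed spindle bursts (0.5-1.5 s) and
#' planted slow-oscillation waves (one full negative-going sine cycle
#' delimited by positive-to-negative zero-crossings). When both are planted
#' and `coupling_phase` is not `NA`, each spindle's peak is placed at that
#' phase within a co-planted SO. Two signal channels (C3, C4) carry the same
#' planted events over independent noise; mastoid channels (M1, M2) carry
#' low-amplitude noise, and the raw centrals are stored as signal +
#' contralateral mastoid so the contralateral re-reference recovers the
#' clean construction.
#'
#' @param h a [hypnogram()]
#' @param stage_spectra list stage -> band fractions (sum to 1)
#' @param spindle_density planted spindle rate (per N2 minute)
#' @param so_rate planted SO rate (per N2 minute)
#' @param coupling_phase degrees in `[0, 360)`, or `NA` for uncoupled
#' @param sample_rate Hz
#' @param seed integer seed (optional)
#' @param background_rms total background RMS (uV)
#' @param spindle_amp spindle burst peak amplitude (uV); the default is five
#'   times the spindle-band background RMS
#'   (`5 * sqrt(beta fraction) * background_rms` = 45 uV at N2 defaults)
#' @param so_amp SO amplitude (uV)
#' @return list with `recording` (raw [eeg_recording()] with C3, C4, M1,
#'   M2) and `ground_truth` (list: `spindles`, `sos` data.frames with
#'   channel/start_s/end_s/peak_s, `stage_fractions`)
#' @export
synthesize_recording <- function(h, stage_spectra = default_stage_spectra(),
                                 spindle_density = 2, so_rate = 3,
                                 coupling_phase = 250, sample_rate = 200,
                                 seed = NULL, background_rms = 30,
                                 spindle_amp = 45, so_amp = 75) {
  if (length(h$stages) == 0) stop("hypnogram must be non-empty")
  if (spindle_density < 0 || so_rate < 0) stop("rates must be >= 0")
  for (st in unique(h$stages)) {
    if (abs(sum(stage_spectra[[st]]) - 1) > 1e-6) {
      stop("stage band fractions must sum to 1")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  fs <- sample_rate
  n_epochs <- length(h$stages)
  n <- n_epochs * h$epoch_length * fs
  bands <- eeg_bands()

  gain <- matrix(0, n_epochs, length(bands),
                 dimnames = list(NULL, names(bands)))
  for (e in seq_len(n_epochs)) {
    fr <- stage_spectra[[h$stages[e]]][names(bands)]
    gain[e, ] <- sqrt(background_rms^2 * fr)
  }
  gain_t <- gain[rep(seq_len(n_epochs), each = h$epoch_length * fs), ,
                 drop = FALSE]

  make_channel <- function() {
    x <- numeric(n)
    for (b in seq_along(bands)) {
      x <- x + gain_t[, b] *
        bandlimited_noise(n, fs, bands[[b]][1], bands[[b]][2])
    }
    x
  }
  sig <- list(C3 = make_channel(), C4 = make_channel())

  n2 <- which(h$stages == "N2")
  spindles <- sos <- list()
  t_axis <- (seq_len(n) - 1) / fs
  for (e in n2) {
    e0 <- (e - 1) * h$epoch_length
    n_so <- stats::rpois(1, so_rate * h$epoch_length / 60)
    n_sp <- stats::rpois(1, spindle_density * h$epoch_length / 60)
    so_here <- list()
    # occupied intervals, kept >= 0.7 s apart so planted events can never be
    # merged by the detector's 0.5-s merge rule
    placed <- matrix(numeric(0), ncol = 2)
    margin <- 0.7
    free_slot <- function(t0, dur) {
      !nrow(placed) ||
        all(t0 + dur + margin < placed[, 1] | t0 > placed[, 2] + margin)
    }
    place <- function(dur) {
      for (try in 1:30) {
        t0 <- e0 + stats::runif(1, 0.7, h$epoch_length - dur - 0.7)
        if (free_slot(t0, dur)) return(t0)
      }
      NA_real_
    }
    add_wave <- function(idx, w) {
      sig$C3[idx] <<- sig$C3[idx] + w
      sig$C4[idx] <<- sig$C4[idx] + w
    }
    for (k in seq_len(n_so)) {
      dur <- stats::runif(1, 1.0, 1.6)
      t0 <- place(dur)
      if (is.na(t0)) next
      idx <- which(t_axis >= t0 & t_axis < t0 + dur)
      add_wave(idx, -so_amp * sin(2 * pi * (t_axis[idx] - t0) / dur))
      placed <- rbind(placed, c(t0, t0 + dur))
      so_here[[length(so_here) + 1]] <- c(t0, t0 + dur)
      sos[[length(sos) + 1]] <- c(start = t0, end = t0 + dur)
    }
    so_free <- seq_along(so_here)            # each SO hosts <= 1 spindle
    for (k in seq_len(n_sp)) {
      dur <- stats::runif(1, 0.5, 1.5)
      if (length(so_free) && !is.na(coupling_phase)) {
        pick <- so_free[sample.int(length(so_free), 1)]
        so_free <- setdiff(so_free, pick)
        so_k <- so_here[[pick]]
        peak <- so_k[1] + (coupling_phase / 360) * (so_k[2] - so_k[1])
        t0 <- peak - dur / 2
        if (t0 < e0 + 0.1 || t0 + dur > e0 + h$epoch_length - 0.1) next
      } else {
        t0 <- place(dur)
        if (is.na(t0)) next
        peak <- t0 + dur / 2
        placed <- rbind(placed, c(t0, t0 + dur))
      }
      idx <- which(t_axis >= t0 & t_axis < t0 + dur)
      env <- 0.5 * (1 - cos(2 * pi * (t_axis[idx] - t0) / dur))
      add_wave(idx, spindle_amp * env *
                 sin(2 * pi * 13.5 * (t_axis[idx] - peak)))
      spindles[[length(spindles) + 1]] <-
        c(start = t0, end = t0 + dur, peak = peak)
    }
  }

  bind_events <- function(lst, with_peak) {
    if (!length(lst)) {
      return(data.frame(channel = character(), start_s = numeric(),
                        end_s = numeric(), peak_s = numeric(),
                        stringsAsFactors = FALSE))
    }
    m <- do.call(rbind, lst)
    base <- data.frame(start_s = m[, "start"], end_s = m[, "end"],
                       peak_s = if (with_peak) m[, "peak"] else NA_real_)
    out <- rbind(cbind(channel = "C3", base), cbind(channel = "C4", base))
    out[order(out$channel, out$start_s), ]
  }

  m1 <- 5 * stats::rnorm(n)
  m2 <- 5 * stats::rnorm(n)
  rec <- eeg_recording(
    list(C3 = sig$C3 + m2, C4 = sig$C4 + m1, M1 = m1, M2 = m2), fs)
  list(recording = rec,
       ground_truth = list(spindles = bind_events(spindles, TRUE),
                           sos = bind_events(sos, FALSE),
                           stage_fractions = stage_spectra))
}

#' Inject flat and high-amplitude artifact segments
#'
#' Overwrites `n_flat` 3-s segments with near-zero signal (RMS <= 1 uV) and
#' `n_high` 3-s segments with high-amplitude noise (RMS ~300 uV), at random
#' non-overlapping positions aligned to the 3-s artifact-mask grid, on all
#' channels.
#'
#' @param rec an [eeg_recording()]
#' @param n_flat,n_high segment counts (>= 0)
#' @param seed integer seed (optional)
#' @return list with `recording` and `intervals` (data.frame `start_s`,
#'   `end_s`, `type`)
#' @export
inject_artifacts <- function(rec, n_flat, n_high, seed = NULL) {
  stopifnot(n_flat >= 0, n_high >= 0)
  if (!is.null(seed)) set.seed(seed)
  nseg <- floor(rec_duration(rec) / 3)
  total <- n_flat + n_high
  if (total > nseg) stop("recording too short for requested artifact count")
  if (total == 0) {
    return(list(recording = rec,
                intervals = data.frame(start_s = numeric(),
                                       end_s = numeric(),
                                       type = character())))
  }
  segs <- sample.int(nseg, total)
  type <- c(rep("flat", n_flat), rep("high", n_high))
  spseg <- round(3 * rec$fs)
  for (i in seq_len(total)) {
    idx <- seq.int((segs[i] - 1L) * spseg + 1L, segs[i] * spseg)
    repl <- if (type[i] == "flat") {
      0.1 * stats::rnorm(spseg)
    } else {
      300 * stats::rnorm(spseg)
    }
    for (ci in seq_along(rec$channels)) rec$channels[[ci]][idx] <- repl
  }
  list(recording = rec,
       intervals = data.frame(start_s = (segs - 1) * 3, end_s = segs * 3,
                              type = type)[order(segs), ])
}

#' Generate a synthetic PSG cohort
#'
#' Deterministic given the config seed. Insomnia subjects draw shifted
#' transition matrices (higher to-Wake rows), shifted Wake/N1 alpha
#' fractions, and reduced spindle densities, per `config$effect_sizes`.
#' With all effect sizes zero both groups are drawn from the same
#' generative law.
#'
#' @param config a [cohort_config()]
#' @return list with `subjects` (data.frame: subject_id, age, sex, group,
#'   site) and `data` (per-subject list: `hypnogram`, `transition_matrix`,
#'   `stage_spectra`, `spindle_density`, and when `config$signal` is TRUE,
#'   `recording` + `ground_truth`)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_insomnia + config$n_control
  group <- c(rep("insomnia", config$n_insomnia),
             rep("control", config$n_control))
  es <- config$effect_sizes
  n_epochs <- round(config$recording_duration * 60 / 30)

  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = NA_real_,
    sex = NA_character_,
    group = ifelse(group == "insomnia", "insomnia", "non-insomnia"),
    site = paste0("site", (seq_len(n) - 1L) %% config$n_sites + 1L),
    stringsAsFactors = FALSE)

  # A cohort with no planted effects is a null cohort: both groups must be
  # drawn from the same generative law, so the insomnia night profile (its
  # base matrix and long sleep-onset bout) only applies when some effect is
  # planted.
  null_cohort <- all(vapply(es, function(x) isTRUE(all(x == 0)), TRUE))

  data <- vector("list", n)
  names(data) <- subjects$subject_id
  for (i in seq_len(n)) {
    g <- group[i]
    subjects$age[i] <- max(18, stats::rnorm(1, config$age_mean[[g]],
                                            config$age_sd))
    subjects$sex[i] <- if (stats::runif(1) < config$p_female[[g]])
      "female" else "male"
    ins_profile <- g == "insomnia" && !null_cohort
    base <- default_transition_matrix(
      if (ins_profile) "insomnia" else "control",
      p_to_wake = if (ins_profile) es$p_to_wake else 0)
    tm <- jitter_transition_matrix(base, sd = 0.10)
    spectra <- default_stage_spectra()
    for (stg in names(spectra)) {
      spectra[[stg]] <- jitter_fractions(spectra[[stg]], sd = 0.10)
    }
    if (ins_profile) {
      spectra$W <- shift_band_fraction(spectra$W, "alpha", es$rel_alpha_wake)
      spectra$N1 <- shift_band_fraction(spectra$N1, "alpha", es$rel_alpha_n1)
    }
    dens <- max(0.2, stats::rnorm(1, 2.4 +
                                    if (ins_profile)
                                      es$spindle_density else 0, 0.8))
    h <- subject_hypnogram(tm, n_epochs,
                           onset_median_min = if (ins_profile) 55 else 8,
                           onset_sdlog = if (ins_profile) 0.55 else 0.5)
    rec_gt <- NULL
    if (config$signal) {
      rec_gt <- synthesize_recording(h, spectra, spindle_density = dens,
                                     sample_rate = config$sample_rate)
    }
    data[[i]] <- list(hypnogram = h, transition_matrix = tm,
                      stage_spectra = spectra, spindle_density = dens,
                      recording = rec_gt$recording,
                      ground_truth = rec_gt$ground_truth)
  }
  list(subjects = subjects, data = data, config = config)
}

# Multiplicative log-normal jitter of transition rows, renormalized.
jitter_transition_matrix <- function(m, sd = 0.1) {
  out <- m * exp(matrix(stats::rnorm(25, 0, sd), 5, 5))
  out / rowSums(out)
}

jitter_fractions <- function(frac, sd = 0.1) {
  f <- frac * exp(stats::rnorm(length(frac), 0, sd))
  f / sum(f)
}

# Whole-night hypnogram for one subject: a lognormal sleep-onset wake bout
# (the time-homogeneous chain alone cannot reproduce the long sleep-onset
# latencies of objective insomnia while keeping WASO realistic) followed by
# the first-order Markov chain.
subject_hypnogram <- function(tm, n_epochs, onset_median_min, onset_sdlog) {
  onset <- round(2 * exp(stats::rnorm(1, log(onset_median_min), onset_sdlog)))
  onset <- max(0L, min(onset, n_epochs - 100L))
  h <- generate_hypnogram(tm, n_epochs - onset)
  if (onset > 0) h <- hypnogram(c(rep("W", onset), h$stages))
  h
}

#' Write cohort recordings and metadata to disk
#'
#' Recordings as EDF, hypnograms and ground-truth events as CSV
#' (subject_id, channel, event_type, start_s, end_s, peak_s), metadata as
#' CSV.
#'
#' @param cohort result of [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  events <- list()
  for (id in names(cohort$data)) {
    d <- cohort$data[[id]]
    write_hypnogram_csv(d$hypnogram,
                        file.path(dir, paste0(id, "_hypnogram.csv")))
    if (!is.null(d$recording)) {
      write_edf(file.path(dir, paste0(id, ".edf")), d$recording$channels,
                d$recording$fs)
      for (ty in c("spindles", "sos")) {
        ev <- d$ground_truth[[ty]]
        if (nrow(ev)) {
          events[[length(events) + 1]] <- data.frame(
            subject_id = id, channel = ev$channel,
            event_type = sub("s$", "", ty),
            start_s = ev$start_s, end_s = ev$end_s,
            peak_s = if ("peak_s" %in% names(ev)) ev$peak_s else NA_real_)
        }
      }
    }
  }
  if (length(events)) {
    utils::write.csv(do.call(rbind, events),
                     file.path(dir, "ground_truth_events.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Fast feature-level cohort simulator
#'
#' Draws per-subject feature values directly from the generative law the
#' signal-level generator targets, skipping EEG synthesis. Used for
#' statistical calibration and power runs where hundreds of cohorts are
#' needed. Transition counts come from actual simulated hypnograms; the
#' continuous features are drawn from the documented between-subject
#' distributions (Wake relative alpha, SD 0.06; spindle density, SD
#' 0.8/min; per-stage WESI logit-scale means, SD 0.3).
#'
#' @param n_insomnia,n_control group sizes
#' @param effect_sizes as in [cohort_config()]; additionally honours
#'   `rel_delta_wake` and `spindle_dispersion` (absolute shifts)
#' @param n_sites number of sites
#' @param n_epochs hypnogram length (epochs)
#' @param seed integer seed (optional)
#' @return list with `subjects` (metadata data.frame) and `features`
#'   (data.frame: subject_id, family, feature, value, plus `from_total` for
#'   transition counts)
#' @export
simulate_feature_cohort <- function(n_insomnia = 50, n_control = 50,
                                    effect_sizes = list(), n_sites = 4,
                                    n_epochs = 960, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  es <- list(p_to_wake = 0, rel_alpha_wake = 0, rel_delta_wake = 0,
             spindle_density = 0, spindle_dispersion = 0, wesi_logit = 0)
  es[names(effect_sizes)] <- effect_sizes
  n <- n_insomnia + n_control
  group <- c(rep("insomnia", n_insomnia), rep("non-insomnia", n_control))
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = pmax(18, stats::rnorm(n, ifelse(group == "insomnia", 56, 50), 14)),
    sex = ifelse(stats::runif(n) <
                   ifelse(group == "insomnia", 0.66, 0.50),
                 "female", "male"),
    group = group,
    site = paste0("site", (seq_len(n) - 1L) %% n_sites + 1L),
    stringsAsFactors = FALSE)

  wesi_base <- c(W = stats::qlogis(0.59), N1 = stats::qlogis(0.45),
                 N2 = stats::qlogis(0.25), N3 = stats::qlogis(0.10),
                 R = stats::qlogis(0.35))
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    ins <- group[i] == "insomnia"
    # both groups share the control base law; every group difference is a
    # planted effect (clean testbed for calibration and power runs)
    tm <- default_transition_matrix("control",
                                    p_to_wake = if (ins) es$p_to_wake else 0)
    tm <- jitter_transition_matrix(tm, sd = 0.10)
    h <- generate_hypnogram(tm, n_epochs)
    tf <- transition_features(count_transitions(h))
    alpha <- stats::rnorm(1, 0.17 + if (ins) es$rel_alpha_wake else 0, 0.06)
    delta <- stats::rnorm(1, 0.45 + if (ins) es$rel_delta_wake else 0, 0.06)
    dens <- max(0.2, stats::rnorm(1, 2.4 +
                                    if (ins) es$spindle_density else 0, 0.8))
    disp <- max(0.05, stats::rnorm(1, 1 +
                                     if (ins) es$spindle_dispersion else 0,
                                   0.15))
    wesi <- wesi_base + stats::rnorm(5, 0, 0.3) +
      if (ins) es$wesi_logit else 0
    feats[[i]] <- rbind(
      data.frame(subject_id = subjects$subject_id[i], family = "transition",
                 feature = tf$feature, value = tf$count,
                 from_total = tf$from_total, stringsAsFactors = FALSE),
      data.frame(subject_id = subjects$subject_id[i],
                 family = c("spectral", "spectral", "spindle", "spindle",
                            rep("wesi", 5)),
                 feature = c("rel_alpha_W", "rel_delta_W",
                             "spindle_density_C3", "spindle_dispersion_C3",
                             paste0("wesi_logit_", names(wesi_base))),
                 value = c(alpha, delta, dens, disp, wesi),
                 from_total = NA_integer_, stringsAsFactors = FALSE))
  }
  list(subjects = subjects, features = do.call(rbind, feats))
}

#' Simulate labelled 3-s-window relative band powers for WESI training
#'
#' Draws per-window relative band-power vectors around stage-dependent
#' profiles (logit-normal jitter), labelled wake = 1 / sleep = 0, for a set
#' of synthetic subjects. `separation` scales how far the Wake profile's
#' alpha/beta excess is pushed (1 = the default stage profiles; larger
#' values make the classes more separable).
#'
#' @param n_subjects number of subjects
#' @param windows_per_subject windows per subject (split half wake, half N2)
#' @param separation class-separation multiplier
#' @param noise_sd logit-scale within-stage jitter SD
#' @param seed integer seed (optional)
#' @return data.frame: subject_id, stage, label, delta, theta, alpha, beta
#' @export
simulate_wesi_windows <- function(n_subjects = 20, windows_per_subject = 200,
                                  separation = 1, noise_sd = 0.4,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prof <- default_stage_spectra()
  w <- shift_band_fraction(prof$W, "alpha",
                           (separation - 1) * 0.15 + 0)
  w <- shift_band_fraction(w, "beta", (separation - 1) * 0.10)
  profiles <- list(W = w, N2 = prof$N2)
  out <- vector("list", n_subjects * 2)
  k <- 0
  for (i in seq_len(n_subjects)) {
    for (stg in c("W", "N2")) {
      m <- windows_per_subject %/% 2
      base <- profiles[[stg]]
      lg <- matrix(log(base), m, 4, byrow = TRUE) +
        matrix(stats::rnorm(m * 4, 0, noise_sd), m, 4)
      p <- exp(lg); p <- p / rowSums(p)
      colnames(p) <- names(base)
      k <- k + 1
      out[[k]] <- data.frame(subject_id = sprintf("S%04d", i), stage = stg,
                             label = as.integer(stg == "W"), p,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(k)])
}
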