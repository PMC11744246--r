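# Macro-architecture summaries, objective PSG insomnia criteria, and 5x5
# sleep-stage transition counts/probabilities.

# Index (within the lights window) of the first epoch starting a run of >= 20
# consecutive non-wake epochs, or NA.
persistent_sleep_onset_epoch <- function(h, run_length = 20L) {
  s <- lights_window_stages(h)
  nonw <- s != "W"
  r <- rle(nonw)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= run_length)
  if (!length(ok)) return(NA_integer_)
  starts[ok[1]]
}

#' Latency to persistent sleep (LPS)
#'
#' Minutes from lights-off to the first epoch of 20 consecutive non-wake
#' epochs; `NA` when persistent sleep never occurs.
#'
#' @param h a [hypnogram()]
#' @return minutes (numeric scalar, possibly `NA`)
#' @export
latency_to_persistent_sleep <- function(h) {
  onset <- persistent_sleep_onset_epoch(h)
  if (is.na(onset)) return(NA_real_)
  (onset - 1L) * h$epoch_length / 60
}

#' Macro-architecture summary of a hypnogram
#'
#' Computes total sleep time, sleep efficiency, WASO, LPS, and per-stage
#' minutes and percentages, all within the lights-off to lights-on window.
#' WASO is wake time after the onset of persistent sleep until lights-on.
#'
#' @param h a [hypnogram()]
#' @return list of class `sleep_summary`
#' @export
sleep_summary <- function(h) {
  s <- lights_window_stages(h)
  n <- length(s)
  epm <- h$epoch_length / 60              # minutes per epoch
  window_min <- n * epm
  mins <- vapply(sleep_stages(), function(st) sum(s == st) * epm, 0)
  tst <- sum(mins[c("N1", "N2", "N3", "R")])
  onset <- persistent_sleep_onset_epoch(h)
  waso <- if (is.na(onset)) NA_real_ else sum(s[onset:n] == "W") * epm
  structure(list(
    TST = tst,
    sleep_efficiency = tst / window_min,
    WASO = waso,
    LPS = latency_to_persistent_sleep(h),
    stage_minutes = mins,
    stage_percent = 100 * mins / window_min,
    awake_minutes = mins[["W"]],
    window_minutes = window_min
  ), class = "sleep_summary")
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat(sprintf("TST %.1f min | SE %.1f%% | WASO %s min | LPS %s min\n",
              x$TST, 100 * x$sleep_efficiency,
              ifelse(is.na(x$WASO), "NA", sprintf("%.1f", x$WASO)),
              ifelse(is.na(x$LPS), "NA", sprintf("%.1f", x$LPS))))
  print(round(rbind(minutes = x$stage_minutes, percent = x$stage_percent), 1))
  invisible(x)
}

#' Objective PSG insomnia criteria
#'
#' True iff WASO >= 30 min AND LPS >= 20 min AND sleep efficiency < 85%.
#' A missing LPS (persistent sleep never reached) fails the criteria, with
#' the reason recorded in the `"reason"` attribute.
#'
#' @param summary a [sleep_summary()]
#' @return logical scalar with attribute `reason` (character, possibly empty)
#' @export
psg_insomnia_criteria <- function(summary) {
  reasons <- character()
  if (is.na(summary$LPS)) {
    reasons <- "LPS undefined (no persistent sleep)"
  } else {
    if (summary$LPS < 20) reasons <- c(reasons, "LPS < 20 min")
    if (is.na(summary$WASO) || summary$WASO < 30) {
      reasons <- c(reasons, "WASO < 30 min")
    }
    if (summary$sleep_efficiency >= 0.85) {
      reasons <- c(reasons, "sleep efficiency >= 85%")
    }
  }
  structure(length(reasons) == 0, reason = reasons)
}

#' Control (non-insomnia) PSG screen
#'
#' True iff sleep efficiency >= 85%.
#' @param summary a [sleep_summary()]
#' @return logical scalar
#' @export
psg_control_criteria <- function(summary) {
  isTRUE(summary$sleep_efficiency >= 0.85)
}

#' Count epoch-to-epoch stage transitions
#'
#' Counts transitions (self-transitions included) over all consecutive epoch
#' pairs in the lights window, producing a 5x5 matrix in the fixed stage
#' order W, N1, N2, N3, R.
#'
#' @param h a [hypnogram()]
#' @return 5x5 integer matrix (from-stage rows, to-stage columns)
#' @export
count_transitions <- function(h) {
  s <- lights_window_stages(h)
  if (length(s) < 2) stop("need >= 2 epochs in the lights window")
  st <- sleep_stages()
  f <- factor(s[-length(s)], st)
  t_ <- factor(s[-1], st)
  m <- table(f, t_)
  out <- matrix(as.integer(m), 5, 5, dimnames = list(st, st))
  out
}

#' Row-normalize transition counts into probabilities
#'
#' Rows with a zero total (stage never occupied as a source) become `NA`.
#'
#' @param counts 5x5 transition count matrix
#' @return 5x5 row-stochastic matrix (rows may be `NA`)
#' @export
transition_probabilities <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == 5), all(counts >= 0))
  rs <- rowSums(counts)
  p <- counts / ifelse(rs > 0, rs, NA_real_)
  dimnames(p) <- dimnames(counts)
  p
}

#' Flatten a transition matrix into the 25 per-subject transition features
#'
#' @param counts 5x5 transition count matrix
#' @return data.frame with columns `from`, `to`, `feature`, `count`,
#'   `from_total`
#' @export
transition_features <- function(counts) {
  st <- sleep_stages()
  g <- expand.grid(to = st, from = st, stringsAsFactors = FALSE)[, 2:1]
  data.frame(
    from = g$from, to = g$to,
    feature = paste0("trans_", g$from, "_", g$to),
    count = as.integer(counts[cbind(g$from, g$to)]),
    from_total = as.integer(rowSums(counts)[g$from]),
    stringsAsFactors = FALSE)
}
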