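# End-to-end orchestration: cohort generation or file input, subject
# screening, per-subject feature extraction, group statistics, and report
# tables.

#' Screen subjects against the objective PSG criteria
#'
#' Insomnia-labelled subjects are retained iff they meet the objective PSG
#' insomnia criteria (WASO >= 30 min, LPS >= 20 min, sleep efficiency <
#' 85%); control-labelled subjects iff sleep efficiency >= 85%. Exclusion
#' reasons are recorded per subject.
#'
#' @param summaries named list of [sleep_summary()] per subject
#' @param groups named group labels (`insomnia` / `non-insomnia`), same
#'   names as `summaries`
#' @return data.frame: `subject_id`, `included`, `reason`
#' @export
screen_subjects <- function(summaries, groups) {
  ids <- names(summaries)
  out <- data.frame(subject_id = ids, included = NA,
                    reason = "", stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    sm <- summaries[[ids[i]]]
    if (groups[[ids[i]]] == "insomnia") {
      crit <- psg_insomnia_criteria(sm)
      out$included[i] <- as.logical(crit)
      out$reason[i] <- paste(attr(crit, "reason"), collapse = "; ")
    } else {
      ok <- psg_control_criteria(sm)
      out$included[i] <- ok
      out$reason[i] <- if (ok) "" else "efficiency < 85%"
    }
  }
  out
}

#' Descriptive group summary table
#'
#' Recomputes the macro-architecture variable set (TST, sleep efficiency,
#' WASO, LPS, stage minutes and percentages) per group from hypnograms
#' alone, as mean (SD), with optional descriptive Welch t-tests.
#'
#' @param summaries named list of [sleep_summary()]
#' @param groups named group labels
#' @param tests add descriptive Welch t-test p-values
#' @return data.frame, one row per variable
#' @export
descriptive_table <- function(summaries, groups, tests = TRUE) {
  grab <- function(sm) {
    c(TST_min = sm$TST, sleep_efficiency_pct = 100 * sm$sleep_efficiency,
      WASO_min = sm$WASO, LPS_min = sm$LPS,
      stats::setNames(sm$stage_minutes,
                      paste0(names(sm$stage_minutes), "_min")),
      stats::setNames(sm$stage_percent,
                      paste0(names(sm$stage_percent), "_pct")))
  }
  m <- t(vapply(summaries, grab, grab(summaries[[1]])))
  g <- unlist(groups)[rownames(m)]
  fmt <- function(v) sprintf("%.1f (%.1f)", mean(v, na.rm = TRUE),
                             stats::sd(v, na.rm = TRUE))
  out <- data.frame(
    variable = colnames(m),
    insomnia = apply(m[g == "insomnia", , drop = FALSE], 2, fmt),
    non_insomnia = apply(m[g == "non-insomnia", , drop = FALSE], 2, fmt),
    stringsAsFactors = FALSE)
  if (tests && length(unique(g)) == 2) {
    out$welch_p <- vapply(colnames(m), function(v) {
      x <- m[g == "insomnia", v]; y <- m[g == "non-insomnia", v]
      if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) return(NA_real_)
      stats::t.test(x, y)$p.value
    }, 0)
  }
  rownames(out) <- NULL
  out
}

# Feature families for one subject on the fast (no-signal) path: features
# are drawn from the cohort generator's own generative law.
fast_path_features <- function(id, d, wesi_shift, is_insomnia) {
  spec <- do.call(rbind, lapply(names(d$stage_spectra), function(stg) {
    fr <- d$stage_spectra[[stg]]
    data.frame(subject_id = id, family = "spectral",
               feature = paste0("spec_", stg, "_", names(fr)),
               value = log(as.numeric(fr)), from_total = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  spin <- data.frame(
    subject_id = id, family = "spindle",
    feature = c("spindle_density_C3", "spindle_density_C4",
                "spindle_dispersion_C3", "spindle_dispersion_C4"),
    value = c(pmax(0.1, d$spindle_density + stats::rnorm(2, 0, 0.05)),
              pmax(0.1, stats::rnorm(2, 1, 0.15))),
    from_total = NA_integer_, stringsAsFactors = FALSE)
  wesi_base <- c(W = stats::qlogis(0.59), N1 = stats::qlogis(0.45),
                 N2 = stats::qlogis(0.25), N3 = stats::qlogis(0.10),
                 R = stats::qlogis(0.35))
  wesi <- data.frame(
    subject_id = id, family = "wesi",
    feature = paste0("wesi_logit_", names(wesi_base)),
    value = wesi_base + stats::rnorm(5, 0, 0.3) +
      if (is_insomnia) wesi_shift else 0,
    from_total = NA_integer_, stringsAsFactors = FALSE)
  rbind(spec, spin, wesi)
}

# Feature families for one subject from its synthesized signal.
signal_path_features <- function(id, d, wesi_model) {
  rec <- preprocess_recording(d$recording)
  h <- d$hypnogram
  spec <- spectral_features(rec, h)
  spec_df <- data.frame(subject_id = id, family = "spectral",
                        feature = spec$feature, value = spec$value,
                        from_total = NA_integer_, stringsAsFactors = FALSE)
  sf <- spindle_features(rec, h)
  spin_df <- data.frame(subject_id = id, family = "spindle",
                        feature = sf$features$feature,
                        value = sf$features$value,
                        from_total = NA_integer_, stringsAsFactors = FALSE)
  w <- window_band_powers_3s(rec)
  stages <- lights_window_stages(h)[w$epoch]
  sm <- wesi_stage_means(wesi_score(wesi_model, w), stages)
  wesi_df <- data.frame(subject_id = id, family = "wesi",
                        feature = paste0("wesi_logit_", sm$stage),
                        value = sm$logit_mean, from_total = NA_integer_,
                        stringsAsFactors = FALSE)
  rbind(spec_df, spin_df, wesi_df)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the cohort, computes macro-architecture summaries, screens
#' subjects against the objective PSG criteria, extracts the four feature
#' families per subject (from synthesized signals when
#' `config$signal = TRUE`, otherwise directly from the generative law),
#' fits the group models, and assembles the report bundle. Subjects failing
#' any stage are excluded with a recorded reason; the run continues.
#'
#' @param config a [cohort_config()]
#' @param output_dir optional directory for CSV outputs
#' @param screen apply subject screening (default TRUE)
#' @return list of class `pipeline_report`: `subjects`, `screening`,
#'   `descriptives`, `features` (long data.frame), `results` (per family),
#'   `transitions`, `log`
#' @export
run_pipeline <- function(config = cohort_config(), output_dir = NULL,
                         screen = TRUE) {
  t0 <- Sys.time()
  cohort <- generate_cohort(config)
  ids <- cohort$subjects$subject_id
  groups <- stats::setNames(cohort$subjects$group, ids)
  summaries <- lapply(cohort$data, function(d) sleep_summary(d$hypnogram))

  screening <- screen_subjects(summaries, as.list(groups))
  if (!screen) screening$included <- TRUE
  keep <- screening$subject_id[screening$included]

  wesi_model <- NULL
  if (config$signal) {
    win <- do.call(rbind, lapply(keep, function(id) {
      rec <- preprocess_recording(cohort$data[[id]]$recording)
      w <- window_band_powers_3s(rec)
      stages <- lights_window_stages(cohort$data[[id]]$hypnogram)[w$epoch]
      cbind(subject_id = id, w, label = as.integer(stages == "W"))
    }))
    wesi_model <- wesi_train(win, seed = config$seed)
  }

  wesi_shift <- if (!is.null(config$effect_sizes$wesi_logit))
    config$effect_sizes$wesi_logit else 0
  features <- do.call(rbind, lapply(keep, function(id) {
    d <- cohort$data[[id]]
    tf <- transition_features(count_transitions(d$hypnogram))
    trans <- data.frame(subject_id = id, family = "transition",
                        feature = tf$feature, value = tf$count,
                        from_total = tf$from_total, stringsAsFactors = FALSE)
    cont <- if (config$signal) {
      signal_path_features(id, d, wesi_model)
    } else {
      fast_path_features(id, d, wesi_shift,
                         groups[[id]] == "insomnia")
    }
    rbind(trans, cont)
  }))

  meta <- cohort$subjects[cohort$subjects$subject_id %in% keep, ]
  results <- list()
  transitions <- NULL
  enough <- length(unique(meta$group)) == 2 && min(table(meta$group)) >= 2
  if (enough) {
    for (fam in c("spectral", "spindle", "wesi")) {
      sub <- features[features$family == fam, ]
      results[[fam]] <- compare_feature_family(sub, meta, family = fam)
    }
    transitions <- compare_transitions(
      features[features$family == "transition", ], meta)
  }

  report <- structure(list(
    subjects = cohort$subjects,
    screening = screening,
    descriptives = descriptive_table(summaries[keep],
                                     as.list(groups[keep])),
    features = features,
    results = results,
    transitions = transitions,
    wesi_model = wesi_model,
    log = list(seed = config$seed, n_included = length(keep),
               n_excluded = sum(!screening$included),
               signal_mode = config$signal,
               runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
               package_version = as.character(utils::packageVersion("sleeparch")))),
    class = "pipeline_report")

  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: %d subjects (%d excluded) | %s mode | %.1f s\n",
              nrow(x$subjects), x$log$n_excluded,
              if (x$log$signal_mode) "signal" else "fast", x$log$runtime_s))
  for (fam in names(x$results)) {
    cat(sprintf("  %s: %d features, %d significant\n", fam,
                nrow(x$results[[fam]]), sum(x$results[[fam]]$significant)))
  }
  if (!is.null(x$transitions)) {
    cat(sprintf("  transition: %d modelled, %d significant\n",
                sum(x$transitions$route %in% c("hurdle", "glmm")),
                sum(x$transitions$significant)))
  }
  invisible(x)
}

#' Write a report bundle to CSV files plus a JSON manifest
#'
#' @param report a `pipeline_report`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(report$screening, file.path(dir, "screening.csv"),
                   row.names = FALSE)
  utils::write.csv(report$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  for (fam in names(report$results)) {
    utils::write.csv(report$results[[fam]],
                     file.path(dir, paste0("results_", fam, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$transitions)) {
    utils::write.csv(report$transitions,
                     file.path(dir, "results_transition.csv"),
                     row.names = FALSE)
    utils::write.csv(transition_grid(report$transitions),
                     file.path(dir, "transition_grid.csv"),
                     row.names = TRUE)
  }
  jsonlite::write_json(report$log, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the analysis pipeline on recordings stored on disk
#'
#' File-input mode: reads a cohort directory as written by [write_cohort()]
#' (per-subject EDF + `<id>_hypnogram.csv`, plus `subjects.csv` metadata),
#' harmonizes each recording, extracts the four feature families, screens
#' subjects and fits the group models. Subjects whose recordings are
#' unusable are excluded with the recorded reason; the run continues.
#'
#' @param dir cohort directory
#' @param output_dir optional directory for CSV outputs
#' @param screen apply subject screening (default TRUE)
#' @param seed seed for the WESI training split
#' @return a `pipeline_report` (see [run_pipeline()])
#' @export
run_pipeline_files <- function(dir, output_dir = NULL, screen = TRUE,
                               seed = 1L) {
  t0 <- Sys.time()
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  failures <- character()
  loaded <- list()
  for (id in subjects$subject_id) {
    got <- tryCatch(
      read_recording(file.path(dir, paste0(id, ".edf")),
                     file.path(dir, paste0(id, "_hypnogram.csv"))),
      condition = function(c) conditionMessage(c))
    if (is.character(got)) failures[id] <- got else loaded[[id]] <- got
  }
  subjects <- subjects[subjects$subject_id %in% names(loaded), ]
  ids <- subjects$subject_id
  groups <- stats::setNames(subjects$group, ids)
  summaries <- lapply(loaded, function(d) sleep_summary(d$hypnogram))

  screening <- screen_subjects(summaries, as.list(groups))
  if (!screen) screening$included <- TRUE
  keep <- screening$subject_id[screening$included]

  pre <- lapply(loaded[keep], function(d)
    preprocess_recording(d$recording))
  win <- do.call(rbind, lapply(keep, function(id) {
    w <- window_band_powers_3s(pre[[id]])
    stages <- lights_window_stages(loaded[[id]]$hypnogram)[w$epoch]
    cbind(subject_id = id, w, label = as.integer(stages == "W"))
  }))
  wesi_model <- wesi_train(win, seed = seed)

  features <- do.call(rbind, lapply(keep, function(id) {
    h <- loaded[[id]]$hypnogram
    tf <- transition_features(count_transitions(h))
    trans <- data.frame(subject_id = id, family = "transition",
                        feature = tf$feature, value = tf$count,
                        from_total = tf$from_total, stringsAsFactors = FALSE)
    rbind(trans,
          signal_path_features(id, list(recording = loaded[[id]]$recording,
                                        hypnogram = h), wesi_model))
  }))

  meta <- subjects[subjects$subject_id %in% keep, ]
  results <- list()
  transitions <- NULL
  if (length(unique(meta$group)) == 2 && min(table(meta$group)) >= 2) {
    for (fam in c("spectral", "spindle", "wesi")) {
      results[[fam]] <- compare_feature_family(
        features[features$family == fam, ], meta, family = fam)
    }
    transitions <- compare_transitions(
      features[features$family == "transition", ], meta)
  }
  report <- structure(list(
    subjects = subjects, screening = screening,
    descriptives = descriptive_table(summaries[keep],
                                     as.list(groups[keep])),
    features = features, results = results, transitions = transitions,
    wesi_model = wesi_model,
    log = list(seed = seed, n_included = length(keep),
               n_excluded = sum(!screening$included),
               unusable = as.list(failures), signal_mode = TRUE,
               runtime_s = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")),
               package_version =
                 as.character(utils::packageVersion("sleeparch")))),
    class = "pipeline_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Render transition results as a 5x5 from/to grid
#'
#' Cells hold the zero-part group estimate (log-odds of the transition
#' occurring at all) with significant transitions marked `*`.
#'
#' @param transitions result of [compare_transitions()]
#' @return 5x5 character matrix
#' @export
transition_grid <- function(transitions) {
  st <- sleep_stages()
  g <- matrix("", 5, 5, dimnames = list(st, st))
  for (i in seq_len(nrow(transitions))) {
    parts <- strsplit(sub("^trans_", "", transitions$feature[i]), "_")[[1]]
    est <- transitions$zero_estimate[i]
    if (is.na(est)) est <- transitions$count_estimate[i]
    g[parts[1], parts[2]] <- if (transitions$route[i] == "not-modelled") "-"
    else paste0(sprintf("%.3f", est),
                if (isTRUE(transitions$significant[i])) "*" else "")
  }
  g
}
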