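# Cohort generator: Markov hypnograms, EEG synthesis ground truth,
# determinism and the feature-level simulator.

test_that("generate_hypnogram honours degenerate chains and validates input", {
  ident <- diag(5); dimnames(ident) <- list(sleep_stages(), sleep_stages())
  expect_equal(generate_hypnogram(ident, 10, seed = 1)$stages, rep("W", 10))

  det <- matrix(0, 5, 5, dimnames = list(sleep_stages(), sleep_stages()))
  det["W", "N1"] <- 1; det["N1", "N1"] <- 1
  det["N2", "N2"] <- det["N3", "N3"] <- det["R", "R"] <- 1
  expect_equal(generate_hypnogram(det, 10, seed = 1)$stages,
               c("W", rep("N1", 9)))

  bad <- ident; bad[1, 1] <- 0.9
  expect_error(generate_hypnogram(bad, 10), "row-stochastic")
  expect_error(generate_hypnogram(ident, 1), ">= 2")
})

test_that("empirical transition frequencies match the chain within 3 SE", {
  tm <- default_transition_matrix("insomnia")
  h <- generate_hypnogram(tm, 5000, seed = 77)
  cnt <- count_transitions(h)
  p <- transition_probabilities(cnt)
  n_from <- rowSums(cnt)
  ok <- n_from >= 100
  se <- sqrt(tm * (1 - tm) / n_from)
  expect_true(all(abs(p[ok, ] - tm[ok, ]) <= 3 * se[ok, ] + 1e-12))
})

test_that("default transition matrices are row-stochastic in both groups", {
  for (g in c("control", "insomnia")) {
    m <- default_transition_matrix(g, p_to_wake = 0.05)
    expect_equal(rowSums(m), rep(1, 5), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(m >= 0))
  }
  # the p_to_wake shift raises every non-Wake row's to-Wake probability
  base <- default_transition_matrix("control")
  shifted <- default_transition_matrix("control", p_to_wake = 0.05)
  expect_equal(shifted[2:5, "W"], base[2:5, "W"] + 0.05,
               ignore_attr = TRUE)
})

test_that("synthesize_recording plants valid, well-separated ground truth", {
  fx <- n2_fixture(n_epochs = 20, seed = 31)
  sp <- fx$gt$spindles[fx$gt$spindles$channel == "C3", ]
  so <- fx$gt$sos[fx$gt$sos$channel == "C3", ]
  expect_true(all(sp$end_s - sp$start_s >= 0.3 & sp$end_s - sp$start_s <= 3))
  expect_true(all(so$end_s - so$start_s >= 0.8 & so$end_s - so$start_s <= 2))
  expect_true(all(sp$peak_s >= sp$start_s & sp$peak_s <= sp$end_s))

  # density 0 -> no spindles
  h <- hypnogram(rep("N2", 10))
  none <- synthesize_recording(h, spindle_density = 0, seed = 1)
  expect_equal(nrow(none$ground_truth$spindles), 0)

  # coupling_phase = 180 -> planted peaks at the SO temporal midpoint
  mid <- synthesize_recording(h, spindle_density = 4, so_rate = 6,
                              coupling_phase = 180, seed = 2)
  gsp <- mid$ground_truth$spindles
  gso <- mid$ground_truth$sos
  for (i in seq_len(nrow(gsp))) {
    j <- which(gso$channel == gsp$channel[i] &
                 gso$start_s <= gsp$peak_s[i] & gso$end_s >= gsp$peak_s[i])
    if (length(j)) {
      expect_equal(gsp$peak_s[i],
                   (gso$start_s[j[1]] + gso$end_s[j[1]]) / 2,
                   tolerance = 1e-6)
    }
  }
  expect_error(synthesize_recording(hypnogram(rep("N2", 2)),
                                    spindle_density = -1), "rates")
})

test_that("stage band fractions steer the synthesized spectrum", {
  # alpha-dominant Wake stage -> downstream relative alpha near 1
  spectra <- default_stage_spectra()
  spectra$W <- c(delta = 0.01, theta = 0.01, alpha = 0.97, beta = 0.01)
  h <- hypnogram(rep("W", 20))
  sy <- synthesize_recording(h, spectra, spindle_density = 0, so_rate = 0,
                             seed = 5)
  rec <- preprocess_recording(sy$recording)
  feats <- spectral_features(rec, h)
  # band-edge leakage of the 2-s multitaper caps this below the planted
  # 0.97, but alpha must dominate by far
  vals <- exp(feats$value[feats$stage == "W"])
  names(vals) <- feats$band[feats$stage == "W"]
  expect_gt(vals[["alpha"]], 0.8)
  expect_true(all(vals[["alpha"]] > 5 * vals[c("delta", "theta", "beta")]))
})

test_that("generate_cohort is deterministic and respects the null config", {
  cfg <- cohort_config(n_insomnia = 4, n_control = 4,
                       recording_duration = 60, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(lapply(a$data, `[[`, "hypnogram"),
                   lapply(b$data, `[[`, "hypnogram"))

  # null cohort: both groups share one generative law (label-exchangeable)
  null_cfg <- cohort_config(n_insomnia = 30, n_control = 30,
                            recording_duration = 120, seed = 7,
                            effect_sizes = list(p_to_wake = 0,
                                                rel_alpha_wake = 0,
                                                rel_alpha_n1 = 0,
                                                spindle_density = 0,
                                                wesi_logit = 0))
  nc <- generate_cohort(null_cfg)
  dens <- vapply(nc$data, `[[`, 0, "spindle_density")
  g <- nc$subjects$group
  expect_gt(stats::t.test(dens[g == "insomnia"],
                          dens[g == "non-insomnia"])$p.value, 0.01)
  alpha_w <- vapply(nc$data, function(d) d$stage_spectra$W[["alpha"]], 0)
  expect_gt(stats::t.test(alpha_w[g == "insomnia"],
                          alpha_w[g == "non-insomnia"])$p.value, 0.01)
})

test_that("cohort defaults land near the published descriptives", {
  cfg <- cohort_config(n_insomnia = 40, n_control = 40, seed = 11)
  co <- generate_cohort(cfg)
  sums <- lapply(co$data, function(d) sleep_summary(d$hypnogram))
  g <- co$subjects$group
  se_ins <- mean(vapply(sums[g == "insomnia"], `[[`, 0, "sleep_efficiency"))
  se_ctl <- mean(vapply(sums[g == "non-insomnia"], `[[`, 0,
                        "sleep_efficiency"))
  expect_lt(se_ins, 0.75)
  expect_gt(se_ctl, 0.88)
  scr <- screen_subjects(sums, stats::setNames(as.list(g),
                                               co$subjects$subject_id))
  expect_gt(mean(scr$included), 0.9)
})

test_that("simulate_feature_cohort emits the four families per subject", {
  co <- simulate_feature_cohort(5, 5, n_epochs = 240, seed = 3)
  expect_equal(nrow(co$subjects), 10)
  per_subj <- table(co$features$family[co$features$subject_id == "S0001"])
  expect_equal(as.integer(per_subj[c("transition", "spectral", "spindle",
                                     "wesi")]),
               c(25L, 2L, 2L, 5L))
  # deterministic under a seed
  co2 <- simulate_feature_cohort(5, 5, n_epochs = 240, seed = 3)
  expect_identical(co$features, co2$features)
})
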