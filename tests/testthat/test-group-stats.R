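# Mixed-model triplets, LRTs, FDR with fixed family sizes, hurdle routing
# and the transition significance rule.

meta_fixture <- function(n = 60, seed = 71) {
  set.seed(seed)
  g <- rep(c("insomnia", "non-insomnia"), each = n / 2)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             age = rnorm(n, 53, 12),
             sex = sample(c("male", "female"), n, TRUE),
             group = g,
             site = paste0("site", (seq_len(n) - 1L) %% 3 + 1L),
             stringsAsFactors = FALSE)
}

test_that("model triplet nests correctly and recovers a planted shift", {
  meta <- meta_fixture(120)
  set.seed(72)
  y <- rnorm(120, 0, 1) + ifelse(meta$group == "insomnia", 0.8, 0)
  tri <- fit_model_triplet(y, meta)
  expect_lte(as.numeric(logLik(tri$null)), as.numeric(logLik(tri$main)))
  expect_lte(as.numeric(logLik(tri$main)),
             as.numeric(logLik(tri$interaction)))
  lrt <- likelihood_ratio_test(tri$null, tri$main)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p_value, 0.01)
  gc <- group_coefficient(tri)
  expect_gt(gc$estimate, 0)
  expect_true(gc$ci[1] < 0.8 && 0.8 < gc$ci[2])
  expect_error(fit_model_triplet(y[1:3], meta[1:3, ]), ">= 2 subjects")
})

test_that("LRT statistic matches hand arithmetic and rejects non-nesting", {
  meta <- meta_fixture(80)
  set.seed(73)
  y <- rnorm(80)
  tri <- fit_model_triplet(y, meta)
  lrt <- likelihood_ratio_test(tri$null, tri$main)
  hand <- 2 * (as.numeric(logLik(tri$main)) - as.numeric(logLik(tri$null)))
  expect_equal(lrt$statistic, max(0, hand), tolerance = 1e-10)
  expect_equal(lrt$p_value, pchisq(lrt$statistic, 1, lower.tail = FALSE))
  expect_error(likelihood_ratio_test(tri$main, tri$null), "nested")
  # identical models -> statistic 0, p = 1
  same <- likelihood_ratio_test(tri$main, tri$main)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("null LRT p-values are approximately uniform", {
  meta <- meta_fixture(100, seed = 74)
  set.seed(75)
  ps <- replicate(60, {
    tri <- fit_model_triplet(rnorm(100), meta, include_interaction = FALSE)
    likelihood_ratio_test(tri$null, tri$main)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("fdr_adjust implements BH with family-size padding", {
  expect_equal(fdr_adjust(0.05, 1), 0.05)
  # hand BH: p=(0.01,0.02,0.03,0.04), N=4 -> all 0.04
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04), 4), rep(0.04, 4))
  # padding to the larger family is more conservative
  p <- c(0.001, 0.02, 0.04)
  small <- fdr_adjust(p, 3)
  big <- fdr_adjust(p, 10)
  expect_true(all(big >= small))
  # hand check with placeholders: ranks as if 10 tests were run
  expect_equal(big, pmin(1, cummax(rev(cummin(rev(p * 10 / seq_along(p)))))))
  expect_true(all(fdr_adjust(p, 25) >= p))
  expect_error(fdr_adjust(c(0.5, 0.2), 1), "family_size")
})

test_that("family sizes are the fixed published constants", {
  fs <- family_sizes()
  expect_equal(fs[["spectral"]], 180L)
  expect_equal(fs[["spindle"]], 14L)
  expect_equal(fs[["wesi"]], 10L)
  expect_equal(fs[["transition"]], 25L)
})

test_that("transition routing follows the prevalence gates", {
  expect_equal(route_transition_model(rep(0, 100)), "not-modelled")
  expect_equal(route_transition_model(c(rep(0, 99), 1)), "not-modelled")
  expect_equal(route_transition_model(c(rep(0, 98), 1, 1)), "hurdle")
  expect_equal(route_transition_model(rep(c(0, 3), 50)), "hurdle")
  expect_equal(route_transition_model(c(0, rep(2, 99))), "glmm")  # 99%
  expect_equal(route_transition_model(rep(2, 100)), "glmm")
})

test_that("hurdle parts separate occurrence and magnitude effects", {
  set.seed(76)
  meta <- meta_fixture(200, seed = 77)
  ins <- meta$group == "insomnia"
  n_tot <- rep(400L, 200)

  # difference only in occurrence probability
  occ <- rbinom(200, 1, ifelse(ins, 0.8, 0.4))
  counts <- occ * rbinom(200, n_tot, 0.02)
  counts[occ == 1 & counts == 0] <- 1
  hz <- fit_hurdle(counts, n_tot, meta)
  expect_lt(hz$zero_coef$p_value, 0.05)
  expect_gt(hz$zero_coef$estimate, 0)
  expect_gt(hz$count_coef$p_value, 0.05)
  expect_lt(hz$lrt$p_value, 0.05)

  # difference only in magnitude among occurrers
  occ2 <- rbinom(200, 1, 0.6)
  counts2 <- occ2 * rbinom(200, n_tot, ifelse(ins, 0.04, 0.02))
  counts2[occ2 == 1 & counts2 == 0] <- 1
  hc <- fit_hurdle(counts2, n_tot, meta)
  expect_lt(hc$count_coef$p_value, 0.05)
  expect_gt(hc$count_coef$estimate, 0)
  expect_gt(hc$zero_coef$p_value, 0.05)

  expect_error(fit_hurdle(rep(2, 200), n_tot, meta), "not routed")
})

test_that("the two-condition transition significance rule holds", {
  mk <- function(pz, pc) {
    structure(list(zero_coef = list(p_value = pz, estimate = 1),
                   count_coef = list(p_value = pc, estimate = 1)),
              class = "hurdle_result")
  }
  expect_false(transition_significance(mk(0.001, 0.001), p_adj = 0.2))
  expect_false(transition_significance(mk(0.5, 0.6), p_adj = 0.01))
  expect_true(transition_significance(mk(0.01, 0.9), p_adj = 0.01))
  expect_true(transition_significance(mk(0.9, 0.01), p_adj = 0.01))
})

test_that("compare_feature_family assembles adjusted results per feature", {
  set.seed(78)
  co <- simulate_feature_cohort(40, 40, effect_sizes =
                                  list(spindle_density = -0.9), seed = 79)
  sub <- co$features[co$features$family == "spindle", ]
  res <- compare_feature_family(sub, co$subjects, family = "spindle")
  expect_equal(res$family_n[1], 14)
  expect_true(all(res$p_main_adj >= res$p_main, na.rm = TRUE))
  expect_lt(res$estimate[res$feature == "spindle_density_C3"], 0)
})
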