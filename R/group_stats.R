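# Mixed-effects group comparison machinery: null / main-effect / interaction
# model triplets, likelihood-ratio tests, FDR adjustment with fixed family
# sizes, hurdle-model routing for sparse transition counts, and the
# two-condition transition significance rule.

#' Fixed multiplicity family sizes
#'
#' FDR within each feature family uses the exploratory family sizes, which
#' are larger than the reported feature counts (the conservative choice):
#' spectral 180, spindle 14, WESI 10, transition 25.
#'
#' @return named integer vector
#' @export
family_sizes <- function() {
  c(spectral = 180L, spindle = 14L, wesi = 10L, transition = 25L)
}

# Shared fixed-effect covariate data: age centred at 50, factors with
# non-insomnia / male / first-site reference levels.
prepare_model_frame <- function(values, metadata) {
  d <- merge(data.frame(subject_id = metadata$subject_id, value = values,
                        stringsAsFactors = FALSE),
             metadata, by = "subject_id")
  d$age_c <- d$age - 50
  d$sex <- factor(d$sex, c("male", "female"))
  d$group <- factor(d$group, c("non-insomnia", "insomnia"))
  d$site <- factor(d$site)
  d$subject_id <- factor(d$subject_id)
  d[!is.na(d$value), ]
}

# Random-effect structure: subject intercept only when subjects repeat
# (with one observation per subject it is an exact variance ridge with the
# residual and is reported as collapsed); site intercept only with >= 2
# sites. Falls back to lm() when no random effect survives.
re_terms <- function(d, include_subject_re = TRUE) {
  terms <- character()
  notes <- character()
  if (include_subject_re) {
    if (anyDuplicated(d$subject_id)) {
      terms <- c(terms, "(1 | subject_id)")
    } else {
      notes <- c(notes,
                 "subject intercept collapsed into residual (1 obs/subject)")
    }
  }
  if (nlevels(droplevels(d$site)) >= 2) {
    terms <- c(terms, "(1 | site)")
  } else {
    notes <- c(notes, "site random effect dropped (single site)")
  }
  list(terms = terms, notes = notes)
}

fit_lmm <- function(fixed, d, re) {
  if (length(re$terms)) {
    fml <- stats::as.formula(paste("value ~", fixed, "+",
                                   paste(re$terms, collapse = " + ")))
    suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
  } else {
    stats::lm(stats::as.formula(paste("value ~", fixed)), data = d)
  }
}

#' Fit the null / main-effect / interaction model triplet
#'
#' All three models share the data and random-effect structure and are fit
#' by maximum likelihood (so likelihood-ratio tests on fixed effects are
#' valid): null `value ~ age_c*sex`, main `+ group`, interaction
#' `value ~ age_c*sex*group`, each plus random intercepts for subject and
#' site where identifiable.
#'
#' @param values numeric feature values, one per metadata row
#' @param metadata data.frame: subject_id, age, sex
#'   (`male`/`female`), group (`insomnia`/`non-insomnia`), site
#' @param include_subject_re keep the subject random intercept when
#'   identifiable
#' @param include_interaction also fit the interaction model (skippable in
#'   repeated simulation runs where only the null-vs-main test is needed)
#' @return list of class `model_triplet`: `null`, `main`, `interaction`
#'   fits, `notes`, `n`
#' @export
fit_model_triplet <- function(values, metadata, include_subject_re = TRUE,
                              include_interaction = TRUE) {
  d <- prepare_model_frame(values, metadata)
  if (length(unique(d$group)) < 2 || min(table(d$group)) < 2) {
    stop("need >= 2 subjects per group with non-missing values")
  }
  re <- re_terms(d, include_subject_re)
  structure(list(
    null = fit_lmm("age_c * sex", d, re),
    main = fit_lmm("age_c * sex + group", d, re),
    interaction = if (include_interaction)
      fit_lmm("age_c * sex * group", d, re),
    notes = re$notes, n = nrow(d)),
    class = "model_triplet")
}

n_fixed <- function(fit) {
  if (inherits(fit, "merMod")) length(lme4::fixef(fit)) else
    length(stats::coef(fit))
}

fixed_names <- function(fit) {
  if (inherits(fit, "merMod")) names(lme4::fixef(fit)) else
    names(stats::coef(fit))
}

#' Likelihood-ratio test between nested fits
#'
#' Chi-squared test on the difference in fixed-effect parameter counts.
#' The nested model's fixed effects must be a subset of the fuller model's.
#'
#' @param nested,fuller fits sharing data (ML, not REML)
#' @return list: `statistic`, `df`, `p_value`
#' @export
likelihood_ratio_test <- function(nested, fuller) {
  if (!all(fixed_names(nested) %in% fixed_names(fuller))) {
    stop("models are not nested (fixed effects)")
  }
  stat <- max(0, 2 * (as.numeric(stats::logLik(fuller)) -
                        as.numeric(stats::logLik(nested))))
  df <- n_fixed(fuller) - n_fixed(nested)
  if (df < 0) stop("fuller model adds no fixed-effect parameters")
  if (df == 0) return(list(statistic = 0, df = 0L, p_value = 1))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Wald summary (estimate, SE, z, p) of one fixed effect.
wald_coef <- function(fit, name) {
  if (inherits(fit, "merMod")) {
    est <- lme4::fixef(fit)
    vc <- suppressWarnings(as.matrix(stats::vcov(fit)))
  } else {
    est <- stats::coef(fit)
    vc <- stats::vcov(fit)
  }
  if (!name %in% names(est)) return(NULL)
  se <- sqrt(vc[name, name])
  z <- est[[name]] / se
  list(estimate = est[[name]], se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       ci = est[[name]] + c(-1, 1) * stats::qnorm(0.975) * se)
}

#' Insomnia group coefficient of a triplet's main-effect model
#' @param triplet a `model_triplet`
#' @return list: `estimate`, `se`, `z`, `p_value`, `ci`
#' @export
group_coefficient <- function(triplet) {
  wald_coef(triplet$main, "groupinsomnia")
}

#' Benjamini-Hochberg adjustment with a fixed family size
#'
#' Step-up FDR computed as if `family_size` tests were run: absent tests
#' enter as non-significant placeholders at p = 1.
#'
#' @param p raw p-values in `[0, 1]`
#' @param family_size total family size (>= `length(p)`)
#' @return adjusted p-values, same length/order as `p`
#' @export
fdr_adjust <- function(p, family_size = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE),
            family_size >= length(p))
  padded <- c(p, rep(1, family_size - length(p)))
  stats::p.adjust(padded, method = "BH")[seq_along(p)]
}

#' Compare a continuous feature family between groups
#'
#' Fits the model triplet per feature, runs the null-vs-main and
#' main-vs-interaction likelihood-ratio tests, and FDR-adjusts within the
#' family at its fixed family size.
#'
#' @param features long data.frame: `subject_id`, `feature`, `value`
#' @param metadata subject metadata (see [fit_model_triplet()])
#' @param family one of `"spectral"`, `"spindle"`, `"wesi"`
#' @param ... passed to [fit_model_triplet()]
#' @return data.frame, one row per feature: LRT p-values, adjusted
#'   p-values, group estimate/CI, significance flag
#' @export
compare_feature_family <- function(features, metadata,
                                   family = c("spectral", "spindle", "wesi"),
                                   ...) {
  family <- match.arg(family)
  fam_n <- family_sizes()[[family]]
  feats <- unique(features$feature)
  if (length(feats) > fam_n) {
    stop("more features than the fixed family size")
  }
  rows <- lapply(feats, function(f) {
    sub <- features[features$feature == f, ]
    vals <- sub$value[match(metadata$subject_id, sub$subject_id)]
    tri <- tryCatch(fit_model_triplet(vals, metadata, ...),
                    error = function(e) NULL)
    if (is.null(tri)) {
      return(data.frame(feature = f, n = sum(!is.na(vals)),
                        estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_main = NA_real_,
                        p_interaction = NA_real_))
    }
    lrt_m <- likelihood_ratio_test(tri$null, tri$main)
    lrt_i <- likelihood_ratio_test(tri$main, tri$interaction)
    gc <- group_coefficient(tri)
    data.frame(feature = f, n = tri$n, estimate = gc$estimate,
               ci_low = gc$ci[1], ci_high = gc$ci[2],
               p_main = lrt_m$p_value, p_interaction = lrt_i$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_main_adj <- fdr_adjust(out$p_main, fam_n)
  out$p_interaction_adj <- fdr_adjust(out$p_interaction, fam_n)
  out$family <- family
  out$family_n <- fam_n
  out$significant <- !is.na(out$p_main_adj) & out$p_main_adj < 0.05
  out
}

#' Route a transition to its count model
#'
#' Prevalence is the fraction of recordings containing the transition at
#' least once: below 1.5% the transition is not modelled, between 1.5% and
#' 98.5% a hurdle model is used, above 98.5% a generalized mixed-effects
#' model.
#'
#' @param counts per-recording counts for one transition
#' @return `"not-modelled"`, `"hurdle"`, or `"glmm"`
#' @export
route_transition_model <- function(counts) {
  stopifnot(length(counts) >= 1)
  prev <- mean(counts > 0)
  if (prev < 0.015) "not-modelled"
  else if (prev <= 0.985) "hurdle"
  else "glmm"
}

fit_binomial_mixed <- function(fixed, d, re_terms, weights_ok = TRUE) {
  resp <- "cbind(k, n_tot - k)"
  if (length(re_terms)) {
    fml <- stats::as.formula(paste(resp, "~", fixed, "+",
                                   paste(re_terms, collapse = " + ")))
    suppressWarnings(suppressMessages(
      lme4::glmer(fml, data = d, family = stats::binomial,
                  control = lme4::glmerControl(
                    check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    calc.derivs = FALSE))))
  } else {
    suppressWarnings(
      stats::glm(stats::as.formula(paste(resp, "~", fixed)), data = d,
                 family = stats::binomial))
  }
}

#' Fit the hurdle model for one transition
#'
#' Two logistic-link mixed models sharing the covariate structure of
#' [fit_model_triplet()]: the zero part models whether a recording contains
#' the transition at all (zero versus non-zero); the count part models, for
#' recordings that contain it, the transition count as binomial out of the
#' recording's total transitions leaving the source stage. The subject
#' random intercept is unidentifiable from one binomial draw per subject
#' and is dropped unless `include_subject_re = TRUE`. The combined
#' likelihood-ratio test adds the two parts (df = 2).
#'
#' @param counts per-recording transition counts
#' @param from_total per-recording total transitions from the source stage
#' @param metadata subject metadata, same order as `counts`
#' @param include_subject_re force the subject random intercept
#' @return list of class `hurdle_result`: `route`, `prevalence`,
#'   `zero_coef` and `count_coef` (group Wald summaries), `lrt`
#'   (combined), per-part fits
#' @export
fit_hurdle <- function(counts, from_total, metadata,
                       include_subject_re = FALSE) {
  route <- route_transition_model(counts)
  if (route != "hurdle") {
    stop("transition not routed to hurdle (prevalence gating)")
  }
  d0 <- prepare_model_frame(as.numeric(counts > 0), metadata)
  d0$k <- d0$value
  d0$n_tot <- 1
  re0 <- re_terms(d0, include_subject_re)$terms
  z_null <- fit_binomial_mixed("age_c * sex", d0, re0)
  z_main <- fit_binomial_mixed("age_c * sex + group", d0, re0)

  keep <- counts > 0 & from_total > 0
  dc <- prepare_model_frame(counts, metadata)
  dc <- dc[dc$subject_id %in% metadata$subject_id[keep], ]
  dc$k <- dc$value
  dc$n_tot <- from_total[match(dc$subject_id, metadata$subject_id)]
  rec <- re_terms(dc, include_subject_re)$terms
  c_null <- fit_binomial_mixed("age_c * sex", dc, rec)
  c_main <- fit_binomial_mixed("age_c * sex + group", dc, rec)

  stat <- max(0, 2 * (as.numeric(stats::logLik(z_main)) +
                        as.numeric(stats::logLik(c_main)) -
                        as.numeric(stats::logLik(z_null)) -
                        as.numeric(stats::logLik(c_null))))
  structure(list(
    route = route, prevalence = mean(counts > 0),
    zero_coef = wald_coef(z_main, "groupinsomnia"),
    count_coef = wald_coef(c_main, "groupinsomnia"),
    lrt = list(statistic = stat, df = 2L,
               p_value = stats::pchisq(stat, 2, lower.tail = FALSE)),
    fits = list(zero_null = z_null, zero_main = z_main,
                count_null = c_null, count_main = c_main)),
    class = "hurdle_result")
}

#' Fit the GLMM route for a near-universal transition
#'
#' Binomial counts out of total source-stage transitions, logit link, same
#' covariates; used when more than 98.5% of recordings contain the
#' transition.
#'
#' @inheritParams fit_hurdle
#' @return list of class `glmm_result`: `route`, `count_coef`, `lrt`, fits
#' @export
fit_transition_glmm <- function(counts, from_total, metadata,
                                include_subject_re = FALSE) {
  keep <- from_total > 0
  d <- prepare_model_frame(counts, metadata)
  d <- d[d$subject_id %in% metadata$subject_id[keep], ]
  d$k <- d$value
  d$n_tot <- from_total[match(d$subject_id, metadata$subject_id)]
  re <- re_terms(d, include_subject_re)$terms
  m0 <- fit_binomial_mixed("age_c * sex", d, re)
  m1 <- fit_binomial_mixed("age_c * sex + group", d, re)
  stat <- max(0, 2 * (as.numeric(stats::logLik(m1)) -
                        as.numeric(stats::logLik(m0))))
  structure(list(
    route = "glmm", prevalence = mean(counts > 0),
    zero_coef = NULL,
    count_coef = wald_coef(m1, "groupinsomnia"),
    lrt = list(statistic = stat, df = 1L,
               p_value = stats::pchisq(stat, 1, lower.tail = FALSE)),
    fits = list(null = m0, main = m1)),
    class = "glmm_result")
}

#' Two-condition transition significance rule
#'
#' A transition differs significantly between groups iff the FDR-adjusted
#' likelihood-ratio p-value is below `alpha` AND at least one insomnia
#' coefficient (zero- or count-part) is individually significant at
#' `alpha`.
#'
#' @param result a `hurdle_result` or `glmm_result`
#' @param p_adj FDR-adjusted LRT p-value for this transition
#' @param alpha significance level (0.05)
#' @return logical scalar
#' @export
transition_significance <- function(result, p_adj, alpha = 0.05) {
  if (is.na(p_adj) || p_adj >= alpha) return(FALSE)
  coef_ps <- c(if (!is.null(result$zero_coef)) result$zero_coef$p_value,
               if (!is.null(result$count_coef)) result$count_coef$p_value)
  any(coef_ps < alpha, na.rm = TRUE)
}

#' Compare all 25 transitions between groups
#'
#' Routes each transition by prevalence, fits the hurdle or GLMM model,
#' applies the family-size-25 FDR adjustment to the modelled transitions,
#' and applies the two-condition significance rule.
#'
#' @param transition_features long data.frame: `subject_id`, `feature`,
#'   `value` (count), `from_total`
#' @param metadata subject metadata
#' @param ... passed to the model fitters
#' @return data.frame, one row per transition: route, prevalence, estimate
#'   summaries, raw and adjusted p, significance flag
#' @export
compare_transitions <- function(transition_features, metadata, ...) {
  feats <- unique(transition_features$feature)
  res <- lapply(feats, function(f) {
    sub <- transition_features[transition_features$feature == f, ]
    idx <- match(metadata$subject_id, sub$subject_id)
    counts <- sub$value[idx]
    ft <- sub$from_total[idx]
    route <- route_transition_model(counts)
    if (route == "not-modelled") {
      return(list(feature = f, route = route, prevalence = mean(counts > 0),
                  fit = NULL))
    }
    fit <- tryCatch(
      if (route == "hurdle") fit_hurdle(counts, ft, metadata, ...)
      else fit_transition_glmm(counts, ft, metadata, ...),
      error = function(e) NULL)
    list(feature = f, route = if (is.null(fit)) "failed" else route,
         prevalence = mean(counts > 0), fit = fit)
  })
  p_raw <- vapply(res, function(r)
    if (is.null(r$fit)) NA_real_ else r$fit$lrt$p_value, 0)
  p_adj <- rep(NA_real_, length(p_raw))
  modelled <- !is.na(p_raw)
  p_adj[modelled] <- fdr_adjust(p_raw[modelled], family_sizes()[["transition"]])
  out <- data.frame(
    feature = vapply(res, `[[`, "", "feature"),
    route = vapply(res, `[[`, "", "route"),
    prevalence = vapply(res, `[[`, 0, "prevalence"),
    zero_estimate = vapply(res, function(r)
      if (!is.null(r$fit$zero_coef)) r$fit$zero_coef$estimate else NA_real_, 0),
    count_estimate = vapply(res, function(r)
      if (!is.null(r$fit$count_coef)) r$fit$count_coef$estimate else NA_real_, 0),
    p_raw = p_raw, p_adj = p_adj, stringsAsFactors = FALSE)
  out$significant <- vapply(seq_along(res), function(i) {
    if (is.null(res[[i]]$fit)) FALSE
    else transition_significance(res[[i]]$fit, p_adj[i])
  }, TRUE)
  out
}
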