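# WESI feature construction, robust sparse training, scoring, stage
# summaries and the finite-difference back-transform.

test_that("build_feature_vector emits 14 predictors matching hand values", {
  rel <- data.frame(delta = 0.4, theta = 0.3, alpha = 0.2, beta = 0.1)
  std <- list(center = c(delta = 0, theta = 0, alpha = 0, beta = 0),
              scale = c(delta = 1, theta = 1, alpha = 1, beta = 1))
  fb <- build_feature_vector(rel, std)
  expect_equal(ncol(fb$features), 14)
  z <- log(c(0.4, 0.3, 0.2, 0.1) / (1 - c(0.4, 0.3, 0.2, 0.1)))
  want <- c(z,
            z[1] * z[2], z[1] * z[3], z[1] * z[4],
            z[2] * z[3], z[2] * z[4], z[3] * z[4],
            z^2)
  expect_equal(as.numeric(fb$features[1, ]), want)
})

test_that("training-set standardization gives mean 0 / SD 1 base features", {
  set.seed(61)
  w <- simulate_wesi_windows(10, 100, seed = 1)
  fb <- build_feature_vector(w)
  base <- fb$features[, 1:4]
  expect_equal(colMeans(base), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(base, 2, sd), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # degenerate relative powers are clipped, not infinite
  fb2 <- build_feature_vector(
    data.frame(delta = 1, theta = 0, alpha = 0, beta = 0),
    fb$standardization)
  expect_true(all(is.finite(fb2$features)))
})

test_that("wesi_train learns separable spectra and fails on shuffled labels", {
  w <- simulate_wesi_windows(25, 400, separation = 2, seed = 10)
  m <- wesi_train(w, seed = 42)
  expect_length(m$coefficients, 15)
  ev <- wesi_evaluate(m, w[m$test_index, ])
  expect_gte(ev$auc, 0.95)
  expect_gt(ev$accuracy, 0.9)

  set.seed(11)
  w2 <- w[sample.int(nrow(w), 10000), ]
  w2$label <- sample(w2$label)
  m2 <- wesi_train(w2, seed = 42)
  ev2 <- wesi_evaluate(m2, w2[m2$test_index, ])
  expect_equal(ev2$auc, 0.5, tolerance = 0.05)
})

test_that("very large lambda shrinks all non-intercept coefficients to ~0", {
  w <- simulate_wesi_windows(10, 100, separation = 2, seed = 12)
  m <- wesi_train(w, lambda = 50, seed = 1)
  expect_true(all(abs(m$coefficients[-1]) < 1e-8))
  expect_true(all(wesi_score(m, w) > 0.1 & wesi_score(m, w) < 0.9))
})

test_that("plain-loss route matches the glmnet oracle", {
  skip_if_not_installed("glmnet")
  w <- simulate_wesi_windows(20, 200, separation = 1.5, seed = 13)
  m <- wesi_train(w, seed = 42, loss = "logistic")
  fb <- build_feature_vector(w[m$train_index, ])
  g <- glmnet::glmnet(fb$features, w$label[m$train_index],
                      family = "binomial", lambda = 0.1,
                      standardize = FALSE, thresh = 1e-12)
  oracle <- c(as.numeric(g$a0), as.numeric(g$beta))
  expect_equal(unname(m$coefficients), oracle, tolerance = 1e-3)
})

test_that("scoring is monotone, bounded and reproduces training fit", {
  w <- simulate_wesi_windows(10, 100, separation = 2, seed = 14)
  m <- wesi_train(w, seed = 1)
  s <- wesi_score(m, w)
  expect_true(all(s > 0 & s < 1))
  # all-zero coefficients -> every score 0.5
  m0 <- m; m0$coefficients[] <- 0
  expect_equal(unique(wesi_score(m0, w)), 0.5)
  # monotonicity in a positively-weighted predictor
  j <- which.max(m$coefficients[2:5])
  band <- c("delta", "theta", "alpha", "beta")[j]
  lo <- data.frame(delta = .25, theta = .25, alpha = .25, beta = .25)
  hi <- lo
  hi[[band]] <- 0.4
  others <- setdiff(band, names(hi))
  hi[setdiff(c("delta", "theta", "alpha", "beta"), band)] <- 0.2
  expect_gt(wesi_score(m, hi), wesi_score(m, lo))
})

test_that("AUC equals the brute-force pairwise oracle; degenerate cases error", {
  set.seed(62)
  sc <- runif(60); lb <- rbinom(60, 1, 0.4)
  pos <- sc[lb == 1]; neg <- sc[lb == 0]
  oracle <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(auc_score(sc, lb), oracle)
  expect_equal(auc_score(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_error(auc_score(sc, rep(1, 60)), "one-class")
})

test_that("no leakage: refitting on the training rows alone is identical", {
  w <- simulate_wesi_windows(20, 200, separation = 1.5, seed = 15)
  m <- wesi_train(w, split = 0.8, seed = 7)
  m_ref <- wesi_train(w[m$train_index, ], split = 1, seed = 99)
  expect_equal(m$coefficients, m_ref$coefficients, tolerance = 1e-8)
  expect_equal(m$standardization, m_ref$standardization)
  # determinism: same seed, same split and fit
  m2 <- wesi_train(w, split = 0.8, seed = 7)
  expect_identical(m$coefficients, m2$coefficients)
  expect_identical(m$train_index, m2$train_index)
  # subject-wise split keeps whole subjects together
  ids_tr <- unique(w$subject_id[m$train_index])
  ids_te <- unique(w$subject_id[m$test_index])
  expect_length(intersect(ids_tr, ids_te), 0)
})

test_that("stage means aggregate scores per stage with logit bookkeeping", {
  sc <- c(0.5, 0.5, 0.9, 0.7, 0.1)
  st <- c("W", "W", "N1", "N1", "N2")
  sm <- wesi_stage_means(sc, st)
  expect_equal(nrow(sm), 5)
  expect_equal(sm$mean_score[sm$stage == "W"], 0.5)
  expect_equal(sm$mean_score[sm$stage == "N1"], 0.8)
  expect_equal(sm$logit_mean[sm$stage == "N1"], qlogis(0.8))
  expect_true(is.na(sm$mean_score[sm$stage == "R"]))
  # bounded by min/max window scores
  expect_true(all(sm$mean_score >= 0.1 & sm$mean_score <= 0.9, na.rm = TRUE))
})

test_that("finite-difference back-transform matches the bootstrap < 0.001", {
  set.seed(63)
  x <- rnorm(300, qlogis(0.65), 0.3)
  v <- validate_linear_scale(x, B = 10000, seed = 1)
  expect_lt(v$abs_difference, 0.001)
  ls <- linear_scale_summary(x)
  expect_true(all(ls$ci > 0 & ls$ci < 1))
  expect_true(ls$ci[1] < ls$mean && ls$mean < ls$ci[2])
  # zero-variance at logit 0 -> mean exactly 0.5, zero-width CI
  z <- linear_scale_summary(rep(0, 10))
  expect_equal(z$mean, 0.5)
  expect_equal(z$ci, c(0.5, 0.5))
})

test_that("model JSON serialization round-trips", {
  w <- simulate_wesi_windows(8, 60, seed = 16)
  m <- wesi_train(w, seed = 2)
  p <- withr::local_tempfile(fileext = ".json")
  write_wesi_model(m, p)
  m2 <- read_wesi_model(p)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(wesi_score(m2, w), wesi_score(m, w))
})
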