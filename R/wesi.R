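# Wake EEG Similarity Index: 3-s-window spectral feature construction,
# L1-regularized robust logistic training, scoring, per-stage summaries and
# the finite-difference linear-scale back-transform.

wesi_band_names <- function() c("delta", "theta", "alpha", "beta")

#' Relative band powers in non-overlapping 3-s windows
#'
#' Windows are aligned to the 3-s artifact-mask grid; C3 and C4 band powers
#' are summed before the relative transform; windows overlapping flagged
#' artifact segments are excluded.
#'
#' @param rec preprocessed [eeg_recording()]
#' @param mask an `artifact_mask`, or `NULL` to compute one
#' @param nw,k multitaper parameters for the single 3-s window
#' @return data.frame: `window_start_s`, `epoch`, `delta`, `theta`, `alpha`,
#'   `beta` (relative powers, each row sums to 1); invalid windows dropped
#' @export
window_band_powers_3s <- function(rec, mask = NULL, nw = 2, k = 3) {
  if (!rec$preprocessed) {
    stop("recording must come from preprocess_recording()")
  }
  if (is.null(mask)) mask <- rms_artifact_mask(rec)
  series <- multitaper_band_powers(rec, mask = NULL, window_s = 3, hop_s = 3,
                                   nw = nw, k = k)
  nseg <- min(length(series$times), ncol(mask$flagged))
  flagged <- apply(mask$flagged, 2, any)[seq_len(nseg)]
  keep <- which(!flagged)
  if (!length(keep)) {
    return(data.frame(window_start_s = numeric(), epoch = integer(),
                      delta = numeric(), theta = numeric(),
                      alpha = numeric(), beta = numeric()))
  }
  total <- Reduce(`+`, series$power)[, keep, drop = FALSE]
  rel <- t(total) / colSums(total)
  colnames(rel) <- wesi_band_names()
  data.frame(window_start_s = series$times[keep],
             epoch = floor(series$times[keep] / 30) + 1L,
             rel)
}

#' Build the 14 WESI predictors from relative band powers
#'
#' Steps: clip relative powers to `[1e-6, 1 - 1e-6]`, logit-transform,
#' z-score (constants estimated from the training data when
#' `standardization` is `NULL`), then form the 4 linear terms, 6 pairwise
#' products and 4 squares of the z-scored logits, in canonical order.
#'
#' @param relatives matrix/data.frame with columns delta, theta, alpha,
#'   beta (rows sum to 1)
#' @param standardization list with `center` and `scale` (length-4 named
#'   vectors), or `NULL` to estimate from `relatives`
#' @return list: `features` (n x 14 matrix), `standardization`
#' @export
build_feature_vector <- function(relatives, standardization = NULL) {
  bn <- wesi_band_names()
  x <- as.matrix(as.data.frame(relatives)[, bn])
  x <- pmin(pmax(x, 1e-6), 1 - 1e-6)
  lg <- log(x / (1 - x))
  if (is.null(standardization)) {
    standardization <- list(center = colMeans(lg),
                            scale = apply(lg, 2, stats::sd))
  }
  z <- sweep(sweep(lg, 2, standardization$center), 2,
             standardization$scale, "/")
  pairs <- utils::combn(4, 2)
  prods <- sapply(seq_len(ncol(pairs)), function(j)
    z[, pairs[1, j]] * z[, pairs[2, j]])
  if (is.null(dim(prods))) prods <- matrix(prods, nrow = 1)
  sq <- z^2
  feats <- cbind(z, prods, sq)
  colnames(feats) <- c(bn,
                       apply(pairs, 2, function(p)
                         paste(bn[p[1]], bn[p[2]], sep = "_x_")),
                       paste0(bn, "_sq"))
  list(features = feats, standardization = standardization)
}

# Stable log(1 + exp(-z)).
log1pexp_neg <- function(z) ifelse(z < -33, -z, log1p(exp(-pmax(z, -33))))

# Objective pieces for the (optionally Huberized) L1 logistic model.
wesi_loss_grad <- function(beta, X, s, delta, loss) {
  z <- s * drop(X %*% beta)
  l <- log1pexp_neg(z)
  if (loss == "huber") {
    hl <- ifelse(l <= delta, l^2 / 2, delta * (l - delta / 2))
    hp <- pmin(l, delta)
  } else {
    hl <- l
    hp <- 1
  }
  gz <- -stats::plogis(-z)                  # d l / d z
  list(value = mean(hl),
       grad = drop(crossprod(X, hp * gz * s)) / nrow(X))
}

soft_threshold <- function(b, t) sign(b) * pmax(abs(b) - t, 0)

# FISTA proximal-gradient minimization of smooth loss + lambda * ||beta[-1]||_1.
fista_l1 <- function(X, s, lambda, delta, loss, max_iter = 3000,
                     tol = 1e-9) {
  p <- ncol(X)
  beta <- numeric(p)
  yv <- beta
  t_k <- 1
  L <- 1
  pen <- function(b) lambda * sum(abs(b[-1]))
  f <- wesi_loss_grad(beta, X, s, delta, loss)
  obj_old <- f$value + pen(beta)
  for (it in seq_len(max_iter)) {
    fy <- wesi_loss_grad(yv, X, s, delta, loss)
    repeat {
      cand <- yv - fy$grad / L
      cand[-1] <- soft_threshold(cand[-1], lambda / L)
      fc <- wesi_loss_grad(cand, X, s, delta, loss)
      dd <- cand - yv
      if (fc$value <= fy$value + sum(fy$grad * dd) + L / 2 * sum(dd^2) +
          1e-12) break
      L <- L * 2
    }
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    yv <- cand + (t_k - 1) / t_new * (cand - beta)
    beta <- cand
    t_k <- t_new
    obj <- fc$value + pen(beta)
    if (abs(obj_old - obj) < tol * max(1, abs(obj_old))) break
    obj_old <- obj
    L <- max(L / 1.5, 1e-4)
  }
  list(beta = beta, iterations = it, objective = obj_old)
}

#' Train the WESI model
#'
#' Windows labelled wake (1) / sleep (0) are split 80/20 (by subject by
#' default, avoiding leakage across a subject's windows), standardization
#' constants and the 14 predictors are built from the training split only,
#' and the 15 parameters (intercept unpenalized) are fit by minimizing the
#' mean Huberized logistic loss plus `lambda * sum(|coef|)` with proximal
#' gradient descent. The Huberized loss applies the Huber function
#' (quadratic below `delta`, linear beyond) to each window's logistic
#' deviance contribution, down-weighting gross label/spectrum mismatches;
#' `loss = "logistic"` switches to the plain log-loss.
#'
#' @param windows data.frame with columns `label` (0/1), `delta`, `theta`,
#'   `alpha`, `beta`, and `subject_id` when splitting by subject
#' @param split training fraction (default 0.8; `1` trains on everything)
#' @param lambda L1 strength (default 0.1)
#' @param delta Huber scale (default 3)
#' @param seed integer seed for the split
#' @param split_by `"subject"` (default) or `"window"`
#' @param loss `"huber"` (default) or `"logistic"`
#' @return object of class `wesi_model`: coefficients (intercept + 14),
#'   standardization constants, hyperparameters, split bookkeeping
#' @export
wesi_train <- function(windows, split = 0.8, lambda = 0.1, delta = 3,
                       seed = 1L, split_by = c("subject", "window"),
                       loss = c("huber", "logistic")) {
  split_by <- match.arg(split_by)
  loss <- match.arg(loss)
  stopifnot(all(windows$label %in% 0:1), split > 0, split <= 1)
  set.seed(seed)
  n <- nrow(windows)
  if (split_by == "subject") {
    if (is.null(windows$subject_id)) stop("subject_id needed for subject split")
    ids <- sort(unique(windows$subject_id))
    n_tr <- max(1L, round(split * length(ids)))
    train_ids <- sort(sample(ids, n_tr))
    tr <- windows$subject_id %in% train_ids
  } else {
    tr <- logical(n)
    tr[sample.int(n, max(1L, round(split * n)))] <- TRUE
  }
  if (length(unique(windows$label[tr])) < 2) {
    stop("training split must contain both classes")
  }
  fb <- build_feature_vector(windows[tr, ], standardization = NULL)
  X <- cbind(intercept = 1, fb$features)
  s <- ifelse(windows$label[tr] == 1, 1, -1)
  fit <- fista_l1(X, s, lambda, delta, loss)
  coefs <- stats::setNames(fit$beta, colnames(X))
  structure(list(coefficients = coefs,
                 standardization = fb$standardization,
                 lambda = lambda, delta = delta, loss = loss,
                 split = split, split_by = split_by, seed = seed,
                 train_index = which(tr), test_index = which(!tr),
                 iterations = fit$iterations, objective = fit$objective),
            class = "wesi_model")
}

#' @export
print.wesi_model <- function(x, ...) {
  cat(sprintf(
    "wesi_model: %d parameters | lambda %.3g, delta %.3g, %s loss | %d/%d train/test windows\n",
    length(x$coefficients), x$lambda, x$delta, x$loss,
    length(x$train_index), length(x$test_index)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Score windows with a fitted WESI model
#'
#' @param model a `wesi_model`
#' @param windows data.frame with relative band-power columns
#' @return numeric scores in (0, 1), one per window
#' @export
wesi_score <- function(model, windows) {
  if (!inherits(model, "wesi_model")) stop("model must be a wesi_model")
  fb <- build_feature_vector(windows, model$standardization)
  eta <- drop(cbind(1, fb$features) %*% model$coefficients)
  stats::plogis(eta)
}

#' Rank-based (Mann-Whitney) AUC
#' @param scores numeric scores
#' @param labels 0/1 labels (both classes present)
#' @return AUC in `[0, 1]`
#' @export
auc_score <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one-class data")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a WESI model on labelled windows
#'
#' @param model a `wesi_model`
#' @param windows labelled windows (both classes present); defaults could be
#'   the held-out test rows of the training frame
#' @param by optional factor (e.g. dataset) for a per-level breakdown
#' @return list with `accuracy` (0.5 threshold) and `auc`; with `by`, an
#'   additional `by_group` data.frame
#' @export
wesi_evaluate <- function(model, windows, by = NULL) {
  sc <- wesi_score(model, windows)
  if (length(unique(windows$label)) < 2) {
    stop("AUC undefined: one-class test set")
  }
  out <- list(accuracy = mean((sc > 0.5) == (windows$label == 1)),
              auc = auc_score(sc, windows$label))
  if (!is.null(by)) {
    out$by_group <- do.call(rbind, lapply(split(seq_along(sc), by),
                                          function(i) {
      data.frame(
        n = length(i),
        accuracy = mean((sc[i] > 0.5) == (windows$label[i] == 1)),
        auc = if (length(unique(windows$label[i])) < 2) NA_real_
        else auc_score(sc[i], windows$label[i]))
    }))
  }
  out
}

#' Mean WESI score per sleep stage
#'
#' @param scores per-window scores
#' @param stages per-window stage labels (`W, N1, N2, N3, R`)
#' @return data.frame: `stage`, `mean_score`, `logit_mean`, `n_windows`
#'   (absent stages are `NA`)
#' @export
wesi_stage_means <- function(scores, stages) {
  out <- data.frame(stage = sleep_stages(), mean_score = NA_real_,
                    logit_mean = NA_real_, n_windows = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(5)) {
    sel <- stages == out$stage[i]
    out$n_windows[i] <- sum(sel)
    if (any(sel)) {
      m <- mean(scores[sel])
      out$mean_score[i] <- m
      out$logit_mean[i] <- stats::qlogis(min(max(m, 1e-12), 1 - 1e-12))
    }
  }
  out
}

# Second-order back-transform of a normal logit-scale summary to the score
# scale, with the curvature term computed by central finite differences.
fd_backtransform <- function(mu, sigma2, h = 1e-3) {
  f2 <- (stats::plogis(mu + h) - 2 * stats::plogis(mu) +
           stats::plogis(mu - h)) / h^2
  stats::plogis(mu) + sigma2 / 2 * f2
}

#' Linear-scale mean and CI from logit-scale stage scores
#'
#' Given per-subject logit-scale WESI stage scores for one group-stage cell
#' (an intercept-only logit-scale model), approximates the mean score on
#' the (0, 1) scale with a finite-difference (delta-method) correction for
#' the logistic curvature, and maps the CI endpoints the same way.
#'
#' @param x numeric vector of logit-scale values (one per subject)
#' @param conf confidence level
#' @return list: `mean`, `ci` (length 2, inside (0, 1)), `logit_mean`,
#'   `logit_var`, `n`
#' @export
linear_scale_summary <- function(x, conf = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2 || stats::var(x) == 0) {
    if (n == 0) stop("no finite values")
    if (n >= 2 && stats::var(x) == 0) {
      m <- stats::plogis(x[1])
      return(list(mean = m, ci = c(m, m), logit_mean = x[1], logit_var = 0,
                  n = n))
    }
    warning("degenerate variance; falling back to plain back-transform")
    return(list(mean = stats::plogis(mean(x)),
                ci = c(NA_real_, NA_real_),
                logit_mean = mean(x), logit_var = NA_real_, n = n))
  }
  mu <- mean(x); s2 <- stats::var(x)
  se <- sqrt(s2 / n)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  m <- fd_backtransform(mu, s2)
  ci <- c(fd_backtransform(mu - zq * se, s2),
          fd_backtransform(mu + zq * se, s2))
  list(mean = min(max(m, 0), 1), ci = pmin(pmax(ci, 0), 1),
       logit_mean = mu, logit_var = s2, n = n)
}

#' Bootstrap validation of the finite-difference back-transform
#'
#' Nonparametric bootstrap of the linear-scale group mean: resamples
#' subjects with replacement `B` times, averaging the per-subject
#' back-transformed scores, and reports the absolute difference from the
#' finite-difference approximation.
#'
#' @param x logit-scale per-subject values for one cell
#' @param B number of bootstrap resamples (default 10000)
#' @param seed integer seed (optional)
#' @return list: `fd_mean`, `bootstrap_mean`, `abs_difference`
#' @export
validate_linear_scale <- function(x, B = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fd <- linear_scale_summary(x)$mean
  y <- stats::plogis(x)
  n <- length(y)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  boots <- colMeans(matrix(y[idx], n, B))
  list(fd_mean = fd, bootstrap_mean = mean(boots),
       abs_difference = abs(fd - mean(boots)))
}

#' Serialize a WESI model to JSON
#' @param model a `wesi_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_wesi_model <- function(model, path) {
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients),
         standardization = lapply(model$standardization, as.list),
         lambda = model$lambda, delta = model$delta, loss = model$loss,
         split = model$split, split_by = model$split_by, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a WESI model from JSON
#' @param path JSON path written by [write_wesi_model()]
#' @return a `wesi_model`
#' @export
read_wesi_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(j$coefficients),
                 standardization = lapply(j$standardization, unlist),
                 lambda = j$lambda, delta = j$delta, loss = j$loss,
                 split = j$split, split_by = j$split_by, seed = j$seed,
                 train_index = integer(), test_index = integer()),
            class = "wesi_model")
}
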