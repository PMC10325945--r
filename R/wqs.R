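# Reverse-oriented weighted quantile sum regression with random subsets
# and repeated holdouts (WQS_RSRH). The decile-scored taxa form a
# weighted index used as the predictor of log2 Pb; weights live on the
# simplex and the index coefficient is sign-constrained during
# training. Each holdout: a random 60/40 train/validation split,
# weights averaged over bootstrap resamples each fitted on a random
# taxon subset, then the index effect re-estimated by unconstrained
# least squares on the validation half. The distribution of validation
# estimates across holdouts is the inferential object.

#' WQS_RSRH configuration
#'
#' @param direction assumed sign of the mixture effect during training.
#' @param n_holdouts repeated holdout splits (200 in the full analysis).
#' @param n_bootstrap with-replacement resamples per holdout (100 in
#'   the full analysis).
#' @param validation_fraction fraction of subjects set aside for
#'   validation (0.4).
#' @param subset_size taxa per random subset, or `"auto"` for
#'   `ceiling(sqrt(c))` with `c` mixture components.
#' @param importance_holdout_fraction fraction of holdouts in which a
#'   taxon's weight must exceed the chance threshold to be called
#'   important (0.8).
#' @param n_starts,maxit,reltol optimiser settings for the constrained
#'   fit (multi-start softmax search).
#' @param seed integer seed.
#' @return a `wqs_config` list.
#' @export
wqs_config <- function(direction = c("negative", "positive"),
                       n_holdouts = 200L, n_bootstrap = 100L,
                       validation_fraction = 0.4, subset_size = "auto",
                       importance_holdout_fraction = 0.8,
                       n_starts = 5L, maxit = 500L, reltol = 1e-8,
                       seed = 1L) {
  direction <- match.arg(direction)
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stopf("validation_fraction must be in (0, 1)")
  if (n_bootstrap < 1L) stopf("n_bootstrap must be >= 1")
  structure(list(
    direction = direction, n_holdouts = as.integer(n_holdouts),
    n_bootstrap = as.integer(n_bootstrap),
    validation_fraction = validation_fraction, subset_size = subset_size,
    importance_holdout_fraction = importance_holdout_fraction,
    n_starts = as.integer(n_starts), maxit = as.integer(maxit),
    reltol = reltol, seed = as.integer(seed)
  ), class = "wqs_config")
}

#' Chance-level importance threshold
#'
#' `1/c` for an index of `c` mixture components: a weight above it
#' exceeds the equal-weight chance level.
#'
#' @param c number of components in the index (>= 1).
#' @return `1/c`.
#' @export
importance_threshold <- function(c) {
  if (!is_count(c)) stopf("c must be a positive integer")
  1 / c
}

#' Weighted quantile sum index
#'
#' Per-sample weighted sum of decile scores, `sum_j w_j q_ij`.
#'
#' @param weights non-negative weights summing to 1 (tolerance 1e-6).
#' @param Q decile-scored sample x taxon matrix.
#' @return numeric index per sample.
#' @export
wqs_index <- function(weights, Q) {
  if (length(weights) != ncol(Q))
    stopf("weights length (%d) must equal taxa count (%d)",
          length(weights), ncol(Q))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
    stopf("weights must be non-negative and sum to 1 (sum = %.6f)",
          sum(weights))
  drop(Q %*% weights)
}

#' Sign-constrained simplex-weight WQS fit
#'
#' Maximises the Gaussian log-likelihood of
#' `y = b0 + b1 (sum_{j in subset} w_j q_j) + Z gamma + e` subject to
#' `w >= 0`, `sum w = 1` over the subset, and `sign(b1)` matching
#' `direction` (`b1 = 0` allowed at the boundary). The weights are
#' reparameterised by softmax and searched by multi-start BFGS with an
#' analytic gradient; for fixed weights `(b0, b1, gamma)` are profiled
#' out by least squares, with `b1` clipped to the feasible sign.
#' Off-subset weights are exactly zero.
#'
#' @param Q decile matrix (full width); columns outside `subset` get
#'   weight 0.
#' @param y outcome (log2 exposure).
#' @param Z covariate design matrix or `NULL`.
#' @param direction `"negative"` or `"positive"`.
#' @param subset integer indices of the active taxa.
#' @param n_starts,maxit,reltol optimiser controls.
#' @return list: `weights` (full length), `beta` (constrained index
#'   coefficient), `loglik`, `converged`.
#' @export
fit_constrained_wqs <- function(Q, y, Z = NULL,
                                direction = c("negative", "positive"),
                                subset = seq_len(ncol(Q)),
                                n_starts = 5L, maxit = 500L,
                                reltol = 1e-8) {
  direction <- match.arg(direction)
  if (length(subset) < 1L) stopf("subset must be non-empty")
  n <- length(y)
  k <- length(subset)
  X0 <- if (is.null(Z)) matrix(1, n, 1L) else cbind(1, Z)
  qr0 <- qr(X0)
  yt <- qr.resid(qr0, y)
  Qt <- qr.resid(qr0, Q[, subset, drop = FALSE])
  A <- crossprod(Qt)
  v <- drop(crossprod(Qt, yt))
  yy <- sum(yt^2)
  sgn <- if (direction == "negative") -1 else 1

  beta_of <- function(w) {
    a <- sum(w * v)
    b <- drop(crossprod(w, A %*% w))
    if (b <= 1e-12) return(c(0, 1e-12))
    bc <- if (sgn < 0) min(a / b, 0) else max(a / b, 0)
    c(bc, b)
  }
  if (k == 1L) {
    w <- 1
    bb <- beta_of(w)
    rss <- max(yy - bb[1]^2 * bb[2], 1e-300)
    weights <- numeric(ncol(Q))
    weights[subset] <- 1
    return(list(weights = weights, beta = bb[1],
                loglik = -n / 2 * (log(2 * pi * rss / n) + 1),
                converged = TRUE))
  }
  # A weak ridge on the softmax parameters removes the shift
  # non-identifiability and keeps line searches off the saturated
  # plateaus (weights pinned at exactly 0/1) where the data gradient
  # vanishes; its scale is far below the RSS differences that matter.
  lambda <- 1e-6 * max(yy, 1e-12) / k
  obj <- function(th) {
    w <- softmax(th)
    a <- sum(w * v)
    b <- drop(crossprod(w, A %*% w))
    if (b <= 1e-12) return(yy + lambda * sum(th^2))
    ac <- if (sgn < 0) min(a, 0) else max(a, 0)
    yy - ac^2 / b + lambda * sum(th^2)
  }
  grad <- function(th) {
    w <- softmax(th)
    a <- sum(w * v)
    b <- drop(crossprod(w, A %*% w))
    pen <- 2 * lambda * th
    if (b <= 1e-12) return(pen)
    active <- if (sgn < 0) a < 0 else a > 0
    if (!active) return(pen)
    gw <- -(2 * a / b) * v + (a / b)^2 * 2 * drop(A %*% w)
    w * (gw - sum(w * gw)) + pen
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1L) numeric(k) else log(stats::rgamma(k, 1) + 1e-9)
    fit <- tryCatch(
      stats::optim(th0, obj, grad, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    weights <- numeric(ncol(Q))
    weights[subset] <- 1 / k
    return(list(weights = weights, beta = 0, loglik = NA_real_,
                converged = FALSE))
  }
  # polish: a solution driven deep into softmax saturation may sit on a
  # flat plateau next to a better near-boundary optimum; restart from a
  # rescaled parameter vector until no further improvement
  for (polish in 1:2) {
    sc <- max(abs(best$par))
    if (sc <= 3) break
    fit <- tryCatch(
      stats::optim(best$par * 3 / sc, obj, grad, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$value < best$value) best <- fit else break
  }
  w <- softmax(best$par)
  bb <- beta_of(w)
  rss <- max(yy - bb[1]^2 * bb[2], 1e-300)
  weights <- numeric(ncol(Q))
  weights[subset] <- w
  list(weights = weights, beta = bb[1],
       loglik = -n / 2 * (log(2 * pi * rss / n) + 1),
       converged = best$convergence == 0L)
}

#' Bootstrap-and-random-subset weight estimation
#'
#' For each of `n_bootstrap` iterations a with-replacement resample of
#' the training rows *and* a uniform random taxon subset are drawn and a
#' sign-constrained fit run on the subset. Weight vectors from converged
#' fits are averaged (unweighted) and renormalised to sum 1.
#'
#' @param Q,y,Z training data (decile matrix, outcome, covariates).
#' @param direction training sign constraint.
#' @param subset_size taxa per subset (`"auto"` = `ceiling(sqrt(c))`).
#' @param n_bootstrap number of resamples.
#' @param identity_resample test hook: use the untouched training rows
#'   instead of resampling (with `n_bootstrap = 1` and
#'   `subset_size = ncol(Q)` this reduces exactly to
#'   [fit_constrained_wqs]).
#' @param n_starts,maxit,reltol optimiser controls.
#' @return list: `weights` (averaged, sum 1), `n_converged`,
#'   `train_betas` (constrained betas of the converged fits).
#' @export
bootstrap_weights <- function(Q, y, Z = NULL,
                              direction = c("negative", "positive"),
                              subset_size = "auto", n_bootstrap = 100L,
                              identity_resample = FALSE, n_starts = 5L,
                              maxit = 500L, reltol = 1e-8) {
  direction <- match.arg(direction)
  cc <- ncol(Q)
  if (identical(subset_size, "auto")) subset_size <- ceiling(sqrt(cc))
  if (subset_size > cc) stopf("subset_size exceeds taxa count")
  acc <- matrix(0, 0, cc)
  betas <- numeric(0)
  for (b in seq_len(n_bootstrap)) {
    rows <- if (identity_resample) seq_len(nrow(Q)) else
      sample.int(nrow(Q), replace = TRUE)
    subset <- if (subset_size == cc) seq_len(cc) else
      sort(sample.int(cc, subset_size))
    fit <- fit_constrained_wqs(Q[rows, , drop = FALSE], y[rows],
                               if (is.null(Z)) NULL else
                                 Z[rows, , drop = FALSE],
                               direction, subset, n_starts, maxit, reltol)
    if (isTRUE(fit$converged)) {
      acc <- rbind(acc, fit$weights)
      betas <- c(betas, fit$beta)
    }
  }
  if (nrow(acc) == 0L) stopf("all bootstrap fits failed to converge")
  w <- colMeans(acc)
  w <- w / sum(w)
  names(w) <- colnames(Q)
  list(weights = w, n_converged = nrow(acc), train_betas = betas)
}

#' One repeated-holdout iteration
#'
#' Random train/validation split (train = `ceiling((1 - f) n)`, e.g.
#' 74/49 for n = 123 at f = 0.4), bootstrap-averaged weights on the
#' training half, then an ordinary (sign-unconstrained) regression of
#' the outcome on the fixed index plus covariates in the validation
#' half — leaving the validation estimate free to fall on either side
#' of zero, which is what makes the holdout sign fraction informative.
#'
#' @param Q,y,Z full data.
#' @param config a [wqs_config].
#' @param holdout_id integer id recorded in the result.
#' @return list of class `wqs_holdout`: `holdout_id`, `train`,
#'   `validation` (index sets), `weights`, `beta_validation`, `se`,
#'   `aic`, `bic`, `log_likelihood`, `converged_bootstraps`, `flagged`.
#' @export
run_holdout <- function(Q, y, Z, config, holdout_id = 1L) {
  n <- nrow(Q)
  n_train <- as.integer(ceiling((1 - config$validation_fraction) * n))
  perm <- sample.int(n)
  train <- sort(perm[seq_len(n_train)])
  valid <- sort(perm[-seq_len(n_train)])
  bw <- bootstrap_weights(Q[train, , drop = FALSE], y[train],
                          if (is.null(Z)) NULL else
                            Z[train, , drop = FALSE],
                          config$direction, config$subset_size,
                          config$n_bootstrap,
                          n_starts = config$n_starts,
                          maxit = config$maxit, reltol = config$reltol)
  idx_v <- wqs_index(bw$weights, Q[valid, , drop = FALSE])
  flagged <- FALSE
  if (stats::sd(idx_v) < 1e-12) {
    flagged <- TRUE
    res <- list(beta = NA_real_, se = NA_real_, aic = NA_real_,
                bic = NA_real_, ll = NA_real_)
  } else {
    df <- data.frame(y = y[valid], wqs = idx_v)
    if (!is.null(Z)) df <- cbind(df, Z[valid, , drop = FALSE])
    fit <- stats::lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    res <- list(beta = sm["wqs", 1], se = sm["wqs", 2],
                aic = stats::AIC(fit), bic = stats::BIC(fit),
                ll = as.numeric(stats::logLik(fit)))
  }
  structure(list(
    holdout_id = holdout_id, train = train, validation = valid,
    weights = bw$weights, beta_validation = res$beta, se = res$se,
    aic = res$aic, bic = res$bic, log_likelihood = res$ll,
    converged_bootstraps = bw$n_converged,
    train_betas = bw$train_betas, flagged = flagged
  ), class = "wqs_holdout")
}

#' Run the full WQS_RSRH analysis
#'
#' `n_holdouts` independent holdout iterations, aggregated into: the
#' mean validation beta, its 2.5-97.5 percentile interval, the fraction
#' of holdout betas below zero, mean weights, per-taxon importance
#' fractions (share of holdouts with weight above `1/c`), the
#' important-taxa set (importance fraction at or above
#' `importance_holdout_fraction`), and mean AIC/BIC.
#'
#' @param Q decile matrix, `y` log2 exposure, `Z` covariate design (or
#'   `NULL`).
#' @param config a [wqs_config].
#' @return object of class `wqs_summary`.
#' @export
run_wqs_rsrh <- function(Q, y, Z, config = wqs_config()) {
  seeds <- spawn_seeds(config$seed, config$n_holdouts)
  fits <- vector("list", config$n_holdouts)
  for (h in seq_len(config$n_holdouts)) {
    set.seed(seeds[h])
    fits[[h]] <- run_holdout(Q, y, Z, config, holdout_id = h)
  }
  flagged <- vapply(fits, function(f) isTRUE(f$flagged), TRUE)
  if (mean(flagged) > 0.5)
    stopf("%d of %d holdouts flagged (degenerate index); check inputs",
          sum(flagged), length(fits))
  ok <- fits[!flagged]
  betas <- vapply(ok, `[[`, 0, "beta_validation")
  W <- t(vapply(ok, `[[`, numeric(ncol(Q)), "weights"))
  colnames(W) <- colnames(Q)
  thr <- importance_threshold(ncol(Q))
  imp_frac <- colMeans(W > thr)
  mean_w <- colMeans(W)
  mean_w <- mean_w / sum(mean_w)
  important <- names(imp_frac)[imp_frac >= config$importance_holdout_fraction]
  structure(list(
    mean_beta = mean(betas),
    ci_lower = unname(stats::quantile(betas, 0.025)),
    ci_upper = unname(stats::quantile(betas, 0.975)),
    fraction_below_zero = mean(betas < 0),
    mean_weights = mean_w,
    importance_threshold = thr,
    per_taxon_importance_fraction = imp_frac,
    important_taxa = important,
    direction = config$direction,
    mean_aic = mean(vapply(ok, `[[`, 0, "aic")),
    mean_bic = mean(vapply(ok, `[[`, 0, "bic")),
    mean_loglik = mean(vapply(ok, `[[`, 0, "log_likelihood")),
    holdout_betas = betas,
    n_holdouts = length(ok), n_flagged = sum(flagged),
    config = config
  ), class = "wqs_summary")
}

#' @export
print.wqs_summary <- function(x, ...) {
  cat(sprintf(
    "WQS_RSRH (%s direction): beta = %.3f, 95%% HI [%.3f, %.3f]\n",
    x$direction, x$mean_beta, x$ci_lower, x$ci_upper))
  cat(sprintf("%.0f%% of %d holdout estimates below zero\n",
              100 * x$fraction_below_zero, x$n_holdouts))
  cat(sprintf("importance threshold 1/%d = %.3f; %d taxa important\n",
              length(x$mean_weights), x$importance_threshold,
              length(x$important_taxa)))
  invisible(x)
}

#' Choose between the negative- and positive-direction models
#'
#' The direction with the smaller mean validation AIC wins; ties break
#' by mean BIC, then by higher mean log-likelihood; an exact three-way
#' tie returns the negative model flagged inconclusive. Fit both
#' summaries on identical data with the same `seed` so the holdout
#' splits are paired.
#'
#' @param summary_neg,summary_pos `wqs_summary` objects from the two
#'   directions.
#' @return list: `direction`, `inconclusive`, `report` (both models'
#'   mean AIC/BIC/log-likelihood).
#' @export
select_direction <- function(summary_neg, summary_pos) {
  rep <- data.frame(
    direction = c("negative", "positive"),
    mean_aic = c(summary_neg$mean_aic, summary_pos$mean_aic),
    mean_bic = c(summary_neg$mean_bic, summary_pos$mean_bic),
    mean_loglik = c(summary_neg$mean_loglik, summary_pos$mean_loglik)
  )
  inconclusive <- FALSE
  if (summary_neg$mean_aic != summary_pos$mean_aic) {
    dir <- rep$direction[which.min(rep$mean_aic)]
  } else if (summary_neg$mean_bic != summary_pos$mean_bic) {
    dir <- rep$direction[which.min(rep$mean_bic)]
  } else if (summary_neg$mean_loglik != summary_pos$mean_loglik) {
    dir <- rep$direction[which.max(rep$mean_loglik)]
  } else {
    dir <- "negative"
    inconclusive <- TRUE
  }
  list(direction = dir, inconclusive = inconclusive, report = rep)
}
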