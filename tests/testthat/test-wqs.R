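# The WQS_RSRH machinery: index arithmetic, constrained fits against a
# grid-search oracle, bootstrap averaging, holdout structure, direction
# selection, and recovery behaviour.

test_that("importance threshold is one over the component count", {
  expect_equal(importance_threshold(20), 0.05)
  expect_equal(round(importance_threshold(37), 3), 0.027)
  expect_equal(importance_threshold(1), 1)
  expect_error(importance_threshold(0), "positive integer")
})

test_that("the WQS index is the weighted decile sum", {
  Q <- cbind(a = c(10L, 0L, 5L), b = c(0L, 10L, 5L))
  expect_equal(wqs_index(c(1, 0), Q), c(10, 0, 5))
  expect_equal(wqs_index(c(0.5, 0.5), Q), c(5, 5, 5))
  expect_error(wqs_index(c(0.5, 0.4), Q), "sum to 1")
  expect_error(wqs_index(c(1), Q), "length")
})

test_that("a single dominant taxon captures nearly all the weight", {
  set.seed(91)
  n <- 80
  Q <- matrix(sample(0:10, n * 4, replace = TRUE), n, 4)
  y <- 5 - 0.6 * Q[, 2] + rnorm(n, 0, 0.01)
  fit <- fit_constrained_wqs(Q, y, NULL, "negative")
  expect_gte(fit$weights[2], 0.95)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_lt(fit$beta, -0.5)
  expect_true(fit$converged)
})

test_that("pure-noise fits stay feasible with a small coefficient", {
  set.seed(92)
  Q <- matrix(sample(0:10, 60 * 5, replace = TRUE), 60, 5)
  y <- rnorm(60)
  fit <- fit_constrained_wqs(Q, y, NULL, "negative")
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_lte(fit$beta, 0)
  expect_lt(abs(fit$beta), 0.5)
})

test_that("two-taxon constrained fits match the dense grid-search oracle", {
  set.seed(93)
  for (rep in 1:5) {
    n <- 60
    Q <- matrix(sample(0:10, n * 2, replace = TRUE), n, 2)
    w1 <- runif(1)
    y <- 3 - 0.5 * (w1 * Q[, 1] + (1 - w1) * Q[, 2]) + rnorm(n, 0, 0.3)
    fit <- fit_constrained_wqs(Q, y, NULL, "negative")
    oracle <- grid_oracle_2taxon(Q, y, NULL, "negative")
    rss_fit <- rss_of_weights(fit$weights, Q, y, NULL, "negative")
    expect_lte(rss_fit, oracle$rss * (1 + 1e-3))
    expect_lt(abs(fit$weights[1] - oracle$w1), 0.011)
  }
})

test_that("off-subset weights are exactly zero", {
  set.seed(94)
  Q <- matrix(sample(0:10, 50 * 6, replace = TRUE), 50, 6)
  y <- rnorm(50)
  fit <- fit_constrained_wqs(Q, y, NULL, "negative", subset = c(2, 5))
  expect_identical(unname(fit$weights[c(1, 3, 4, 6)]), rep(0, 4))
  expect_equal(sum(fit$weights[c(2, 5)]), 1, tolerance = 1e-9)
})

test_that("bootstrap averaging with the identity hook reduces to a single fit", {
  set.seed(95)
  Q <- matrix(sample(0:10, 40 * 4, replace = TRUE), 40, 4)
  y <- 2 - 0.4 * Q[, 1] + rnorm(40, 0, 0.2)
  set.seed(1)
  bw <- bootstrap_weights(Q, y, NULL, "negative", subset_size = 4,
                          n_bootstrap = 1, identity_resample = TRUE)
  set.seed(1)
  single <- fit_constrained_wqs(Q, y, NULL, "negative")
  expect_equal(unname(bw$weights), unname(single$weights),
               tolerance = 1e-12)
  expect_equal(sum(bw$weights), 1, tolerance = 1e-9)
})

test_that("training betas respect the configured sign constraint", {
  sc <- make_test_cohort(n = 60, k = 10, seed = 96)
  set.seed(2)
  bw <- bootstrap_weights(sc$Q, sc$y2, sc$Z, "negative",
                          subset_size = "auto", n_bootstrap = 30)
  expect_true(all(bw$train_betas <= 0))
  expect_equal(sum(bw$weights), 1, tolerance = 1e-9)
  set.seed(2)
  bp <- bootstrap_weights(sc$Q, sc$y2, sc$Z, "positive",
                          subset_size = "auto", n_bootstrap = 10)
  expect_true(all(bp$train_betas >= 0))
})

test_that("holdout split sizes follow the 60/40 rule", {
  sc <- make_test_cohort(n = 60, k = 8, seed = 97)
  cfg <- wqs_config(n_holdouts = 1, n_bootstrap = 3, seed = 5)
  # the cohort split rule: n = 123 gives train 74 / validation 49
  expect_identical(ceiling(0.6 * 123), 74)
  set.seed(5)
  h <- run_holdout(sc$Q, sc$y2, sc$Z, cfg)
  expect_identical(length(h$train), 36L) # ceiling(0.6 * 60)
  expect_identical(length(h$validation), 24L)
  expect_length(intersect(h$train, h$validation), 0)
  set.seed(5)
  h2 <- run_holdout(sc$Q, sc$y2, sc$Z, cfg)
  expect_identical(h$train, h2$train)
  expect_equal(h$beta_validation, h2$beta_validation)
})

test_that("a strong negative signal drives the holdout summary negative", {
  sc <- make_test_cohort(n = 100, k = 10, beta_true = -0.5,
                         noise_sd = 0.15, seed = 98)
  cfg <- wqs_config(n_holdouts = 20, n_bootstrap = 10, seed = 3)
  s <- run_wqs_rsrh(sc$Q, sc$y2, sc$Z, cfg)
  expect_lt(s$mean_beta, 0)
  expect_gte(s$fraction_below_zero, 0.95)
  expect_equal(sum(s$mean_weights), 1, tolerance = 1e-6)
  expect_true(all(s$per_taxon_importance_fraction >= 0 &
                    s$per_taxon_importance_fraction <= 1))
  expect_identical(s$n_holdouts, 20L)
})

test_that("the WQS summary is reproducible under a fixed seed", {
  sc <- make_test_cohort(n = 50, k = 8, seed = 99)
  cfg <- wqs_config(n_holdouts = 5, n_bootstrap = 5, seed = 21)
  a <- run_wqs_rsrh(sc$Q, sc$y2, sc$Z, cfg)
  b <- run_wqs_rsrh(sc$Q, sc$y2, sc$Z, cfg)
  expect_identical(a$holdout_betas, b$holdout_betas)
  expect_identical(a$mean_weights, b$mean_weights)
})

test_that("direction selection follows AIC, is symmetric, and breaks ties to negative", {
  sc_neg <- make_test_cohort(n = 80, k = 8, beta_true = -0.5,
                             noise_sd = 0.2, seed = 101)
  cfg <- wqs_config(n_holdouts = 10, n_bootstrap = 8, seed = 7)
  cfg_pos <- cfg; cfg_pos$direction <- "positive"
  s_neg <- run_wqs_rsrh(sc_neg$Q, sc_neg$y2, sc_neg$Z, cfg)
  s_pos <- run_wqs_rsrh(sc_neg$Q, sc_neg$y2, sc_neg$Z, cfg_pos)
  sel <- select_direction(s_neg, s_pos)
  expect_identical(sel$direction, "negative")
  # mirrored outcome: flipping y about its mean favours the positive model
  y_flip <- 2 * mean(sc_neg$y2) - sc_neg$y2
  s_neg2 <- run_wqs_rsrh(sc_neg$Q, y_flip, sc_neg$Z, cfg)
  s_pos2 <- run_wqs_rsrh(sc_neg$Q, y_flip, sc_neg$Z, cfg_pos)
  expect_identical(select_direction(s_neg2, s_pos2)$direction, "positive")
  # exact tie: identical summaries
  tie <- select_direction(s_neg, s_neg)
  expect_identical(tie$direction, "negative")
  expect_true(tie$inconclusive)
})
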