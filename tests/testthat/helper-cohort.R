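# Shared fixture builders. Everything is generated in code at test time.

# Small-to-default synthetic cohort, preprocessed and ready for the
# mixture / association stages.
make_test_cohort <- function(n = 60L, k = 12L, beta_true = -0.5,
                             noise_sd = 0.25, seed = 1L,
                             important = seq_len(min(3L, k)),
                             missing_rate = 0) {
  b1 <- floor(n / 2)
  cfg <- simulation_config(
    n_subjects = n, n_taxa = k, batch_sizes = c(b1, n - b1),
    important_taxa = important, beta_true = beta_true,
    noise_sd = noise_sd, missing_rate = missing_rate, seed = seed
  )
  sim <- simulate_cohort(cfg)
  cohort <- if (missing_rate > 0)
    impute_covariates(sim$cohort, seed = seed)$cohort else sim$cohort
  filt <- prevalence_filter(sim$profile, 0.05)
  list(sim = sim, cfg = cfg, cohort = cohort,
       Q = decile_score(filt$profile),
       Z = covariate_design(cohort),
       y2 = log2(cohort$pb_2t_ugL), y3 = log2(cohort$pb_3t_ugL))
}

# All permutations of 1..n (n small), one per row.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Independent brute-force pseudo-F for a binary grouping, computed from
# raw pairwise distances (no Gower centring): the classical one-way
# decomposition SS_total = (1/n) sum d^2, SS_within = sum_g (1/n_g)
# within-group sum of d^2.
oracle_f_binary <- function(D, groups) {
  n <- nrow(D)
  d2 <- D^2
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_b <- ss_tot - ss_w
  a <- length(unique(groups))
  (ss_b / (a - 1)) / (ss_w / (n - a))
}

# Dense grid-search oracle for the 2-taxon constrained WQS fit:
# profile OLS over w1 in {0, 0.01, ..., 1} with the index coefficient
# clamped to the requested sign.
grid_oracle_2taxon <- function(Q, y, Z = NULL, direction = "negative") {
  grid <- seq(0, 1, by = 0.01)
  X0 <- if (is.null(Z)) matrix(1, length(y), 1) else cbind(1, Z)
  rss <- vapply(grid, function(w1) {
    idx <- Q[, 1] * w1 + Q[, 2] * (1 - w1)
    fit <- lm.fit(cbind(X0, idx), y)
    b1 <- fit$coefficients[ncol(X0) + 1L]
    feasible <- if (direction == "negative") b1 <= 0 else b1 >= 0
    if (is.na(b1) || !feasible) {
      sum(lm.fit(X0, y)$residuals^2)
    } else {
      sum(fit$residuals^2)
    }
  }, 0)
  list(w1 = grid[which.min(rss)], rss = min(rss))
}

rss_of_weights <- function(w, Q, y, Z = NULL, direction = "negative") {
  X0 <- if (is.null(Z)) matrix(1, length(y), 1) else cbind(1, Z)
  idx <- drop(Q %*% w)
  fit <- lm.fit(cbind(X0, idx), y)
  b1 <- fit$coefficients[ncol(X0) + 1L]
  feasible <- if (direction == "negative") b1 <= 0 else b1 >= 0
  if (is.na(b1) || !feasible) sum(lm.fit(X0, y)$residuals^2)
  else sum(fit$residuals^2)
}
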