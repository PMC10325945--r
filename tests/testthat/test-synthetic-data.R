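# Cohort simulator: determinism, compositional structure, and the
# exposure linkage that makes downstream parameter recovery well-posed.

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- simulation_config(n_subjects = 30, n_taxa = 8,
                           batch_sizes = c(14, 16), important_taxa = 1:2,
                           seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$generated_index, b$truth$generated_index)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(batch_sizes = c(50, 50)), "sum")
  expect_error(simulation_config(important_taxa = 0:4), "1..n_taxa")
  expect_error(simulation_config(noise_sd = 0), "positive")
  expect_error(simulation_config(missing_rate = 0.2), "missing_rate")
  w <- c(0.5, 0.6, rep(0, 38))
  expect_error(simulation_config(true_weights = w, important_taxa = 1:2),
               "summing to 1")
})

test_that("counts are non-negative integers with positive sample totals", {
  cfg <- simulation_config(n_subjects = 20, n_taxa = 10,
                           batch_sizes = c(10, 10), important_taxa = 1:2,
                           seed = 3)
  prof <- generate_taxa_counts(cfg, seed = 3)
  expect_true(all(prof$values >= 0))
  expect_true(all(prof$values == floor(prof$values)))
  expect_true(all(rowSums(prof$values) > 0))
  expect_identical(as.vector(table(prof$batch)), c(10L, 10L))
})

test_that("without zero-inflation, equal concentrations give uniform mean composition", {
  k <- 8L
  cfg <- simulation_config(
    n_subjects = 500, n_taxa = k, batch_sizes = c(250, 250),
    important_taxa = 1:2, zero_inflation = 0,
    dirichlet_concentration = rep(50, k), batch_shift = 1,
    sequencing_depth = 5e4, seed = 9
  )
  rel <- to_relative_abundance(generate_taxa_counts(cfg, seed = 9))
  expect_equal(unname(colMeans(rel$values)), rep(1 / k, k),
               tolerance = 0.02)
})

test_that("heavy zero-inflation yields the matching prevalence", {
  # 30 taxa so that whole-sample redraws (all taxa masked) are rare and
  # the conditional prevalence stays near 1 - zero_inflation
  cfg <- simulation_config(
    n_subjects = 400, n_taxa = 30, batch_sizes = c(200, 200),
    important_taxa = 1:2, zero_inflation = 0.9,
    dirichlet_concentration = rep(20, 30), batch_shift = 1, seed = 5
  )
  prof <- generate_taxa_counts(cfg, seed = 5)
  prev <- colMeans(prof$values > 0)
  # binomial error around 0.1 at n = 400: sd ~ 0.015
  expect_true(all(abs(prev - 0.1) < 0.06))
  expect_lt(abs(mean(prev) - 0.1), 0.02)
})

test_that("relative abundances close to 1 per sample", {
  sc <- make_test_cohort(n = 30, k = 8, seed = 2)
  expect_true(all(abs(rowSums(sc$sim$profile$values) - 1) < 1e-12))
})

test_that("null mixture effect breaks the index-exposure link", {
  sc <- make_test_cohort(n = 200, k = 10, beta_true = 0, noise_sd = 0.5,
                         seed = 8)
  r <- cor(sc$sim$truth$generated_index, sc$y2)
  expect_lt(abs(r), 0.2)
})

test_that("strong negative mixture effect gives strongly negative correlation", {
  sc <- make_test_cohort(n = 120, k = 10, beta_true = -0.5,
                         noise_sd = 0.1, seed = 8)
  expect_lt(cor(sc$sim$truth$generated_index, sc$y2), -0.8)
})

test_that("generated index equals the weighted decile sum", {
  sc <- make_test_cohort(n = 40, k = 8, seed = 4)
  Qfull <- decile_score(sc$sim$profile)
  expect_equal(sc$sim$truth$generated_index,
               drop(Qfull %*% sc$cfg$true_weights))
})

test_that("trimester exposures carry the configured log2-scale correlation", {
  b1 <- simulation_config(n_subjects = 400, n_taxa = 8,
                          batch_sizes = c(200, 200), important_taxa = 1:2,
                          exposure_cor_2T_3T = 1, seed = 6)
  sim <- simulate_cohort(b1)
  expect_equal(cor(log2(sim$cohort$pb_2t_ugL), log2(sim$cohort$pb_3t_ugL)),
               1, tolerance = 1e-12)
  b2 <- simulation_config(n_subjects = 400, n_taxa = 8,
                          batch_sizes = c(200, 200), important_taxa = 1:2,
                          exposure_cor_2T_3T = 0.7, seed = 6)
  sim2 <- simulate_cohort(b2)
  expect_equal(cor(log2(sim2$cohort$pb_2t_ugL),
                   log2(sim2$cohort$pb_3t_ugL)), 0.7, tolerance = 0.08)
  expect_true(all(sim2$cohort$pb_2t_ugL > 0))
})

test_that("exposure scale is calibrated near the cohort's mean Pb", {
  sim <- simulate_cohort(simulation_config(seed = 10))
  expect_equal(median(sim$cohort$pb_2t_ugL), 33.6, tolerance = 0.25 * 33.6)
})

test_that("covariate missingness is MCAR on BMI and SES only, at the configured rate", {
  cfg <- simulation_config(seed = 11) # n = 123, missing_rate 0.04
  cov <- generate_covariates(cfg, seed = 11)
  expect_identical(cov$observed[!is.na(cov$observed)],
                   cov$complete[!is.na(cov$observed)])
  n_na <- colSums(is.na(cov$observed))
  expect_equal(unname(n_na[c("sex", "maternal_age", "child_age",
                             "batch")]), rep(0, 4))
  # expected ~5 per eligible column; binomial sd ~ 2.2
  expect_true(all(n_na[c("ses", "maternal_bmi")] <= 14))
  cov0 <- generate_covariates(cfg, seed = 11, missing_rate = 0)
  expect_false(anyNA(cov0$observed))
  cov_b <- generate_covariates(cfg, seed = 11)
  expect_identical(cov$observed, cov_b$observed)
})

test_that("cohort files round-trip through the documented formats", {
  sc <- make_test_cohort(n = 20, k = 6, seed = 12)
  dir <- tempfile("sim_out_")
  paths <- write_cohort_files(sc$sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_taxa_tsv(paths[["taxa"]])
  expect_equal(back$values, sc$sim$counts$values)
  expect_identical(as.character(back$batch),
                   as.character(sc$sim$counts$batch))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$beta_true, sc$cfg$beta_true)
  expect_equal(truth$true_weights, sc$cfg$true_weights)
  unlink(dir, recursive = TRUE)
})
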