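# Synthetic cohort generator: zero-inflated Dirichlet-multinomial taxa
# counts in two sequencing batches, covariates with MCAR missingness,
# and trimester exposures linearly linked (on the log2 scale) to a
# sparse weighted decile index — the exact structure the downstream
# mixture model assumes, so parameter recovery is well-posed.

#' Simulation configuration
#'
#' Defaults describe the emulated cohort: 123 subjects sequenced in two
#' batches of 50 and 73, 40 species-level taxa, 5 truly associated taxa
#' at weight 0.2 each, a mixture effect of -0.5 per unit of the WQS
#' index on log2 Pb, trimester exposures correlated at 0.7, calibrated
#' so the 2nd-trimester geometric-mean Pb is near 33.6 ug/L, 30%
#' zero-inflation, and under 5% missingness on maternal BMI and SES.
#'
#' @param n_subjects,n_taxa cohort and taxa-panel sizes.
#' @param batch_sizes two batch sizes summing to `n_subjects`.
#' @param important_taxa indices of truly associated taxa.
#' @param true_weights non-negative weights summing to 1 over
#'   `important_taxa` (zero elsewhere). Default: equal weights.
#' @param beta_true mixture effect on log2 Pb per unit of the index.
#' @param covariate_effects length-7 vector of covariate effects on
#'   log2 Pb (order of [covariate_design] columns).
#' @param exposure_mean_ugL target geometric-mean 2nd-trimester Pb.
#' @param exposure_cor_2T_3T correlation of the two trimester exposures
#'   on the log2 scale.
#' @param zero_inflation probability a taxon is structurally absent
#'   from a sample.
#' @param dirichlet_concentration per-taxon Dirichlet concentration;
#'   default is a geometric decay summing to 10 (strongly overdispersed,
#'   rank-skewed compositions typical of stool metagenomes).
#' @param batch_shift multiplicative shift applied to the concentration
#'   parameters of batch 2 (a mild compositional batch effect).
#' @param missing_rate MCAR missingness probability (<= 0.05), applied
#'   to maternal BMI and SES only.
#' @param noise_sd residual SD of log2 Pb around the linear predictor.
#' @param sequencing_depth reads per sample for the multinomial draw.
#' @param seed integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 123L,
                              n_taxa = 40L,
                              batch_sizes = c(50L, 73L),
                              important_taxa = 1:5,
                              true_weights = NULL,
                              beta_true = -0.5,
                              covariate_effects = c(0.10, 0.05, 0.10,
                                                    0.01, 0.005, 0.02,
                                                    0.10),
                              exposure_mean_ugL = 33.6,
                              exposure_cor_2T_3T = 0.7,
                              zero_inflation = 0.3,
                              dirichlet_concentration = NULL,
                              batch_shift = 1.5,
                              missing_rate = 0.04,
                              noise_sd = 0.25,
                              sequencing_depth = 1e5,
                              seed = 1L) {
  if (sum(batch_sizes) != n_subjects)
    stopf("batch_sizes must sum to n_subjects")
  if (any(important_taxa < 1 | important_taxa > n_taxa))
    stopf("important_taxa must index 1..n_taxa")
  if (is.null(true_weights)) {
    true_weights <- numeric(n_taxa)
    true_weights[important_taxa] <- 1 / length(important_taxa)
  }
  if (length(true_weights) != n_taxa || any(true_weights < 0) ||
      abs(sum(true_weights) - 1) > 1e-9)
    stopf("true_weights must be length n_taxa, >= 0, summing to 1")
  if (any(true_weights[-important_taxa] != 0))
    stopf("true_weights must be zero off the important set")
  if (is.null(dirichlet_concentration)) {
    decay <- exp(-seq(0, 3, length.out = n_taxa))
    dirichlet_concentration <- 10 * decay / sum(decay)
  }
  if (length(dirichlet_concentration) != n_taxa ||
      any(dirichlet_concentration <= 0))
    stopf("dirichlet_concentration must be %d positive values", n_taxa)
  if (missing_rate < 0 || missing_rate > 0.05)
    stopf("missing_rate must be in [0, 0.05]")
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  if (abs(exposure_cor_2T_3T) > 1)
    stopf("exposure_cor_2T_3T must be in [-1, 1]")
  structure(list(
    n_subjects = as.integer(n_subjects), n_taxa = as.integer(n_taxa),
    batch_sizes = as.integer(batch_sizes),
    important_taxa = as.integer(important_taxa),
    true_weights = true_weights, beta_true = beta_true,
    covariate_effects = covariate_effects,
    exposure_mean_ugL = exposure_mean_ugL,
    exposure_cor_2T_3T = exposure_cor_2T_3T,
    zero_inflation = zero_inflation,
    dirichlet_concentration = dirichlet_concentration,
    batch_shift = batch_shift, missing_rate = missing_rate,
    noise_sd = noise_sd, sequencing_depth = sequencing_depth,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate zero-inflated Dirichlet-multinomial taxa counts
#'
#' For each sample: a Bernoulli presence mask (probability
#' `1 - zero_inflation` per taxon) zeroes concentration parameters
#' *before* the Dirichlet draw — structural absences, with compositions
#' valid by construction — then counts come from a multinomial at the
#' configured depth. Batch 2 concentrations are multiplied by
#' `batch_shift`. A sample whose mask removes every taxon is redrawn
#' (up to 100 times, then an error).
#'
#' @param config a [simulation_config].
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return a count [taxa_profile] with batch labels.
#' @export
generate_taxa_counts <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  k <- config$n_taxa
  batch <- rep(c("batch1", "batch2"), times = config$batch_sizes)
  counts <- matrix(0L, n, k,
                   dimnames = list(sprintf("S%03d", seq_len(n)),
                                   sprintf("taxon_%02d", seq_len(k))))
  for (i in seq_len(n)) {
    conc <- config$dirichlet_concentration
    if (batch[i] == "batch2") conc <- conc * config$batch_shift
    for (try in seq_len(100L)) {
      mask <- stats::rbinom(k, 1L, 1 - config$zero_inflation)
      if (any(mask == 1L)) break
      if (try == 100L) stopf("sample %d: all taxa masked after 100 redraws", i)
    }
    g <- numeric(k)
    on_idx <- which(mask == 1L)
    g[on_idx] <- stats::rgamma(length(on_idx), shape = conc[on_idx], rate = 1)
    if (sum(g) <= 0) { # all gamma draws underflowed; give the largest mass
      g[on_idx[which.max(conc[on_idx])]] <- 1
    }
    p <- g / sum(g)
    counts[i, ] <- stats::rmultinom(1L, size = config$sequencing_depth, prob = p)
  }
  taxa_profile(counts, batch = batch, is_relative = FALSE)
}

#' Generate covariates with MCAR missingness
#'
#' Child sex is Bernoulli (60% male, the cohort's split), SES a 3-level
#' ordinal (lower/middle/higher at 54/37/10%), maternal age and BMI
#' Gaussian in plausible ranges, child age 9-11 years. Missingness is
#' injected completely at random on maternal BMI and SES only; batch is
#' never missing.
#'
#' @param config a [simulation_config].
#' @param seed optional seed.
#' @param missing_rate override of `config$missing_rate` (used
#'   internally to obtain the complete table).
#' @return list with `observed` (missingness injected), `complete`, and
#'   logical `missing_mask` (same shape as the table).
#' @export
generate_covariates <- function(config, seed = NULL,
                                missing_rate = config$missing_rate) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  complete <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    sex = ifelse(stats::rbinom(n, 1L, 0.398) == 1L, "female", "male"),
    ses = sample(c("lower", "middle", "higher"), n, replace = TRUE,
                 prob = c(0.536, 0.366, 0.098)),
    maternal_age = clamp(stats::rnorm(n, 28.5, 5.2), 18, 45),
    maternal_bmi = clamp(stats::rnorm(n, 27.2, 4.0), 17, 45),
    child_age = clamp(stats::rnorm(n, 9.7, 0.7), 9, 11),
    batch = rep(c("batch1", "batch2"), times = config$batch_sizes),
    stringsAsFactors = FALSE
  )
  observed <- complete
  mask <- matrix(FALSE, n, ncol(complete),
                 dimnames = list(complete$subject_id, names(complete)))
  if (missing_rate > 0) {
    for (col in c("maternal_bmi", "ses")) {
      hit <- stats::runif(n) < missing_rate
      observed[[col]][hit] <- NA
      mask[, col] <- hit
    }
  }
  list(observed = observed, complete = complete, missing_mask = mask)
}

#' Generate trimester exposures from the decile index
#'
#' The generative model is the one the mixture stage fits:
#' `log2(Pb_2T) = b0 + beta_true * sum_j w_j q_ij + Z gamma + eps`,
#' `eps ~ N(0, noise_sd^2)`, with `q` the decile-scored taxa matrix and
#' `Z` the (complete) covariate design. The intercept is chosen so the
#' geometric-mean Pb matches `exposure_mean_ugL`. The 3rd-trimester
#' exposure is generated on the log2 scale with correlation
#' `exposure_cor_2T_3T` to the 2nd trimester and a slightly higher mean
#' (ratio 34.9/33.6, the cohort's trimester means).
#'
#' @param config a [simulation_config].
#' @param Q decile-scored taxa matrix (from [decile_score]).
#' @param covariates *complete* covariate table (see
#'   [generate_covariates]).
#' @param seed optional seed.
#' @return list with `pb_2t_ugL`, `pb_3t_ugL`, and `truth` (a
#'   `simulation_truth` list: `true_weights`, `beta_true`,
#'   `important_taxa`, `generated_index`).
#' @export
generate_exposures <- function(config, Q, covariates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$noise_sd <= 0) stopf("noise_sd must be positive")
  n <- config$n_subjects
  stopifnot(nrow(Q) == n, ncol(Q) == config$n_taxa)
  idx <- drop(Q %*% config$true_weights)
  Z <- covariate_design(covariates)
  gam <- config$covariate_effects[seq_len(ncol(Z))]
  lp <- config$beta_true * idx + drop(Z %*% gam)
  b0 <- log2(config$exposure_mean_ugL) - mean(lp)
  l2_2t <- b0 + lp + stats::rnorm(n, 0, config$noise_sd)
  rho <- config$exposure_cor_2T_3T
  ctr <- l2_2t - mean(l2_2t)
  l2_3t <- log2(config$exposure_mean_ugL * 34.9 / 33.6) +
    rho * ctr + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n, 0, stats::sd(ctr))
  truth <- structure(list(
    true_weights = config$true_weights, beta_true = config$beta_true,
    important_taxa = config$important_taxa, generated_index = idx
  ), class = "simulation_truth")
  list(pb_2t_ugL = 2^l2_2t, pb_3t_ugL = 2^l2_3t, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates the generators with sub-seeds spawned deterministically
#' from `config$seed`: counts, relative abundances, pooled decile
#' scores, covariates, and exposures linked to the true sparse index.
#'
#' @param config a [simulation_config].
#' @return list with `counts` (count [taxa_profile]), `profile`
#'   (relative abundances), `Q` (decile matrix used for generation),
#'   `cohort` (data frame: exposures on both scales + covariates with
#'   missingness), `cohort_complete` (no missingness), `missing_mask`,
#'   and `truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  seeds <- spawn_seeds(config$seed, 4L)
  counts <- generate_taxa_counts(config, seed = seeds[1])
  profile <- to_relative_abundance(counts)
  Q <- decile_score(profile)
  cov <- generate_covariates(config, seed = seeds[2])
  exp <- generate_exposures(config, Q, cov$complete, seed = seeds[3])
  base <- data.frame(
    subject_id = cov$complete$subject_id,
    pb_2t_ugL = exp$pb_2t_ugL, pb_3t_ugL = exp$pb_3t_ugL,
    log2_pb_2t = log2(exp$pb_2t_ugL), log2_pb_3t = log2(exp$pb_3t_ugL),
    stringsAsFactors = FALSE
  )
  cohort <- cbind(base, cov$observed[-1L])
  cohort_complete <- cbind(base, cov$complete[-1L])
  list(counts = counts, profile = profile, Q = Q, cohort = cohort,
       cohort_complete = cohort_complete, missing_mask = cov$missing_mask,
       truth = exp$truth)
}

#' Write a simulated cohort in the pipeline's input formats
#'
#' Emits the same files the real pipeline reads: a sample x taxon count
#' TSV, a cohort CSV (exposures + covariates), and a ground-truth JSON
#' sidecar (`true_weights`, `beta_true`, `important_taxa`,
#' `generated_index`).
#'
#' @param sim result of [simulate_cohort].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_cohort_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  taxa_path <- file.path(dir, "taxa_counts.tsv")
  cohort_path <- file.path(dir, "cohort.csv")
  truth_path <- file.path(dir, "truth.json")
  write_taxa_tsv(sim$counts, taxa_path)
  utils::write.csv(sim$cohort, cohort_path, row.names = FALSE)
  jsonlite::write_json(
    list(true_weights = sim$truth$true_weights,
         beta_true = sim$truth$beta_true,
         important_taxa = sim$truth$important_taxa,
         generated_index = sim$truth$generated_index),
    truth_path, digits = NA, auto_unbox = TRUE
  )
  invisible(c(taxa = taxa_path, cohort = cohort_path, truth = truth_path))
}
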