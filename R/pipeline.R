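# End-to-end orchestration: preprocess -> descriptives -> diversity ->
# WQS (both directions x both trimesters) -> direction selection ->
# TWAS -> pathways, from a single config with one global seed that
# deterministically spawns per-stage seeds.

#' Analysis configuration for a full pipeline run
#'
#' Inputs are either file paths (taxa TSV + cohort CSV) or a
#' [simulation_config] for a fully synthetic run. All stage seeds are
#' derived from `seed` by stage-name hashing, so stages are
#' reproducible in isolation.
#'
#' @param taxa,cohort input file paths (ignored when `sim` is given).
#' @param sim optional [simulation_config]; when present the cohort is
#'   simulated in-memory.
#' @param filter_threshold,filter_metric taxa filter settings (0.05
#'   prevalence in the primary analysis).
#' @param exposures trimesters to analyse (`"2t"`, `"3t"`).
#' @param wqs a [wqs_config] giving resampling sizes for the WQS stage
#'   (its `direction`/`seed` are overridden per stage).
#' @param n_perm PERMANOVA permutations (10,000 in the full analysis).
#' @param twas_alpha,twas_meff TWAS correction settings.
#' @param pathway_k top-k pathway list size.
#' @param pathway_profile optional stratified pathway table (path or
#'   data frame); synthetic runs generate one keyed to the simulated
#'   taxa when absent.
#' @param out_dir output directory.
#' @param seed global seed.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(taxa = NULL, cohort = NULL, sim = NULL,
                            filter_threshold = 0.05,
                            filter_metric = "prevalence",
                            exposures = c("2t", "3t"),
                            wqs = wqs_config(),
                            n_perm = 10000L,
                            twas_alpha = 0.05, twas_meff = "liji",
                            pathway_k = 20L, pathway_profile = NULL,
                            out_dir = tempfile("gutmix_run_"),
                            seed = 1L) {
  if (is.null(sim) && (is.null(taxa) || is.null(cohort)))
    stopf("provide either input paths (taxa + cohort) or a simulation config")
  if (!is.null(taxa) && !file.exists(taxa)) stopf("taxa file not found: %s", taxa)
  if (!is.null(cohort) && !file.exists(cohort))
    stopf("cohort file not found: %s", cohort)
  structure(list(
    taxa = taxa, cohort = cohort, sim = sim,
    filter_threshold = filter_threshold, filter_metric = filter_metric,
    exposures = exposures, wqs = wqs, n_perm = as.integer(n_perm),
    twas_alpha = twas_alpha, twas_meff = twas_meff,
    pathway_k = as.integer(pathway_k), pathway_profile = pathway_profile,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "analysis_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes
#' machine-readable outputs: descriptive tables, a diversity summary
#' (alpha regression + Kruskal-Wallis + PERMANOVA per trimester), WQS
#' summaries for both directions and trimesters with the selected
#' direction, per-holdout betas and mean weights, TWAS tables with the
#' multiplicity report, the pathway Venn partition, and a run manifest
#' with per-stage seeds and md5 checksums of every output file.
#'
#' @param config an [analysis_config].
#' @return invisibly, a list with all stage results and `manifest`.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_seeds <- list()
  outputs <- character()
  emit <- function(df, name) {
    p <- write_tsv(df, file.path(config$out_dir, name))
    outputs <<- c(outputs, p)
    p
  }
  emit_json <- function(x, name) {
    p <- file.path(config$out_dir, name)
    jsonlite::write_json(x, p, digits = NA, auto_unbox = TRUE, null = "null")
    outputs <<- c(outputs, p)
    p
  }

  # --- inputs -------------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    stage_seeds$simulate <- sim_cfg$seed
    sim <- simulate_cohort(sim_cfg)
    counts <- sim$counts
    cohort_raw <- sim$cohort
    truth <- sim$truth
  } else {
    counts <- read_taxa_tsv(config$taxa)
    cohort_raw <- utils::read.csv(config$cohort, stringsAsFactors = FALSE)
  }

  # --- preprocess ---------------------------------------------------
  stage_seeds$impute <- stage_seed(config$seed, "impute")
  profile <- if (counts$is_relative) counts else
    to_relative_abundance(counts)
  filt <- prevalence_filter(profile, config$filter_threshold,
                            config$filter_metric)
  Q <- decile_score(filt$profile)
  imp <- impute_covariates(cohort_raw, seed = stage_seeds$impute)
  cohort <- imp$cohort
  cohort$log2_pb_2t <- log2_exposure(cohort$pb_2t_ugL, cohort$subject_id)
  cohort$log2_pb_3t <- log2_exposure(cohort$pb_3t_ugL, cohort$subject_id)
  Z <- covariate_design(cohort)

  # --- descriptives -------------------------------------------------
  descr <- lapply(config$exposures, function(tr)
    descriptives_by_quartile(cohort, tr))
  names(descr) <- config$exposures
  for (tr in config$exposures)
    emit(descr[[tr]], sprintf("table1_descriptives_%s.tsv", tr))

  # --- diversity ----------------------------------------------------
  stage_seeds$permanova <- stage_seed(config$seed, "permanova")
  alpha <- shannon_alpha(profile)
  bc <- bray_curtis(profile)
  diversity <- lapply(config$exposures, function(tr) {
    l2 <- cohort[[paste0("log2_pb_", tr)]]
    pb <- cohort[[paste0("pb_", tr, "_ugL")]]
    kw <- kruskal_wallis_by_quartile(alpha, assign_quartiles(pb))
    ar <- alpha_regression(alpha, l2, Z)
    pm <- permanova(bc, l2, Z, n_perm = config$n_perm,
                    seed = stage_seeds$permanova)
    list(kruskal = kw, alpha_reg = ar[c("estimate", "se", "p_value")],
         permanova = pm)
  })
  names(diversity) <- config$exposures
  div_rows <- do.call(rbind, lapply(config$exposures, function(tr) {
    d <- diversity[[tr]]
    data.frame(
      exposure = tr,
      term = c("alpha_kruskal_H", "alpha_regression_beta",
               "beta_permanova_R2"),
      estimate = c(d$kruskal$statistic, d$alpha_reg$estimate,
                   d$permanova$exposure_R2),
      p_value = c(d$kruskal$p_value, d$alpha_reg$p_value,
                  d$permanova$p_value),
      n_perm = c(NA, NA, d$permanova$n_perm),
      seed = c(NA, NA, d$permanova$seed)
    )
  }))
  emit(div_rows, "table2_diversity.tsv")

  # --- WQS (both directions, both trimesters) -----------------------
  wqs_res <- list()
  for (tr in config$exposures) {
    l2 <- cohort[[paste0("log2_pb_", tr)]]
    wseed <- stage_seed(config$seed, paste0("wqs_", tr))
    stage_seeds[[paste0("wqs_", tr)]] <- wseed
    fit_dir <- function(dir) {
      cf <- config$wqs
      cf$direction <- dir
      cf$seed <- wseed # paired holdout splits across directions
      run_wqs_rsrh(Q, l2, Z, cf)
    }
    s_neg <- fit_dir("negative")
    s_pos <- fit_dir("positive")
    sel <- select_direction(s_neg, s_pos)
    chosen <- if (sel$direction == "negative") s_neg else s_pos
    wqs_res[[tr]] <- list(negative = s_neg, positive = s_pos,
                          selected = sel, chosen = chosen)
    emit_json(list(
      exposure = tr, direction = chosen$direction,
      selected = sel$direction, inconclusive = sel$inconclusive,
      mean_beta = chosen$mean_beta, ci_lower = chosen$ci_lower,
      ci_upper = chosen$ci_upper,
      fraction_below_zero = chosen$fraction_below_zero,
      importance_threshold = chosen$importance_threshold,
      important_taxa = chosen$important_taxa,
      mean_aic = chosen$mean_aic, mean_bic = chosen$mean_bic,
      n_holdouts = chosen$n_holdouts, seed = wseed
    ), sprintf("wqs_summary_%s.json", tr))
    emit(data.frame(holdout = seq_along(chosen$holdout_betas),
                    beta = chosen$holdout_betas),
         sprintf("wqs_holdout_betas_%s.tsv", tr))
    emit(data.frame(taxon_id = names(chosen$mean_weights),
                    mean_weight = unname(chosen$mean_weights),
                    importance_fraction =
                      unname(chosen$per_taxon_importance_fraction)),
         sprintf("wqs_weights_%s.tsv", tr))
  }

  # --- TWAS ---------------------------------------------------------
  twas_res <- list()
  for (tr in config$exposures) {
    l2 <- cohort[[paste0("log2_pb_", tr)]]
    res <- taxa_wide_association(Q, l2, Z)
    m_eff <- effective_number_of_tests(Q, config$twas_meff)
    corr <- apply_correction(res, m_eff, config$twas_alpha)
    twas_res[[tr]] <- corr
    emit(corr$results, sprintf("twas_%s.tsv", tr))
    emit_json(corr$report, sprintf("twas_multiplicity_%s.json", tr))
    emit(volcano_table(corr$results), sprintf("twas_volcano_%s.tsv", tr))
  }

  # --- pathways -----------------------------------------------------
  pathway_res <- NULL
  if (length(config$exposures) == 2L) {
    pw_tab <- config$pathway_profile
    if (is.null(pw_tab) && !is.null(config$sim)) {
      pw_seed <- stage_seed(config$seed, "pathways")
      stage_seeds$pathways <- pw_seed
      pw_tab <- synth_pathway_table(colnames(Q), seed = pw_seed)
    }
    if (!is.null(pw_tab)) {
      prof <- parse_pathway_profiles(pw_tab)
      lists <- lapply(config$exposures, function(tr) {
        imp_taxa <- wqs_res[[tr]]$chosen$important_taxa
        # match the normalised species labels used in pathway strata
        imp_taxa <- gsub("_", " ", species_from_lineage(imp_taxa))
        if (length(imp_taxa) == 0L) return(character())
        ft <- pathways_of_taxa(prof, imp_taxa)
        if (nrow(ft) == 0L) character() else
          top_k_pathways(ft, config$pathway_k)
      })
      pathway_res <- venn_partition(lists[[1]], lists[[2]])
      emit_json(list(only_2t = pathway_res$only_2t,
                     common = pathway_res$common,
                     only_3t = pathway_res$only_3t,
                     counts = as.list(pathway_res$counts)),
                "pathways_venn.json")
    }
  }

  # --- manifest -----------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("gutmix")),
    seed = config$seed,
    stage_seeds = stage_seeds,
    filter = list(threshold = config$filter_threshold,
                  metric = config$filter_metric,
                  n_retained = ncol(Q)),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p)))
  )
  emit_json(manifest, "manifest.json")
  invisible(list(
    profile = profile, filtered = filt, Q = Q, cohort = cohort,
    truth = truth, descriptives = descr, diversity = diversity,
    wqs = wqs_res, twas = twas_res, pathways = pathway_res,
    manifest = manifest, out_dir = config$out_dir
  ))
}

#' Sensitivity re-run at a stricter taxa filter
#'
#' Repeats the WQS analysis with taxa detected in at least
#' `threshold` (default 25%) of samples in both batches, without
#' rescaling the retained sub-composition, and reports the base and
#' sensitivity estimates side by side together with the dropped taxa.
#'
#' @param config the [analysis_config] used for the base run.
#' @param base result of [run_all] on `config`.
#' @param threshold sensitivity filter threshold (default 0.25).
#' @return list: `comparison` data frame (per trimester: base and
#'   sensitivity mean beta / CI), `dropped_taxa`, `wqs` (sensitivity
#'   summaries).
#' @export
run_sensitivity <- function(config, base, threshold = 0.25) {
  filt <- prevalence_filter(base$profile, threshold, config$filter_metric)
  dropped <- setdiff(colnames(base$Q), filt$retained)
  Q2 <- decile_score(filt$profile)
  Z <- covariate_design(base$cohort)
  res <- list()
  rows <- list()
  for (tr in config$exposures) {
    l2 <- base$cohort[[paste0("log2_pb_", tr)]]
    cf <- config$wqs
    cf$direction <- base$wqs[[tr]]$selected$direction
    cf$seed <- stage_seed(config$seed, paste0("wqs_sens_", tr))
    s <- run_wqs_rsrh(Q2, l2, Z, cf)
    res[[tr]] <- s
    b <- base$wqs[[tr]]$chosen
    rows[[tr]] <- data.frame(
      exposure = tr,
      analysis = c("base", "sensitivity"),
      threshold = c(config$filter_threshold, threshold),
      n_taxa = c(ncol(base$Q), ncol(Q2)),
      mean_beta = c(b$mean_beta, s$mean_beta),
      ci_lower = c(b$ci_lower, s$ci_lower),
      ci_upper = c(b$ci_upper, s$ci_upper),
      stringsAsFactors = FALSE
    )
  }
  list(comparison = do.call(rbind, rows), dropped_taxa = dropped,
       wqs = res)
}
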