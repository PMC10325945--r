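# Preprocessing: relative abundance, two-batch prevalence filtering,
# log2 exposure transform, decile scoring, quartile assignment,
# descriptive tables.

#' Convert counts to relative abundance
#'
#' Each sample's counts are divided by its total so rows sum to one.
#' Zeros are preserved exactly.
#'
#' @param x a count [taxa_profile] or a non-negative sample x taxon
#'   matrix.
#' @param batch batch labels, used only when `x` is a bare matrix.
#' @return a relative-abundance [taxa_profile].
#' @export
to_relative_abundance <- function(x, batch = "batch1") {
  prof <- if (inherits(x, "taxa_profile")) x else taxa_profile(x, batch)
  tot <- rowSums(prof$values)
  if (any(tot <= 0)) {
    bad <- rownames(prof$values)[tot <= 0]
    stopf("sample(s) with zero total abundance: %s",
          paste(bad, collapse = ", "))
  }
  taxa_profile(prof$values / tot, batch = prof$batch, is_relative = TRUE)
}

#' Filter taxa by detection in every sequencing batch
#'
#' A taxon is retained when it clears the threshold in *each* batch
#' separately — the guard against batch-specific taxa driving results.
#' The default metric is prevalence: the fraction of samples in a batch
#' with non-zero abundance must be at least `threshold`. A mean-relative-
#' abundance metric is available behind `metric` for comparison.
#' Retained columns are *not* renormalised: the filtered table is a
#' sub-composition carried forward as-is, so the original contributions
#' of each taxon are preserved and results are comparable across
#' thresholds.
#'
#' @param profile a relative-abundance [taxa_profile] with >= 2 batches.
#' @param threshold detection threshold in (0, 1); 0.05 in the primary
#'   analysis, 0.25 in the sensitivity analysis.
#' @param metric `"prevalence"` (default) or `"mean_abundance"`.
#' @return a list with `profile` (filtered [taxa_profile]) and
#'   `retained` (character vector of retained taxon ids).
#' @export
prevalence_filter <- function(profile, threshold = 0.05,
                              metric = c("prevalence", "mean_abundance")) {
  metric <- match.arg(metric)
  stopifnot(inherits(profile, "taxa_profile"))
  if (threshold <= 0 || threshold >= 1)
    stopf("threshold must be in (0, 1)")
  if (nlevels(profile$batch) < 2)
    stopf("prevalence_filter requires at least two batches")
  v <- profile$values
  per_batch <- vapply(levels(profile$batch), function(b) {
    rows <- profile$batch == b
    if (metric == "prevalence") {
      colMeans(v[rows, , drop = FALSE] > 0)
    } else {
      colMeans(v[rows, , drop = FALSE])
    }
  }, numeric(ncol(v)))
  keep <- apply(per_batch >= threshold, 1L, all)
  if (!any(keep))
    stopf("no taxa retained at threshold %.3f; try a lower threshold",
          threshold)
  filtered <- taxa_profile(v[, keep, drop = FALSE], batch = profile$batch,
                           is_relative = profile$is_relative)
  list(profile = filtered, retained = colnames(v)[keep])
}

#' Log-base-2 transform of an exposure vector
#'
#' @param pb positive exposure values (blood Pb, micrograms per litre).
#' @param ids optional subject ids used in error messages.
#' @return `log2(pb)`.
#' @export
log2_exposure <- function(pb, ids = NULL) {
  ids <- ids %||% seq_along(pb)
  bad <- !is.na(pb) & pb <= 0
  if (any(bad))
    stopf("non-positive exposure for subject(s): %s",
          paste(ids[bad], collapse = ", "))
  log2(pb)
}

#' Decile-score a relative-abundance profile
#'
#' Replaces each taxon's abundances by quantile ranks so mixture
#' components are comparable: zeros are pinned at score 0, and the
#' non-zero values of each taxon are rank-partitioned into `n_groups`
#' equally sized groups scored `1..n_groups` (empirical deciles of the
#' non-zero distribution by default). Ties share the score of their
#' average rank's group. Scoring pools both batches; batch enters the
#' downstream models as a covariate, not a stratification variable.
#'
#' @param profile a relative-abundance [taxa_profile] (or numeric
#'   matrix).
#' @param n_groups number of quantile groups for the non-zero values
#'   (default 10 = deciles).
#' @param per_batch score within each batch separately (off by default).
#' @return integer matrix of scores in `0..n_groups`, same dimnames as
#'   the input, with attribute `n_groups`.
#' @export
decile_score <- function(profile, n_groups = 10L, per_batch = FALSE) {
  v <- if (inherits(profile, "taxa_profile")) {
    if (!profile$is_relative)
      stopf("decile_score expects a relative-abundance profile")
    profile$values
  } else {
    as.matrix(profile)
  }
  score_col <- function(x) {
    s <- integer(length(x))
    nz <- which(x > 0)
    m <- length(nz)
    if (m == 0L) return(s)
    r <- rank(x[nz], ties.method = "average")
    s[nz] <- pmin(as.integer(floor((r - 1) * n_groups / m)) + 1L, n_groups)
    s
  }
  out <- if (per_batch && inherits(profile, "taxa_profile")) {
    res <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
    for (b in levels(profile$batch)) {
      rows <- profile$batch == b
      res[rows, ] <- apply(v[rows, , drop = FALSE], 2L, score_col)
    }
    res
  } else {
    apply(v, 2L, score_col)
  }
  dimnames(out) <- dimnames(v)
  if (any(colSums(out) == 0))
    warnf("%d taxa are entirely zero and scored 0 throughout",
          sum(colSums(out) == 0))
  storage.mode(out) <- "integer"
  attr(out, "n_groups") <- n_groups
  out
}

#' Assign exposure quartiles
#'
#' Cuts at the empirical 25/50/75 percentiles; ties go to the lower
#' quartile. With distinct values group sizes differ by at most one.
#'
#' @param x numeric exposure vector, `length(x) >= 4`.
#' @return integer labels in 1..4.
#' @export
assign_quartiles <- function(x) {
  if (length(x) < 4L) stopf("need at least 4 observations")
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  if (qs[1] == qs[3]) warnf("degenerate exposure: quartile cut points tie")
  1L + (x > qs[1]) + (x > qs[2]) + (x > qs[3])
}

#' Descriptive table by exposure quartile
#'
#' Cohort characteristics split by quartile of one trimester's exposure:
#' mean (SE) for continuous covariates, n (column %) for categorical
#' ones, plus an overall column. A quartile with a single subject gets
#' `NA` for its SE.
#'
#' @param cohort a cohort data frame (see [simulate_cohort] for the
#'   column dictionary).
#' @param exposure `"2t"` or `"3t"`: which trimester's Pb defines the
#'   quartiles.
#' @return long-format data frame with columns `variable`, `level`,
#'   `statistic`, `overall`, `q1`..`q4`.
#' @export
descriptives_by_quartile <- function(cohort, exposure = c("2t", "3t")) {
  exposure <- match.arg(exposure)
  pb <- cohort[[paste0("pb_", exposure, "_ugL")]]
  q <- assign_quartiles(pb)
  cont <- c(
    setNames(paste0("pb_", exposure, "_ugL"),
             sprintf("Pb %s (ug/L)", toupper(exposure))),
    "Maternal age (years)" = "maternal_age",
    "Maternal BMI (kg/m2)" = "maternal_bmi",
    "Child age (years)" = "child_age"
  )
  catg <- c("Child sex" = "sex", "Maternal SES" = "ses", "Batch" = "batch")
  mean_se <- function(x) {
    x <- x[!is.na(x)]
    se <- if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
    c(mean = mean(x), se = se)
  }
  rows <- list()
  for (nm in names(cont)) {
    x <- cohort[[cont[[nm]]]]
    cells <- vapply(1:4, function(g) mean_se(x[q == g]), numeric(2))
    ov <- mean_se(x)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm, level = "", statistic = "mean (SE)",
      overall = sprintf("%.2f (%s)", ov[1],
                        ifelse(is.na(ov[2]), "-", sprintf("%.2f", ov[2]))),
      q1 = sprintf("%.2f (%s)", cells[1, 1],
                   ifelse(is.na(cells[2, 1]), "-", sprintf("%.2f", cells[2, 1]))),
      q2 = sprintf("%.2f (%s)", cells[1, 2],
                   ifelse(is.na(cells[2, 2]), "-", sprintf("%.2f", cells[2, 2]))),
      q3 = sprintf("%.2f (%s)", cells[1, 3],
                   ifelse(is.na(cells[2, 3]), "-", sprintf("%.2f", cells[2, 3]))),
      q4 = sprintf("%.2f (%s)", cells[1, 4],
                   ifelse(is.na(cells[2, 4]), "-", sprintf("%.2f", cells[2, 4]))),
      stringsAsFactors = FALSE
    )
  }
  for (nm in names(catg)) {
    x <- factor(cohort[[catg[[nm]]]])
    for (lv in levels(x)) {
      cnt <- vapply(1:4, function(g) sum(x[q == g] == lv, na.rm = TRUE), 0L)
      tot <- vapply(1:4, function(g) sum(!is.na(x[q == g])), 0L)
      ovc <- sum(x == lv, na.rm = TRUE)
      fmt <- function(n, d) sprintf("%d (%.1f)", n, 100 * n / max(d, 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = lv, statistic = "n (%)",
        overall = fmt(ovc, sum(!is.na(x))),
        q1 = fmt(cnt[1], tot[1]), q2 = fmt(cnt[2], tot[2]),
        q3 = fmt(cnt[3], tot[3]), q4 = fmt(cnt[4], tot[4]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Covariate design matrix for the adjusted models
#'
#' Fixed a-priori adjustment set used throughout: child sex (male
#' reference), maternal SES as two indicator contrasts (lower
#' reference), maternal age, maternal BMI, child age, and sequencing
#' batch (first batch reference). Expects complete covariates
#' (run [impute_covariates] first).
#'
#' @param cohort cohort data frame with complete covariates.
#' @return numeric design matrix (no intercept column).
#' @export
covariate_design <- function(cohort) {
  need <- c("sex", "ses", "maternal_age", "maternal_bmi", "child_age",
            "batch")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("missing covariate column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyNA(cohort[need]))
    stopf("covariates contain missing values; impute first")
  ses <- factor(cohort$ses, levels = c("lower", "middle", "higher"))
  if (anyNA(ses)) stopf("ses must be one of lower/middle/higher")
  batch <- factor(cohort$batch)
  sex <- if (is.numeric(cohort$sex)) cohort$sex else
    as.numeric(cohort$sex == "female")
  Z <- cbind(
    sex_female = sex,
    ses_middle = as.numeric(ses == "middle"),
    ses_higher = as.numeric(ses == "higher"),
    maternal_age = cohort$maternal_age,
    maternal_bmi = cohort$maternal_bmi,
    child_age = cohort$child_age
  )
  if (nlevels(batch) > 1L)
    Z <- cbind(Z, batch2 = as.numeric(batch == levels(batch)[2L]))
  rownames(Z) <- cohort$subject_id
  Z
}
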