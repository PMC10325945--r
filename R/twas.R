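# Taxa-wide association: one covariate-adjusted linear model per taxon
# (decile score on log2 Pb), with Bonferroni correction softened by the
# eigenvalue-based effective number of tests.

#' Per-taxon association model
#'
#' Gaussian linear model of one taxon's decile score on log2 Pb plus
#' the fixed covariate set; the exposure coefficient with its SE and
#' two-sided p-value is the result. A constant taxon column yields an
#' NA row with a warning rather than an error.
#'
#' @param scores one taxon's decile scores (or abundances).
#' @param log2_pb log2-transformed exposure.
#' @param Z covariate design matrix from [covariate_design] (or a
#'   covariate table).
#' @param taxon_id label carried into the result.
#' @return one-row data frame: `taxon_id`, `estimate`, `se`, `p_raw`,
#'   `neg_log10_p`, `direction_flag`.
#' @export
fit_taxon_model <- function(scores, log2_pb, Z, taxon_id = "taxon") {
  if (!is.matrix(Z)) Z <- covariate_design(Z)
  if (stats::sd(scores) < 1e-12) {
    warnf("taxon %s has a constant column; returning NA", taxon_id)
    return(data.frame(taxon_id = taxon_id, estimate = NA_real_,
                      se = NA_real_, p_raw = NA_real_,
                      neg_log10_p = NA_real_,
                      direction_flag = NA_character_,
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(score = scores, log2_pb = log2_pb, Z)
  fit <- stats::lm(score ~ ., data = df)
  sm <- summary(fit)$coefficients
  est <- sm["log2_pb", 1]
  p <- sm["log2_pb", 4]
  data.frame(taxon_id = taxon_id, estimate = est, se = sm["log2_pb", 2],
             p_raw = p, neg_log10_p = -log10(p),
             direction_flag = if (est < 0) "negative" else "positive",
             stringsAsFactors = FALSE)
}

#' Taxa-wide association analysis
#'
#' Runs [fit_taxon_model] over every column of the decile-scored taxa
#' matrix.
#'
#' @param Q sample x taxon matrix of decile scores.
#' @param log2_pb log2 exposure.
#' @param Z covariate design matrix or table.
#' @return data frame with one row per taxon.
#' @export
taxa_wide_association <- function(Q, log2_pb, Z) {
  if (!is.matrix(Z)) Z <- covariate_design(Z)
  out <- lapply(seq_len(ncol(Q)), function(j)
    fit_taxon_model(Q[, j], log2_pb, Z,
                    taxon_id = colnames(Q)[j] %||% paste0("taxon_", j)))
  do.call(rbind, out)
}

#' Effective number of tests from correlation eigenvalues
#'
#' Computes the eigenvalues of the Pearson correlation matrix of the
#' analysis taxa matrix and reduces them to an effective test count.
#' The default is the Li-Ji construction,
#' `m_eff = sum_i [ I(|l_i| >= 1) + (|l_i| - floor(|l_i|)) ]`: fully
#' independent columns give `m_eff = M`, a perfectly correlated pair
#' collapses to one test. The simpler eigenvalue-variance form
#' (Cheverud/Nyholt), `1 + (M - 1)(1 - var(l)/M)`, is available for
#' comparison.
#'
#' @param mat sample x taxon matrix (decile-scored analysis matrix by
#'   convention) with at least 2 non-constant columns.
#' @param method `"liji"` (default) or `"nyholt"`.
#' @return effective number of tests, `1 <= m_eff <= M`.
#' @export
effective_number_of_tests <- function(mat, method = c("liji", "nyholt")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  usable <- apply(mat, 2L, function(x) stats::sd(x) > 0)
  if (sum(usable) < 2L)
    stopf("need at least 2 non-constant columns (have %d)", sum(usable))
  cm <- stats::cor(mat[, usable, drop = FALSE])
  lam <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  lam <- abs(lam)
  if (method == "liji") {
    sum(as.numeric(lam >= 1) + (lam - floor(lam)))
  } else {
    M <- length(lam)
    1 + (M - 1) * (1 - stats::var(lam) / M)
  }
}

#' Apply the effective-tests Bonferroni correction
#'
#' A taxon is significant when its raw p-value is below
#' `alpha / m_eff`.
#'
#' @param results TWAS result data frame (from
#'   [taxa_wide_association]).
#' @param m_eff effective number of tests (>= 1).
#' @param alpha nominal significance level.
#' @return list: `results` with a `significant_after_correction`
#'   column, and `report` (n_taxa, m_eff, alpha_nominal,
#'   alpha_adjusted).
#' @export
apply_correction <- function(results, m_eff, alpha = 0.05) {
  if (m_eff < 1) stopf("m_eff must be >= 1")
  alpha_adj <- alpha / m_eff
  results$significant_after_correction <- !is.na(results$p_raw) &
    results$p_raw < alpha_adj
  list(results = results,
       report = list(n_taxa = nrow(results), m_eff = m_eff,
                     alpha_nominal = alpha, alpha_adjusted = alpha_adj))
}

#' Plot-ready volcano table
#'
#' Estimates against `-log10 p`, sorted by ascending p-value, with the
#' direction flag recorded (the plotting convention colours negative
#' and positive associations differently). NA-estimate rows are dropped
#' and their count attached as attribute `n_dropped`.
#'
#' @param results TWAS result data frame.
#' @return data frame `taxon_id`, `estimate`, `neg_log10_p`,
#'   `direction_flag` (plus significance flag if present).
#' @export
volcano_table <- function(results) {
  if (nrow(results) == 0L) stopf("results must be non-empty")
  keep <- !is.na(results$estimate)
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$p_raw), , drop = FALSE]
  cols <- intersect(c("taxon_id", "estimate", "neg_log10_p",
                      "direction_flag", "significant_after_correction"),
                    names(out))
  out <- out[, cols, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}
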