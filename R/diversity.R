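# Alpha diversity (Shannon, nats), Bray-Curtis dissimilarity, and the
# unadjusted / covariate-adjusted association tests.

#' Shannon alpha diversity (natural log)
#'
#' `-sum p_i ln p_i` over the non-zero proportions of each sample, after
#' renormalising the row to sum one (so the statistic is invariant to a
#' positive rescaling of the row). Zeros contribute nothing.
#'
#' @param x a [taxa_profile] or a non-negative matrix/vector of
#'   abundances.
#' @return numeric vector of Shannon indices, one per sample.
#' @export
shannon_alpha <- function(x) {
  v <- if (inherits(x, "taxa_profile")) x$values else
    if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  tot <- rowSums(v)
  if (any(tot <= 0)) stopf("sample(s) with zero total abundance")
  drop(vegan::diversity(v / tot, index = "shannon"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`; in `[0, 1]` for
#' non-negative profiles, 0 for identical samples, 1 for disjoint
#' support. A semimetric (triangle inequality not guaranteed).
#'
#' @param x a [taxa_profile] or non-negative sample x taxon matrix with
#'   positive row sums.
#' @return a `dist` object with attribute `metric = "bray"`.
#' @export
bray_curtis <- function(x) {
  v <- if (inherits(x, "taxa_profile")) x$values else as.matrix(x)
  if (any(rowSums(v) <= 0)) stopf("sample(s) with zero total abundance")
  d <- vegan::vegdist(v, method = "bray")
  attr(d, "metric") <- "bray"
  d
}

#' Kruskal-Wallis test of alpha diversity across exposure quartiles
#'
#' Rank-based H with tie correction against a chi-square reference with
#' `groups - 1` df. Empty groups are dropped with a warning; a fully
#' tied sample is reported as H = 0, p = 1.
#'
#' @param alpha numeric alpha-diversity values.
#' @param groups group labels (exposure quartiles).
#' @return list with `statistic` (H), `df`, `p_value`, `n_groups`.
#' @export
kruskal_wallis_by_quartile <- function(alpha, groups) {
  groups <- if (is.factor(groups)) groups else factor(groups)
  sizes <- table(groups)
  if (any(sizes == 0L)) {
    warnf("dropping %d empty group(s)", sum(sizes == 0L))
    groups <- droplevels(groups)
  }
  if (nlevels(groups) < 2L) stopf("need at least 2 non-empty groups")
  if (length(unique(alpha)) == 1L)
    return(list(statistic = 0, df = nlevels(groups) - 1L, p_value = 1,
                n_groups = nlevels(groups)))
  kt <- stats::kruskal.test(alpha, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n_groups = nlevels(groups))
}

#' Covariate-adjusted regression of alpha diversity on exposure
#'
#' Ordinary least squares of Shannon diversity on log2 Pb plus the fixed
#' adjustment set (sex, SES contrasts, maternal age, BMI, child age,
#' batch). Errors on a rank-deficient design, naming the collinear
#' columns.
#'
#' @param alpha Shannon values per subject.
#' @param log2_pb log2-transformed exposure.
#' @param covariates complete covariate table or a pre-built design
#'   matrix from [covariate_design].
#' @return list with `estimate`, `se`, `p_value` for the exposure term,
#'   and the full `fit` (an `lm` object).
#' @export
alpha_regression <- function(alpha, log2_pb, covariates) {
  Z <- if (is.matrix(covariates)) covariates else covariate_design(covariates)
  X <- cbind(log2_pb = log2_pb, Z)
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1L) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X) + 1L)] - 1L]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  df <- data.frame(alpha = alpha, X, check.names = FALSE)
  fit <- stats::lm(alpha ~ ., data = df)
  sm <- summary(fit)$coefficients
  list(estimate = sm["log2_pb", 1], se = sm["log2_pb", 2],
       p_value = sm["log2_pb", 4], fit = fit)
}
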