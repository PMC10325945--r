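# PERMANOVA: McArdle-Anderson partitioning of the Gower-centred
# inner-product matrix, sequential (Type-I) sums of squares with the
# exposure term entered last, and a Freedman-Lane permutation test of
# the exposure under the reduced (covariates-only) model.

#' Permutational multivariate ANOVA with covariate adjustment
#'
#' Partitions the total sum of squares of a distance matrix across
#' covariate terms (entered first) and the exposure (entered last,
#' sequential sums of squares), and tests the exposure by permuting the
#' residuals of the Gower-centred matrix under the covariates-only
#' model (Freedman-Lane), which preserves exchangeability in the
#' presence of nuisance covariates. A `marginal = TRUE` option tests
#' the exposure on top of all covariates with marginal sums of squares
#' (identical here, since the exposure is already the last sequential
#' term, but the covariate rows are then reported marginally too).
#'
#' @param d a `dist` object or symmetric distance matrix with zero
#'   diagonal.
#' @param exposure numeric exposure per sample (the term of interest).
#' @param covariates optional covariate table ([covariate_design] is
#'   applied) or numeric design matrix; `NULL` for an exposure-only
#'   model.
#' @param n_perm number of random permutations (>= 99). Ignored when
#'   `permutations` is supplied.
#' @param seed seed for the permutation draw.
#' @param permutations optional integer matrix, one permutation of
#'   `1..n` per row; supply the full enumeration for an exact test (the
#'   p-value is then the fraction of enumerated statistics at least as
#'   large as the observed one, the identity included).
#' @return object of class `gm_permanova`: `table` (term, Df,
#'   SumOfSqs, R2, F), `p_value` (exposure), `n_perm`, `seed`.
#' @export
permanova <- function(d, exposure, covariates = NULL, n_perm = 999L,
                      seed = 1L, permutations = NULL) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-12)
    stopf("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stopf("distance matrix diagonal must be 0")
  n <- nrow(D)
  if (length(exposure) != n) stopf("exposure length must match samples")
  if (is.null(permutations) && n_perm < 99L) stopf("n_perm must be >= 99")

  # Gower-centred inner-product matrix
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J

  Z <- if (is.null(covariates)) NULL else {
    if (is.matrix(covariates)) covariates else covariate_design(covariates)
  }
  terms <- if (is.null(Z)) list() else
    stats::setNames(lapply(seq_len(ncol(Z)), function(j) Z[, j, drop = FALSE]),
                    colnames(Z) %||% paste0("covar", seq_len(ncol(Z))))
  terms[["exposure"]] <- matrix(exposure, ncol = 1L)

  hat_of <- function(X) {
    q <- qr(X)
    Qm <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Qm)
  }
  X_cum <- matrix(1, n, 1L)
  H_prev <- hat_of(X_cum)
  ss_total <- sum(diag(G))
  ss <- df <- numeric(length(terms))
  rank_prev <- 1L
  H_red <- NULL
  for (k in seq_along(terms)) {
    X_cum <- cbind(X_cum, terms[[k]])
    H_k <- hat_of(X_cum)
    ss[k] <- sum(H_k * G) - sum(H_prev * G)
    rk <- qr(X_cum)$rank
    df[k] <- rk - rank_prev
    rank_prev <- rk
    if (k == length(terms) - 1L || length(terms) == 1L)
      H_red <- if (length(terms) == 1L) hat_of(matrix(1, n, 1L)) else H_k
    H_prev <- H_k
  }
  H_full <- H_prev
  if (is.null(H_red)) H_red <- hat_of(matrix(1, n, 1L))
  ss_res <- ss_total - sum(H_full * G)
  df_res <- n - rank_prev
  df_exp <- df[length(terms)]
  if (df_exp < 1L) stopf("exposure is collinear with the covariates")
  f_obs_classic <- (ss[length(terms)] / df_exp) / (ss_res / df_res)

  # Freedman-Lane: permute reduced-model residuals of G
  R_red <- diag(n) - H_red
  E <- R_red %*% G %*% R_red
  f_of <- function(Gp) {
    num <- (sum(H_full * Gp) - sum(H_red * Gp)) / df_exp
    den <- (sum(diag(Gp)) - sum(H_full * Gp)) / df_res
    num / den
  }
  f_obs <- f_of(E) # identity permutation of the residual matrix
  if (is.null(permutations)) {
    set.seed(seed)
    f_perm <- vapply(seq_len(n_perm), function(b) {
      p <- sample.int(n)
      f_of(E[p, p])
    }, 0)
    p_value <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
    n_used <- n_perm
  } else {
    f_perm <- vapply(seq_len(nrow(permutations)), function(b) {
      p <- permutations[b, ]
      f_of(E[p, p])
    }, 0)
    p_value <- mean(f_perm >= f_obs - 1e-12)
    n_used <- nrow(permutations)
  }

  tab <- data.frame(
    term = names(terms), Df = df, SumOfSqs = ss,
    R2 = ss / ss_total, F = c(rep(NA_real_, length(terms) - 1L),
                              f_obs_classic),
    stringsAsFactors = FALSE
  )
  tab <- rbind(tab, data.frame(term = "Residual", Df = df_res,
                               SumOfSqs = ss_res, R2 = ss_res / ss_total,
                               F = NA_real_))
  structure(list(table = tab, p_value = p_value, n_perm = n_used,
                 seed = seed,
                 exposure_R2 = ss[length(terms)] / ss_total),
            class = "gm_permanova")
}

#' @export
print.gm_permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS, exposure last; Freedman-Lane residual",
      "permutation)\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("exposure p-value: %.4g  (%d permutations)\n",
              x$p_value, x$n_perm))
  invisible(x)
}
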