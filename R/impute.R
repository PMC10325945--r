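# Chained-equation imputation of the covariate table. Each incomplete
# column is cycled over, modelled on all other covariates: predictive
# mean matching for continuous columns, a draw from the predicted class
# probabilities of a multinomial logistic model for categorical ones.
# A single completed dataset is returned from a fixed, seeded number of
# cycles; observed cells are never altered.

#' Impute missing covariates by chained equations
#'
#' @param cohort cohort data frame; missingness is expected only in the
#'   covariate columns (`sex`, `ses`, `maternal_age`, `maternal_bmi`,
#'   `child_age`). Warns above 5% per-column missingness, errors above
#'   20% or on a fully missing column.
#' @param seed integer seed (imputation is stochastic).
#' @param n_cycles chained-equation cycles (default 5).
#' @param k_pmm donor-pool size for predictive mean matching.
#' @return list with `cohort` (completed data frame) and `report`
#'   (data frame: column, n_missing, method).
#' @export
impute_covariates <- function(cohort, seed = 1L, n_cycles = 5L, k_pmm = 5L) {
  set.seed(seed)
  covars <- intersect(
    c("sex", "ses", "maternal_age", "maternal_bmi", "child_age", "batch"),
    names(cohort)
  )
  n <- nrow(cohort)
  n_miss <- vapply(cohort[covars], function(x) sum(is.na(x)), 0L)
  if (any(n_miss == n))
    stopf("column(s) entirely missing: %s",
          paste(covars[n_miss == n], collapse = ", "))
  if (any(n_miss / n > 0.20))
    stopf("column(s) exceed 20%% missingness: %s",
          paste(covars[n_miss / n > 0.20], collapse = ", "))
  if (any(n_miss / n > 0.05))
    warnf("column(s) exceed 5%% missingness: %s",
          paste(covars[n_miss / n > 0.05], collapse = ", "))
  incomplete <- covars[n_miss > 0]
  report <- data.frame(
    column = incomplete,
    n_missing = n_miss[incomplete],
    method = vapply(incomplete, function(cl)
      if (is.numeric(cohort[[cl]])) "pmm" else "multinomial draw", ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (length(incomplete) == 0L)
    return(list(cohort = cohort, report = report))

  work <- cohort[covars]
  miss_idx <- lapply(work, function(x) which(is.na(x)))
  # initial fill: mean / mode
  for (cl in incomplete) {
    x <- work[[cl]]
    if (is.numeric(x)) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
    } else {
      tab <- table(x)
      x[is.na(x)] <- names(tab)[which.max(tab)]
    }
    work[[cl]] <- x
  }
  rhs_design <- function(except) {
    cols <- setdiff(covars, except)
    stats::model.matrix(~ ., data = as.data.frame(
      lapply(work[cols], function(x) if (is.character(x)) factor(x) else x)
    ))[, -1L, drop = FALSE]
  }
  for (cycle in seq_len(n_cycles)) {
    for (cl in incomplete) {
      mi <- miss_idx[[cl]]
      obs <- setdiff(seq_len(n), mi)
      X <- rhs_design(cl)
      if (is.numeric(work[[cl]])) {
        fit <- stats::lm.fit(cbind(1, X[obs, , drop = FALSE]),
                             cohort[[cl]][obs])
        pred_all <- drop(cbind(1, X) %*% fit$coefficients)
        for (i in mi) {
          d <- abs(pred_all[obs] - pred_all[i])
          donors <- obs[order(d)[seq_len(min(k_pmm, length(obs)))]]
          work[[cl]][i] <- cohort[[cl]][sample(donors, 1L)]
        }
      } else {
        y <- factor(cohort[[cl]][obs])
        df <- data.frame(.y = y, X[obs, , drop = FALSE])
        fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE)
        pr <- stats::predict(fit,
                             newdata = data.frame(X[mi, , drop = FALSE]),
                             type = "probs")
        if (is.null(dim(pr))) {
          pr <- if (nlevels(y) == 2L) cbind(1 - pr, pr) else
            matrix(pr, nrow = 1L)
        }
        lv <- levels(y)
        for (j in seq_along(mi))
          work[[cl]][mi[j]] <- sample(lv, 1L, prob = pr[j, ])
      }
    }
  }
  completed <- cohort
  for (cl in incomplete) {
    x <- cohort[[cl]]
    x[miss_idx[[cl]]] <- work[[cl]][miss_idx[[cl]]]
    completed[[cl]] <- x
  }
  list(cohort = completed, report = report)
}
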