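# Alpha/beta diversity and their association tests, including the
# PERMANOVA oracle and calibration checks.

test_that("Shannon diversity matches closed forms in nats", {
  expect_equal(shannon_alpha(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_alpha(c(1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(shannon_alpha(c(0.5, 0.5, 0)), log(2), tolerance = 1e-12)
  expect_error(shannon_alpha(c(0, 0, 0)), "zero total")
})

test_that("Shannon is invariant to rescaling a sample", {
  set.seed(71)
  x <- rgamma(10, 1)
  expect_equal(shannon_alpha(x), shannon_alpha(7.3 * x), tolerance = 1e-12)
})

test_that("Bray-Curtis matches worked values and is a proper dissimilarity", {
  m <- rbind(a = c(0.7, 0.3), b = c(0.3, 0.7), c = c(0.7, 0.3),
             d = c(1, 0), e = c(0, 1))
  D <- as.matrix(bray_curtis(m))
  expect_equal(D["a", "c"], 0, tolerance = 1e-12)
  expect_equal(D["d", "e"], 1, tolerance = 1e-12)
  expect_equal(D["a", "b"], 0.4, tolerance = 1e-12)
  expect_equal(D, t(D), tolerance = 1e-12)
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("Kruskal-Wallis H matches the hand-computed rank formula", {
  out <- kruskal_wallis_by_quartile(c(1, 2, 3, 4, 5, 6),
                                    rep(c("lo", "hi"), each = 3))
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/(6*7) (36/3 + 225/3) - 21
  expect_equal(out$statistic, 12 / 42 * (12 + 75) - 21, tolerance = 1e-12)
  expect_equal(out$statistic, 3.857, tolerance = 1e-3)
})

test_that("fully tied alpha values give H = 0, p = 1", {
  out <- kruskal_wallis_by_quartile(rep(1.5, 8), rep(1:2, each = 4))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
})

test_that("empty groups are dropped with a warning", {
  g <- factor(rep(c("a", "b"), each = 4), levels = c("a", "b", "c"))
  expect_warning(out <- kruskal_wallis_by_quartile(rnorm(8), g), "empty")
  expect_identical(out$n_groups, 2L)
})

test_that("null Kruskal-Wallis p-values are approximately uniform", {
  set.seed(72)
  ps <- replicate(500, {
    kruskal_wallis_by_quartile(rnorm(48), rep(1:4, each = 12))$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("alpha regression recovers a planted exposure effect", {
  sc <- make_test_cohort(n = 80, k = 8, seed = 73)
  set.seed(73)
  alpha <- 2 - 0.3 * sc$y2 + rnorm(80, 0, 1e-8)
  fit <- alpha_regression(alpha, sc$y2, sc$Z)
  expect_equal(fit$estimate, -0.3, tolerance = 1e-4)
  expect_lt(fit$p_value, 1e-10)
})

test_that("alpha regression keeps its nominal type-I error", {
  sc <- make_test_cohort(n = 60, k = 6, seed = 74)
  set.seed(74)
  ps <- replicate(500, {
    alpha_regression(rnorm(60), sc$y2, sc$Z)$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("a duplicated covariate column is reported as collinear", {
  sc <- make_test_cohort(n = 40, k = 6, seed = 75)
  Zdup <- cbind(sc$Z, maternal_age_copy = sc$Z[, "maternal_age"])
  expect_error(alpha_regression(rnorm(40), sc$y2, Zdup),
               "maternal_age_copy")
})

test_that("PERMANOVA agrees with vegan::adonis2 on F and R2", {
  set.seed(76)
  m <- matrix(rgamma(30 * 12, 1), 30, 12)
  m <- m / rowSums(m)
  expo <- rnorm(30)
  d <- bray_curtis(m)
  mine <- permanova(d, expo, NULL, n_perm = 199, seed = 1)
  ref <- vegan::adonis2(d ~ expo, permutations = 99)
  expect_equal(mine$table$F[1], ref$F[1], tolerance = 1e-9)
  expect_equal(mine$table$R2[1], ref$R2[1], tolerance = 1e-9)
  expect_equal(mine$table$SumOfSqs[1:2], ref$SumOfSqs[1:2],
               tolerance = 1e-9)
})

test_that("PERMANOVA R2 components sum to one and p is seed-reproducible", {
  sc <- make_test_cohort(n = 40, k = 10, seed = 77)
  d <- bray_curtis(sc$sim$profile)
  a <- permanova(d, sc$y2, sc$Z, n_perm = 199, seed = 4)
  b <- permanova(d, sc$y2, sc$Z, n_perm = 199, seed = 4)
  expect_equal(sum(a$table$R2), 1, tolerance = 1e-9)
  expect_identical(a$p_value, b$p_value)
  expect_true(all(a$table$Df > 0))
})

test_that("PERMANOVA p-value is invariant to sample reordering", {
  sc <- make_test_cohort(n = 30, k = 8, seed = 78)
  D <- as.matrix(bray_curtis(sc$sim$profile))
  a <- permanova(D, sc$y2, sc$Z, n_perm = 499, seed = 9)
  perm <- sample(30)
  b <- permanova(D[perm, perm], sc$y2[perm], sc$Z[perm, ],
                 n_perm = 499, seed = 9)
  expect_equal(a$table$F[nrow(a$table) - 1], b$table$F[nrow(b$table) - 1],
               tolerance = 1e-9)
  expect_lt(abs(a$p_value - b$p_value), 0.05)
})

test_that("exposure-only PERMANOVA p matches exhaustive enumeration at n = 6", {
  set.seed(79)
  m <- matrix(rgamma(6 * 5, 1), 6, 5)
  m <- m / rowSums(m)
  D <- as.matrix(bray_curtis(m))
  groups <- c(0, 0, 0, 1, 1, 1)
  perms <- all_perms(6)
  mine <- permanova(D, groups, NULL, permutations = perms)
  f_obs <- oracle_f_binary(D, groups)
  f_all <- apply(perms, 1, function(p) oracle_f_binary(D, groups[p]))
  expect_equal(mine$table$F[1], f_obs, tolerance = 1e-9)
  expect_equal(mine$p_value, mean(f_all >= f_obs - 1e-12),
               tolerance = 1e-12)
})

test_that("a perfectly separated binary exposure is detected", {
  set.seed(80)
  m <- rbind(
    matrix(rep(c(10, 1, 1, 1), each = 10), 10) + matrix(runif(40), 10),
    matrix(rep(c(1, 1, 1, 10), each = 10), 10) + matrix(runif(40), 10)
  )
  m <- m / rowSums(m)
  expo <- rep(c(0, 1), each = 10)
  out <- permanova(bray_curtis(m), expo, NULL, n_perm = 999, seed = 2)
  expect_lte(out$p_value, 1 / 1000 + 1e-12)
  expect_gt(out$exposure_R2, 0.5)
})

test_that("malformed distance input is rejected", {
  D <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(permanova(D, c(0, 1)), "symmetric")
  D2 <- matrix(c(0.5, 1, 1, 0), 2, 2)
  expect_error(permanova(D2, c(0, 1)), "diagonal")
})
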