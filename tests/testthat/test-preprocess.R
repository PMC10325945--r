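# Preprocessing: relative abundance, two-batch filtering, decile
# scoring, quartiles, descriptives, imputation.

test_that("relative abundance is row proportions with zeros preserved", {
  m <- rbind(c(10, 30, 60), c(0, 0, 5))
  rel <- to_relative_abundance(m)
  expect_equal(unname(rel$values[1, ]), c(0.1, 0.3, 0.6))
  expect_equal(unname(rel$values[2, ]), c(0, 0, 1))
  expect_error(to_relative_abundance(rbind(c(1, 1), c(0, 0))),
               "zero total")
})

test_that("prevalence filter requires the threshold in every batch", {
  # taxon A: 6% / 6.8%  -> kept at 5%; taxon B: 10% / 4% -> dropped
  n1 <- 50; n2 <- 73
  v <- matrix(0, n1 + n2, 3,
              dimnames = list(NULL, c("A", "B", "keepall")))
  v[1:3, "A"] <- 0.1; v[n1 + (1:5), "A"] <- 0.1
  v[1:5, "B"] <- 0.1; v[n1 + (1:2), "B"] <- 0.1
  v[, "keepall"] <- 0.2
  prof <- taxa_profile(v, batch = rep(c("b1", "b2"), c(n1, n2)),
                       is_relative = TRUE)
  out <- prevalence_filter(prof, 0.05)
  expect_true("A" %in% out$retained)
  expect_false("B" %in% out$retained)
  rare <- taxa_profile(v[, c("A", "B")],
                       batch = rep(c("b1", "b2"), c(n1, n2)),
                       is_relative = TRUE)
  expect_error(prevalence_filter(rare, 0.5), "lower threshold")
  expect_error(prevalence_filter(taxa_profile(v, "one", is_relative = TRUE),
                                 0.05), "two batches")
})

test_that("filter retention is monotone in the threshold and preserves values", {
  sc <- make_test_cohort(n = 60, k = 15, seed = 21)
  r05 <- prevalence_filter(sc$sim$profile, 0.05)
  r25 <- prevalence_filter(sc$sim$profile, 0.25)
  expect_true(all(r25$retained %in% r05$retained))
  # no renormalisation: sub-composition carried forward as-is
  expect_equal(r05$profile$values,
               sc$sim$profile$values[, r05$retained, drop = FALSE])
})

test_that("mean-abundance filter variant is available", {
  v <- cbind(big = c(0.9, 0.9, 0.8, 0.8), small = c(0.1, 0.1, 0.2, 0.2))
  prof <- taxa_profile(v, batch = c("b1", "b1", "b2", "b2"),
                       is_relative = TRUE)
  out <- prevalence_filter(prof, 0.5, metric = "mean_abundance")
  expect_identical(out$retained, "big")
})

test_that("log2 exposure transform validates positivity", {
  expect_equal(log2_exposure(c(32, 1)), c(5, 0))
  expect_error(log2_exposure(c(4, 0), ids = c("a", "b")), "b")
})

test_that("decile scoring pins zeros and chunks non-zero values into tenths", {
  x <- c(rep(0, 5), sample(seq(0.01, 0.2, length.out = 20)))
  m <- cbind(taxon = x)
  s <- decile_score(taxa_profile(m, "b1", is_relative = TRUE))
  expect_true(all(s[x == 0] == 0))
  # 20 distinct non-zero values -> exactly two per decile group,
  # matching an independent sort-and-chunk oracle
  nz <- x[x > 0]
  oracle <- integer(length(nz))
  oracle[order(nz)] <- rep(1:10, each = 2)
  expect_identical(unname(s[x > 0, 1]), oracle)
  expect_identical(as.vector(table(s[x > 0])), rep(2L, 10))
})

test_that("a column with exactly ten distinct non-zero values scores 1..10", {
  x <- c(0, 0.05, 0, 0.01, 0.02, 0.08, 0.03, 0.04, 0.06, 0.07, 0.10, 0.09)
  s <- decile_score(matrix(x, ncol = 1))
  expect_identical(sort(unname(s[x > 0, 1])), 1:10)
  expect_identical(unname(s[order(x)[x[order(x)] > 0], 1]), 1:10)
})

test_that("an all-zero taxon is scored zero with a warning", {
  m <- cbind(a = c(0, 0, 0), b = c(0.1, 0.2, 0.3))
  expect_warning(s <- decile_score(m), "entirely zero")
  expect_identical(unname(s[, "a"]), rep(0L, 3))
})

test_that("decile scores are invariant to monotone transforms of the non-zero values", {
  set.seed(31)
  x <- c(rep(0, 8), runif(25))
  s1 <- decile_score(matrix(x, ncol = 1))
  s2 <- decile_score(matrix(ifelse(x > 0, exp(3 * x), 0), ncol = 1))
  expect_identical(s1[, 1], s2[, 1])
})

test_that("quartile assignment cuts at empirical quartiles with ties going low", {
  expect_identical(assign_quartiles(1:8), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_warning(q <- assign_quartiles(rep(2, 10)), "degenerate")
  expect_identical(q, rep(1L, 10))
  set.seed(7)
  x <- sample(seq_len(1000), 123)
  sizes <- sort(as.vector(table(assign_quartiles(x))))
  expect_true(max(sizes) - min(sizes) <= 1)
})

test_that("descriptives table reports means, SEs and counts by quartile", {
  sc <- make_test_cohort(n = 40, k = 6, seed = 41)
  tab <- descriptives_by_quartile(sc$cohort, "2t")
  expect_true(all(c("variable", "overall", "q1", "q4") %in% names(tab)))
  # hand-computed oracle for one quartile of one covariate
  q <- assign_quartiles(sc$cohort$pb_2t_ugL)
  x <- sc$cohort$maternal_age[q == 1]
  expected <- sprintf("%.2f (%.2f)", mean(x), sd(x) / sqrt(length(x)))
  expect_identical(tab$q1[tab$variable == "Maternal age (years)"], expected)
  # categorical counts sum to the group size
  sexrows <- tab[tab$variable == "Child sex", ]
  counts <- as.integer(sub(" .*", "", sexrows$q2))
  expect_identical(sum(counts), sum(q == 2))
})

test_that("a quartile degenerate to one subject reports an undefined SE", {
  cohort <- data.frame(
    subject_id = sprintf("s%d", 1:5),
    pb_2t_ugL = c(1, 2, 3, 4, 100), pb_3t_ugL = c(1, 2, 3, 4, 100),
    sex = "male", ses = "lower", maternal_age = c(20, 21, 22, 23, 24),
    maternal_bmi = 25, child_age = 10, batch = "b1",
    stringsAsFactors = FALSE
  )
  tab <- descriptives_by_quartile(cohort, "2t")
  expect_match(tab$q4[tab$variable == "Maternal age (years)"],
               "\\(-\\)")
})

test_that("taxa profile TSV round trip is exact", {
  sc <- make_test_cohort(n = 15, k = 5, seed = 51)
  p <- tempfile(fileext = ".tsv")
  write_taxa_tsv(sc$sim$profile, p)
  back <- read_taxa_tsv(p)
  expect_equal(back$values, sc$sim$profile$values)
  unlink(p)
})

test_that("MetaPhlAn-style merged tables parse to species-level profiles", {
  lin <- c(
    "k__Bacteria|p__Bacteroidetes",
    "k__Bacteria|p__Bacteroidetes|g__Bacteroides|s__Bacteroides_caccae",
    "k__Bacteria|p__Bacteroidetes|g__Bacteroides|s__Bacteroides_caccae|t__GCF_1",
    "k__Bacteria|p__Firmicutes|g__Ruminococcus|s__Ruminococcus_gnavus"
  )
  tab <- data.frame(clade_name = lin, S1 = c(100, 60, 60, 40),
                    S2 = c(100, 20, 20, 80), check.names = FALSE)
  p <- tempfile(fileext = ".tsv")
  write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- read_metaphlan(p, batch = c("b1", "b2"))
  expect_identical(dim(prof$values), c(2L, 2L)) # species rows only
  expect_true(prof$is_relative)
  expect_equal(unname(prof$values[, 1]), c(0.6, 0.2))
  expect_identical(attr(prof, "species_label"),
                   c("Bacteroides caccae", "Ruminococcus gnavus"))
  unlink(p)
})
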