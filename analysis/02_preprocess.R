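#!/usr/bin/env Rscript
# Stage 2 — preprocessing and descriptives.
#
# Counts -> relative abundance; taxa kept only if detected in at least
# 5% of samples in EACH sequencing batch (no renormalisation of the
# retained sub-composition); missing covariates completed by seeded
# chained-equation imputation; exposures log2-transformed; descriptive
# tables by exposure quartile for both trimesters.

library(gutmix)

counts <- read_taxa_tsv("results/data/taxa_counts.tsv")
cohort_raw <- read.csv("results/data/cohort.csv", stringsAsFactors = FALSE)

profile <- to_relative_abundance(counts)
filt <- prevalence_filter(profile, threshold = 0.05)
message(sprintf("taxa retained at 5%% prevalence in both batches: %d / %d",
                length(filt$retained), ncol(profile$values)))
f25 <- prevalence_filter(profile, threshold = 0.25)
message(sprintf("  (sensitivity panel at 25%%: %d taxa)",
                length(f25$retained)))

imp <- impute_covariates(cohort_raw, seed = 4L)
message(sprintf("imputed %s",
                if (nrow(imp$report) == 0) "nothing (complete table)" else
                  paste(sprintf("%s: %d cells (%s)", imp$report$column,
                                imp$report$n_missing, imp$report$method),
                        collapse = "; ")))
cohort <- imp$cohort

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
for (tr in c("2t", "3t")) {
  tab <- descriptives_by_quartile(cohort, tr)
  write.table(tab, sprintf("results/tables/table1_descriptives_%s.tsv", tr),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# analysis-ready objects for the later stages (plain text only)
Q <- decile_score(filt$profile)
write_taxa_tsv(filt$profile, "results/data/taxa_filtered_relabund.tsv")
write.table(data.frame(sample_id = rownames(Q), Q, check.names = FALSE),
            "results/data/taxa_deciles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.csv(cohort, "results/data/cohort_imputed.csv", row.names = FALSE)
message("wrote filtered profile, decile matrix, imputed cohort, Table-1 tables")
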