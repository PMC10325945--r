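#!/usr/bin/env Rscript
# Stage 6 — gene-function pathways of the important taxa.
#
# Extracts the pathways carried by the WQS-important taxa at each
# trimester from a stratified pathway-abundance table (synthetic here,
# keyed to the simulated taxa), takes the top 20 by occurrence
# frequency, and partitions the two lists into a Venn structure.

library(gutmix)

imp2 <- unlist(jsonlite::read_json("results/wqs/summary_2t.json",
                                   simplifyVector = TRUE)$important_taxa)
imp3 <- unlist(jsonlite::read_json("results/wqs/summary_3t.json",
                                   simplifyVector = TRUE)$important_taxa)
Qdf <- read.delim("results/data/taxa_deciles.tsv", check.names = FALSE)
taxa <- colnames(Qdf)[-1]

pw_tab <- synth_pathway_table(taxa, n_pathways = 40, n_samples = 5,
                              seed = 23L)
prof <- parse_pathway_profiles(pw_tab)
norm <- function(x) gsub("_", " ", species_from_lineage(x))

lists <- lapply(list(imp2, imp3), function(imp) {
  ft <- pathways_of_taxa(prof, norm(imp))
  top_k_pathways(ft, k = 20)
})
vp <- venn_partition(lists[[1]], lists[[2]])
print(vp)
message(sprintf("%.0f%% of the union is shared between trimesters",
                100 * vp$counts[2] / sum(vp$counts)))

dir.create("results/pathways", recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(
  list(only_2t = vp$only_2t, common = vp$common, only_3t = vp$only_3t,
       counts = as.list(vp$counts)),
  "results/pathways/venn.json", auto_unbox = TRUE, digits = NA)
n <- max(lengths(list(vp$only_2t, vp$common, vp$only_3t)))
pad <- function(x) c(x, rep("", n - length(x)))
write.table(
  data.frame(only_2t = pad(vp$only_2t), common = pad(vp$common),
             only_3t = pad(vp$only_3t)),
  "results/pathways/venn.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
message("wrote results/pathways/venn.{json,tsv}")
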