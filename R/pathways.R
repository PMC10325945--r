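# Pathway-overlap analysis: parse stratified pathway-abundance tables,
# extract the pathways carried by the WQS-important taxa at each
# trimester, rank by occurrence frequency, and partition the two top-k
# lists into a Venn structure.

#' Parse a stratified pathway-abundance table
#'
#' Reads the merged stratified TSV convention of functional profilers:
#' first column `"PWY-ID: description|g__Genus.s__Genus_species"` (or
#' unstratified `"PWY-ID: description"`), remaining columns one per
#' sample. UNMAPPED and UNINTEGRATED rows are excluded; malformed
#' stratification strings are skipped with a counted warning. Species
#' labels are normalised (`g__X.s__X_caccae` -> `"X caccae"`) to match
#' the taxa table's display names.
#'
#' @param x TSV path or an equivalent data frame (pathway column
#'   first).
#' @return long-format data frame of records `pathway_id`, `species`
#'   (`"unstratified"` when absent), `sample_id`, `abundance`, with
#'   attribute `n_skipped`.
#' @export
parse_pathway_profiles <- function(x) {
  tab <- if (is.character(x)) {
    utils::read.delim(x, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    x
  }
  key <- as.character(tab[[1L]])
  samples <- names(tab)[-1L]
  drop <- grepl("^(UNMAPPED|UNINTEGRATED)", key)
  tab <- tab[!drop, , drop = FALSE]
  key <- key[!drop]
  pid <- sub(":.*$", "", sub("\\|.*$", "", key))
  strat <- ifelse(grepl("|", key, fixed = TRUE),
                  sub("^[^|]*\\|", "", key), "unstratified")
  malformed <- strat != "unstratified" &
    !grepl("s__", strat, fixed = TRUE)
  if (any(malformed))
    warnf("skipping %d row(s) with malformed stratification",
          sum(malformed))
  keep <- !malformed
  pid <- pid[keep]
  strat <- strat[keep]
  tab <- tab[keep, , drop = FALSE]
  species <- ifelse(strat == "unstratified", "unstratified",
                    species_from_lineage(strat))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  out <- data.frame(
    pathway_id = rep(pid, times = length(samples)),
    species = rep(species, times = length(samples)),
    sample_id = rep(samples, each = length(pid)),
    abundance = as.vector(vals),
    stringsAsFactors = FALSE
  )
  if (any(out$abundance < 0)) stopf("pathway abundances must be >= 0")
  attr(out, "n_skipped") <- sum(malformed)
  out
}

#' Pathways carried by a set of important taxa
#'
#' For each pathway, the occurrence frequency: the number of
#' important-taxon strata in which the pathway has non-zero abundance
#' in at least one sample. Total abundance over those strata is kept as
#' the ranking tie-breaker. Taxa absent from the profile are reported
#' in attribute `absent_taxa`, not an error.
#'
#' @param profile long-format records from [parse_pathway_profiles].
#' @param taxa character set of important species names.
#' @return data frame `pathway_id`, `frequency`, `total_abundance`,
#'   sorted by frequency; empty (with a warning) if no stratum matches.
#' @export
pathways_of_taxa <- function(profile, taxa) {
  if (length(taxa) == 0L) stopf("taxa must be non-empty")
  absent <- setdiff(taxa, unique(profile$species))
  rec <- profile[profile$species %in% taxa & profile$abundance > 0, ,
                 drop = FALSE]
  if (nrow(rec) == 0L) {
    warnf("no pathway stratum matches the given taxa")
    out <- data.frame(pathway_id = character(), frequency = integer(),
                      total_abundance = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "absent_taxa") <- absent
    return(out)
  }
  freq <- tapply(rec$species, rec$pathway_id,
                 function(s) length(unique(s)))
  tot <- tapply(rec$abundance, rec$pathway_id, sum)
  out <- data.frame(pathway_id = names(freq),
                    frequency = as.integer(freq),
                    total_abundance = as.numeric(tot[names(freq)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, -out$total_abundance, out$pathway_id), ]
  rownames(out) <- NULL
  attr(out, "absent_taxa") <- absent
  out
}

#' Top-k pathways by occurrence frequency
#'
#' Deterministic ranking: frequency first, total abundance as the
#' tie-breaker, then lexicographic pathway id. `rank_by = "abundance"`
#' swaps the first two keys.
#'
#' @param freq_table output of [pathways_of_taxa].
#' @param k how many pathways (20 in the reported analysis).
#' @param rank_by `"frequency"` (default) or `"abundance"`.
#' @return character vector of pathway ids, length `min(k, nrow)`.
#' @export
top_k_pathways <- function(freq_table, k = 20L,
                           rank_by = c("frequency", "abundance")) {
  rank_by <- match.arg(rank_by)
  if (k < 1L) stopf("k must be >= 1")
  ord <- if (rank_by == "frequency") {
    order(-freq_table$frequency, -freq_table$total_abundance,
          freq_table$pathway_id)
  } else {
    order(-freq_table$total_abundance, -freq_table$frequency,
          freq_table$pathway_id)
  }
  ids <- freq_table$pathway_id[ord]
  if (length(ids) < k)
    warnf("only %d pathways available (k = %d)", length(ids), k)
  utils::head(ids, k)
}

#' Venn partition of two pathway lists
#'
#' Splits the union of the two trimester lists into pathways unique to
#' the first, common to both, and unique to the second.
#'
#' @param list_2t,list_3t character vectors of pathway ids.
#' @return list of class `venn_partition`: `only_2t`, `common`,
#'   `only_3t`, and integer `counts`.
#' @export
venn_partition <- function(list_2t, list_3t) {
  a <- unique(list_2t)
  b <- unique(list_3t)
  out <- list(
    only_2t = sort(setdiff(a, b)),
    common = sort(intersect(a, b)),
    only_3t = sort(setdiff(b, a))
  )
  out$counts <- lengths(out[1:3])
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("pathway overlap: %d only 2T | %d common | %d only 3T\n",
              x$counts[1], x$counts[2], x$counts[3]))
  invisible(x)
}

#' Synthetic stratified pathway table for simulated taxa
#'
#' Builds a small pathway-abundance table whose strata reference the
#' simulated taxa (synthetic stand-in for a functional-profiler output;
#' pathway ids are generic `PWY-###` labels). Each taxon carries a
#' random subset of a shared pathway pool so that important-taxon
#' pathway extraction and the trimester Venn overlap are exercisable on
#' purely simulated cohorts.
#'
#' @param taxa character vector of taxon/species names.
#' @param n_pathways size of the shared pathway pool.
#' @param n_samples number of sample columns.
#' @param seed integer seed.
#' @return data frame in the stratified-TSV layout accepted by
#'   [parse_pathway_profiles].
#' @export
synth_pathway_table <- function(taxa, n_pathways = 40L, n_samples = 5L,
                                seed = 1L) {
  set.seed(seed)
  pool <- sprintf("PWY-%03d", seq_len(n_pathways))
  rows <- list()
  for (tx in taxa) {
    carried <- sample(pool, sample(5:15, 1L))
    lab <- paste0("g__", sub(" .*", "", tx), ".s__", gsub(" ", "_", tx))
    for (pw in carried) {
      rows[[length(rows) + 1L]] <- c(
        paste0(pw, ": synthetic pathway|", lab),
        sprintf("%.4f", stats::rgamma(n_samples, 2, 10))
      )
    }
  }
  m <- do.call(rbind, rows)
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- c("# Pathway", sprintf("S%03d", seq_len(n_samples)))
  for (j in 2:ncol(out)) out[[j]] <- as.numeric(out[[j]])
  out
}
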