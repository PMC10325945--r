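#' Sample-by-taxon abundance profile
#'
#' The compositional substrate of every analysis stage: a numeric
#' sample x taxon matrix (counts or relative abundances), per-sample
#' sequencing-batch labels, and a flag saying whether rows are
#' proportions. Full lineage strings may be kept as taxon names; a
#' species-level display label is derived on request.
#'
#' @param values numeric sample x taxon matrix, non-negative.
#' @param batch batch label per sample (coerced to factor). A single
#'   value is recycled.
#' @param is_relative logical; `TRUE` if rows are proportions. If rows
#'   are proportions each must sum to at most 1 (sub-compositions after
#'   filtering are allowed).
#' @param sample_ids,taxon_ids optional identifiers; default to the
#'   dimnames of `values`.
#'
#' @return An object of class `taxa_profile`: a list with elements
#'   `values`, `batch`, `is_relative`.
#' @export
taxa_profile <- function(values, batch, is_relative = FALSE,
                         sample_ids = NULL, taxon_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("abundance values must be numeric")
  if (any(values < 0)) stopf("abundance values must be non-negative")
  sample_ids <- sample_ids %||% rownames(values) %||%
    sprintf("S%03d", seq_len(nrow(values)))
  taxon_ids <- taxon_ids %||% colnames(values) %||%
    sprintf("taxon_%02d", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids)) stopf("sample ids must be unique")
  dimnames(values) <- list(sample_ids, taxon_ids)
  if (length(batch) == 1L) batch <- rep(batch, nrow(values))
  if (length(batch) != nrow(values))
    stopf("batch must give one label per sample")
  if (is_relative) {
    rs <- rowSums(values)
    if (any(rs > 1 + 1e-9))
      stopf("relative-abundance rows must sum to <= 1 (max row sum %.6f)",
            max(rs))
  }
  structure(
    list(values = values, batch = factor(batch), is_relative = is_relative),
    class = "taxa_profile"
  )
}

#' @export
print.taxa_profile <- function(x, ...) {
  cat(sprintf(
    "taxa_profile: %d samples x %d taxa (%s), %d batch(es)\n",
    nrow(x$values), ncol(x$values),
    if (x$is_relative) "relative abundance" else "counts",
    nlevels(x$batch)
  ))
  invisible(x)
}

#' @export
dim.taxa_profile <- function(x) dim(x$values)

#' Read a MetaPhlAn-style merged abundance table
#'
#' Reads the merged TSV produced by taxonomic profilers: first column a
#' pipe-delimited clade lineage (`k__...|p__...|...|s__...`), remaining
#' columns one per sample. Species-level rows are selected (lineage
#' contains `s__` but no strain-level `t__`); values are transposed to
#' sample x taxon orientation. Whether the file holds counts or
#' percentages/proportions is auto-detected from the column sums:
#' percentage tables (sums near 100) are rescaled to proportions.
#'
#' @param path TSV file path.
#' @param batch batch label per sample column (recycled if length 1).
#' @param species_only keep only species-level rows (default `TRUE`).
#' @return a [taxa_profile]. Taxon ids are the full lineages; the
#'   species display label is attached as attribute `species_label`.
#' @export
read_metaphlan <- function(path, batch = "batch1", species_only = TRUE) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  lineage <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (species_only) {
    keep <- grepl("s__", lineage, fixed = TRUE) &
      !grepl("t__", lineage, fixed = TRUE)
    lineage <- lineage[keep]
    vals <- vals[keep, , drop = FALSE]
  }
  m <- t(vals) # samples x taxa
  colnames(m) <- lineage
  cs <- rowSums(m)
  is_rel <- FALSE
  if (all(abs(cs - 100) < 1)) {
    m <- m / 100
    is_rel <- TRUE
  } else if (all(cs <= 1 + 1e-6)) {
    is_rel <- TRUE
  }
  prof <- taxa_profile(m, batch = batch, is_relative = is_rel)
  attr(prof, "species_label") <- species_from_lineage(lineage)
  prof
}

#' Species display label from a clade lineage
#'
#' `...|g__Bacteroides|s__Bacteroides_caccae` becomes
#' `"Bacteroides caccae"`; inputs without an `s__` field are returned
#' unchanged.
#'
#' @param lineage character vector of pipe-delimited lineages or
#'   `g__X.s__Y` pathway strata.
#' @return character vector of species names.
#' @export
species_from_lineage <- function(lineage) {
  out <- lineage
  has <- grepl("s__", lineage, fixed = TRUE)
  sp <- sub(".*s__", "", lineage[has])
  sp <- sub("\\|t__.*$", "", sp)
  out[has] <- gsub("_", " ", sp)
  out
}

#' Write / read a plain sample x taxon TSV
#'
#' Round-trip storage for a [taxa_profile]: samples in rows, taxa in
#' columns, a `sample_id` first column and a `batch` second column.
#' Values are written at full precision so that write-then-read
#' reproduces the matrix exactly.
#'
#' @param profile a [taxa_profile].
#' @param path output TSV path.
#' @export
write_taxa_tsv <- function(profile, path) {
  df <- data.frame(
    sample_id = rownames(profile$values),
    batch = as.character(profile$batch),
    profile$values,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_taxa_tsv
#' @param is_relative flag for the returned profile; if `NULL`,
#'   auto-detected from row sums.
#' @export
read_taxa_tsv <- function(path, is_relative = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("sample_id", "batch")),
                    drop = FALSE])
  rownames(m) <- df$sample_id
  if (is.null(is_relative)) is_relative <- all(rowSums(m) <= 1 + 1e-6)
  taxa_profile(m, batch = df$batch, is_relative = is_relative)
}
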