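# Immunopeptidome post-processing: decoy-based FDR filtering, length
# and binding-rank filters, repertoire comparison and source-gene
# aggregation.

#' Decoy-based FDR filter
#'
#' Finds the lowest score threshold `t` such that
#' `#decoys(score >= t) / #targets(score >= t) <= fdr` and returns the
#' target records at or above it (ties at the threshold are kept). If
#' no threshold achieves the bound an empty table is returned; if no
#' decoys are present the FDR is undefined and all targets are
#' returned with a warning.
#'
#' @param records Data frame with at least `score` and `is_decoy`.
#' @param fdr FDR bound (fraction).
#' @return The filtered target records.
#' @export
fdr_filter <- function(records, fdr = 0.05) {
  stopifnot(all(c("score", "is_decoy") %in% names(records)))
  targets <- records[!records$is_decoy, , drop = FALSE]
  if (!any(records$is_decoy)) {
    warning("no decoy records: FDR undefined, returning all targets")
    return(targets)
  }
  if (!nrow(targets)) return(targets)
  for (t in sort(unique(records$score))) {
    nt <- sum(targets$score >= t)
    if (nt == 0L) break
    nd <- sum(records$score[records$is_decoy] >= t)
    if (nd / nt <= fdr) {
      return(targets[targets$score >= t, , drop = FALSE])
    }
  }
  targets[0, , drop = FALSE]
}

#' Construct an immunopeptidome
#'
#' @param sample_id Sample label.
#' @param peptides Character vector (deduplicated, sorted).
#' @param annotations Optional per-peptide data frame.
#' @return An `immunopeptidome` object.
#' @export
immunopeptidome <- function(sample_id, peptides, annotations = NULL) {
  structure(
    list(sample_id = sample_id, peptides = sort(unique(peptides)),
         annotations = annotations),
    class = "immunopeptidome"
  )
}

#' @export
print.immunopeptidome <- function(x, ...) {
  cat("immunopeptidome '", x$sample_id, "': ", length(x$peptides),
      " unique peptides\n", sep = "")
  invisible(x)
}

#' Length and binding-rank filter
#'
#' Keeps peptides of `min_len` to `max_len` residues (inclusive) with
#' predicted eluted-ligand rank at or below `max_rank` percent, and
#' deduplicates to a peptide set per sample. Apply after
#' [fdr_filter()].
#'
#' @param records Data frame with `peptide`, `sample_id`,
#'   `percent_rank`.
#' @param min_len,max_len Peptide length bounds in aa.
#' @param max_rank Percent-rank bound.
#' @return Named list of `immunopeptidome` objects, one per sample.
#' @export
map_filter <- function(records, min_len = 8L, max_len = 11L,
                       max_rank = 2.0) {
  len <- nchar(records$peptide)
  keep <- len >= min_len & len <= max_len &
    records$percent_rank <= max_rank
  kept <- records[keep, , drop = FALSE]
  out <- list()
  for (s in sort(unique(kept$sample_id))) {
    sub <- kept[kept$sample_id == s, , drop = FALSE]
    ann <- unique(sub[, intersect(c("peptide", "best_allele",
                                    "source_accession", "db_origin"),
                                  names(sub)), drop = FALSE])
    out[[s]] <- immunopeptidome(s, sub$peptide, ann)
  }
  out
}

#' Jaccard similarity of two immunopeptidomes
#'
#' @param a,b `immunopeptidome` objects or character vectors.
#' @return `|A intersect B| / |A union B|` (0 when both are empty).
#' @export
jaccard <- function(a, b) {
  pa <- unique(if (inherits(a, "immunopeptidome")) a$peptides else a)
  pb <- unique(if (inherits(b, "immunopeptidome")) b$peptides else b)
  u <- length(union(pa, pb))
  if (u == 0L) return(0)
  length(intersect(pa, pb)) / u
}

#' Per-sample source-gene summary with sharing counts
#'
#' A source gene generating several unique peptides in a sample is
#' counted once for that sample; `shared_by` counts the samples in
#' which the gene appears, supporting shared-by-at-least-`n` selection
#' rules. Peptides without a gene mapping are pooled under
#' `"unannotated"`.
#'
#' @param peptidomes List of `immunopeptidome` objects.
#' @param gene_map Data frame with columns `peptide`, `gene`.
#' @param min_shared Sharing threshold for the `selected` flag.
#' @return Data frame: `gene`, one peptide-count column per sample,
#'   `shared_by`, `selected`.
#' @export
source_gene_summary <- function(peptidomes, gene_map, min_shared = 4L) {
  if (!length(peptidomes)) {
    return(data.frame(gene = character(0), shared_by = integer(0),
                      selected = logical(0), stringsAsFactors = FALSE))
  }
  per_sample <- lapply(peptidomes, function(p) {
    g <- gene_map$gene[match(p$peptides, gene_map$peptide)]
    g[is.na(g)] <- "unannotated"
    tab <- table(g)
    stats::setNames(as.integer(tab), names(tab))
  })
  names(per_sample) <- vapply(peptidomes, `[[`, character(1), "sample_id")
  genes <- sort(unique(unlist(lapply(per_sample, names))))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (s in names(per_sample)) {
    v <- per_sample[[s]][genes]
    v[is.na(v)] <- 0L
    out[[s]] <- as.integer(v)
  }
  counts <- as.matrix(out[, names(per_sample), drop = FALSE])
  out$shared_by <- as.integer(rowSums(counts > 0L))
  out$selected <- out$shared_by >= min_shared
  out
}
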