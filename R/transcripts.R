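# Transcript model coordinate arithmetic. A transcript model is a plain
# list: transcript_id, gene_id, biotype, chrom, strand, exons (integer
# matrix, columns start0/end0, 0-based half-open, rows in ascending
# genomic order) and cds (optional c(start0, end0) in spliced
# coordinates). Spliced coordinates run 5' to 3' along the transcript.

# exons in transcript (5'->3') order
.tx_chunks <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  ord <- if (tx$strand == "+") seq_len(n) else rev(seq_len(n))
  ex[ord, , drop = FALSE]
}

#' Spliced length of a transcript model
#' @param tx A transcript model list.
#' @return Integer length in nucleotides.
#' @export
spliced_length <- function(tx) {
  sum(tx$exons[, 2] - tx$exons[, 1])
}

# genomic span c(start0, end0)
.tx_span <- function(tx) {
  c(min(tx$exons[, 1]), max(tx$exons[, 2]))
}

#' Spliced (mature) sequence of a transcript
#'
#' @param tx A transcript model list.
#' @param genome A `toy_genome` (or named character vector of
#'   chromosome sequences).
#' @return The sense-strand spliced sequence.
#' @export
spliced_seq <- function(tx, genome) {
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes else genome
  s <- chroms[[tx$chrom]]
  ch <- .tx_chunks(tx)
  parts <- character(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    sub <- substr(s, ch[i, 1] + 1L, ch[i, 2])
    parts[i] <- if (tx$strand == "+") sub else revcomp(sub)
  }
  paste(parts, collapse = "")
}

#' Project a spliced interval onto the genome
#'
#' @param tx A transcript model list.
#' @param s,e Spliced interval, 0-based half-open.
#' @return Integer matrix of genomic blocks (columns start0/end0),
#'   ascending.
#' @export
genomic_blocks <- function(tx, s, e) {
  stopifnot(s >= 0, e > s, e <= spliced_length(tx))
  ch <- .tx_chunks(tx)
  lens <- ch[, 2] - ch[, 1]
  cum <- c(0L, cumsum(lens))
  blocks <- list()
  for (i in seq_len(nrow(ch))) {
    os <- max(s, cum[i])
    oe <- min(e, cum[i + 1L])
    if (os >= oe) next
    if (tx$strand == "+") {
      gs <- ch[i, 1] + (os - cum[i])
      ge <- ch[i, 1] + (oe - cum[i])
    } else {
      ge <- ch[i, 2] - (os - cum[i])
      gs <- ch[i, 2] - (oe - cum[i])
    }
    blocks[[length(blocks) + 1L]] <- c(gs, ge)
  }
  m <- do.call(rbind, blocks)
  m <- m[order(m[, 1]), , drop = FALSE]
  colnames(m) <- c("start0", "end0")
  m
}

#' Map a genomic position into spliced coordinates
#'
#' @param tx A transcript model list.
#' @param gpos 0-based genomic position.
#' @return Spliced 0-based position, or `NA` if intronic/outside.
#' @export
genomic_to_spliced <- function(tx, gpos) {
  ch <- .tx_chunks(tx)
  lens <- ch[, 2] - ch[, 1]
  cum <- c(0L, cumsum(lens))
  for (i in seq_len(nrow(ch))) {
    if (gpos >= ch[i, 1] && gpos < ch[i, 2]) {
      off <- if (tx$strand == "+") gpos - ch[i, 1] else ch[i, 2] - 1L - gpos
      return(cum[i] + off)
    }
  }
  NA_integer_
}

# overwrite a spliced interval (must lie within one exon) with `nt`;
# returns the modified chromosome string
.write_spliced <- function(chromseq, tx, s, nt) {
  b <- genomic_blocks(tx, s, s + nchar(nt))
  if (nrow(b) != 1L) stop("interval crosses an exon junction")
  value <- if (tx$strand == "+") nt else revcomp(nt)
  substr(chromseq, b[1, 1] + 1L, b[1, 2]) <- value
  chromseq
}

# transcripts whose exon span overlaps [start0, end0) on `chrom`
.overlapping_transcripts <- function(annotation, chrom, start0, end0,
                                     strand = NULL) {
  keep <- vapply(annotation, function(tx) {
    if (tx$chrom != chrom) return(FALSE)
    if (!is.null(strand) && tx$strand != strand) return(FALSE)
    sp <- .tx_span(tx)
    start0 < sp[2] && end0 > sp[1]
  }, logical(1))
  annotation[keep]
}
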