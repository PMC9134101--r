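# MAP-coding-sequence handling: reverse translation, exact genomic and
# transcriptomic placement, and RPHM/KPHM quantification in RNA-seq
# read sets.

#' Reverse-translate a peptide into its coding sequences
#'
#' Returns an IUPAC-degenerate codon string (one minimal degenerate
#' codon per residue), the exact number of distinct coding sequences
#' (the product of the per-residue codon degeneracies), and the
#' explicit enumeration when that number does not exceed
#' `max_enumeration`. Note the degenerate string is a positionwise
#' superset of the true coding-sequence set (e.g. `YTN` for Leu also
#' covers `TTC`), so matches against it must be verified by
#' translation — [map_mcs()] does this.
#'
#' @param peptide Amino acid sequence over the standard 20-letter
#'   alphabet.
#' @param max_enumeration Enumeration cap; set to 0 to skip
#'   enumeration entirely.
#' @return List with `peptide`, `degenerate`, `n_sequences`,
#'   `sequences` (sorted character vector or `NULL`).
#' @export
reverse_translate <- function(peptide, max_enumeration = 1e5) {
  res <- strsplit(peptide, "")[[1]]
  if (!length(res) || !all(res %in% AA20)) {
    stop("peptide must be a non-empty string over the 20 standard residues")
  }
  cods <- lapply(res, aa_codons)
  n <- prod(lengths(cods))
  seqs <- NULL
  if (n <= max_enumeration && max_enumeration > 0) {
    seqs <- sort(Reduce(function(a, b) as.vector(outer(a, b, paste0)), cods))
  }
  list(
    peptide = peptide,
    degenerate = paste(vapply(res, degenerate_codon, character(1)),
                       collapse = ""),
    n_sequences = n,
    sequences = seqs
  )
}

# scan one DNA subject (character) with a degenerate pattern; returns
# 0-based start positions of matches whose translation equals `peptide`
.scan_degenerate <- function(pattern, subject_dna, peptide,
                             rc = FALSE) {
  pat <- Biostrings::DNAString(if (rc) revcomp(pattern) else pattern)
  m <- Biostrings::matchPattern(pat, subject_dna,
                                fixed = c(pattern = FALSE, subject = TRUE))
  if (!length(m)) return(list(starts = integer(0), mcs = character(0)))
  seqs <- as.character(m)
  if (rc) seqs <- revcomp(seqs)
  ok <- translate_nt(seqs) == peptide
  list(starts = Biostrings::start(m)[ok] - 1L, mcs = seqs[ok])
}

#' Locate all exact placements of a peptide's coding sequences
#'
#' Scans both strands of every chromosome and the spliced sequence of
#' every annotated transcript with the peptide's degenerate
#' reverse-translation pattern, verifying each match by translation
#' (equivalent to enumerating all coding sequences, with bounded
#' memory). Transcript hits that cross an exon junction are reported
#' as spliced hits with their genomic blocks; hits contained in a
#' single exon coincide with genomic hits and are not duplicated.
#'
#' @param peptide Amino acid sequence.
#' @param genome A `toy_genome` (tumor or reference).
#' @param annotation Transcript models; defaults to
#'   `genome$annotation`.
#' @return Data frame of hits: `peptide`, `mcs`, `chrom`, `start0`,
#'   `end0`, `strand`, `spliced`, `transcript_id`, `sp_start0`, and a
#'   `blocks` list column of genomic block matrices. Sorted by
#'   (chrom, start0); empty when the peptide has no perfect placement.
#' @export
map_mcs <- function(peptide, genome, annotation = NULL) {
  annotation <- annotation %||% genome$annotation
  pattern <- reverse_translate(peptide, max_enumeration = 0)$degenerate
  rows <- list()
  add <- function(mcs, chrom, start0, end0, strand, spliced = FALSE,
                  transcript_id = NA_character_, sp_start0 = NA_integer_,
                  blocks = NULL) {
    rows[[length(rows) + 1L]] <<- list(
      peptide = peptide, mcs = mcs, chrom = chrom,
      start0 = as.integer(start0), end0 = as.integer(end0),
      strand = strand, spliced = spliced, transcript_id = transcript_id,
      sp_start0 = sp_start0,
      blocks = blocks %||% matrix(c(start0, end0), 1L, 2L,
                                  dimnames = list(NULL, c("start0", "end0")))
    )
  }
  w <- nchar(pattern)
  for (chrom in names(genome$chromosomes)) {
    subj <- Biostrings::DNAString(genome$chromosomes[[chrom]])
    fw <- .scan_degenerate(pattern, subj, peptide, rc = FALSE)
    for (i in seq_along(fw$starts)) {
      add(fw$mcs[i], chrom, fw$starts[i], fw$starts[i] + w, "+")
    }
    rv <- .scan_degenerate(pattern, subj, peptide, rc = TRUE)
    for (i in seq_along(rv$starts)) {
      add(rv$mcs[i], chrom, rv$starts[i], rv$starts[i] + w, "-")
    }
  }
  for (tx in annotation) {
    sp <- spliced_seq(tx, genome)
    if (nchar(sp) < w) next
    hit <- .scan_degenerate(pattern, Biostrings::DNAString(sp), peptide)
    for (i in seq_along(hit$starts)) {
      s <- hit$starts[i]
      b <- genomic_blocks(tx, s, s + w)
      if (nrow(b) == 1L) next  # single-exon hit: already found genomically
      add(hit$mcs[i], tx$chrom, b[1, 1], b[nrow(b), 2], tx$strand,
          spliced = TRUE, transcript_id = tx$transcript_id,
          sp_start0 = s, blocks = b)
    }
  }
  if (!length(rows)) {
    return(data.frame(
      peptide = character(0), mcs = character(0), chrom = character(0),
      start0 = integer(0), end0 = integer(0), strand = character(0),
      spliced = logical(0), transcript_id = character(0),
      sp_start0 = integer(0), blocks = I(list()),
      stringsAsFactors = FALSE
    ))
  }
  df <- data.frame(
    peptide = vapply(rows, `[[`, character(1), "peptide"),
    mcs = vapply(rows, `[[`, character(1), "mcs"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start0 = vapply(rows, `[[`, integer(1), "start0"),
    end0 = vapply(rows, `[[`, integer(1), "end0"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    spliced = vapply(rows, `[[`, logical(1), "spliced"),
    transcript_id = vapply(rows, `[[`, character(1), "transcript_id"),
    sp_start0 = vapply(rows, `[[`, integer(1), "sp_start0"),
    stringsAsFactors = FALSE
  )
  df$blocks <- I(lapply(rows, `[[`, "blocks"))
  key <- paste(df$chrom, df$start0, df$end0, df$strand, df$mcs)
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$chrom, df$start0), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read-containment quantification (RPHM)
#'
#' Counts reads that fully contain any of the peptide's located coding
#' sequences as an exact substring (sense orientation; the reverse
#' complement is also checked for unstranded read sets) and normalizes
#' per 10^8 reads sequenced.
#'
#' @param peptide Amino acid sequence (carried through).
#' @param hits [map_mcs()] output, or a character vector of coding
#'   sequences.
#' @param readset A `read_set`.
#' @return List with `read_count` and `rphm`.
#' @export
rphm_quantify <- function(peptide, hits, readset) {
  if (readset$total_reads == 0) {
    stop("RPHM undefined: read set has total_reads = 0")
  }
  mcs <- unique(if (is.data.frame(hits)) hits$mcs else hits)
  contains <- rep(FALSE, length(readset$reads))
  for (m in mcs) {
    contains <- contains | grepl(m, readset$reads, fixed = TRUE)
    if (!readset$stranded) {
      contains <- contains | grepl(revcomp(m), readset$reads, fixed = TRUE)
    }
  }
  count <- sum(contains)
  list(read_count = count, rphm = count * 1e8 / readset$total_reads)
}

#' Minimum k-mer occurrence quantification (KPHM)
#'
#' For each coding sequence, looks up all its 24-nt sliding windows in
#' a canonical 24-mer set and takes the minimum occurrence (`kmin`;
#' absent k-mers count 0) — an estimate of the number of reads fully
#' overlapping the coding sequence, since a k-mer originates from a
#' single read. The reported coding sequence is by default the most
#' expressed one (the argmax of `kmin`, ties broken lexicographically);
#' `mode = "single"` requires a single coding sequence. KPHM is
#' `kmin * 1e8 / rtot` exactly.
#'
#' @param peptide Amino acid sequence (carried through).
#' @param mcs_set Character vector of coding sequences (each >= 24 nt).
#' @param kmer24 A canonical `kmer_set` with `k = 24`.
#' @param mode `"max"` or `"single"`.
#' @return List with `kmin`, `kphm`, `mcs` (the coding sequence used).
#' @export
kphm_quantify <- function(peptide, mcs_set, kmer24,
                          mode = c("max", "single")) {
  mode <- match.arg(mode)
  if (kmer24$k != 24L || !kmer24$canonical) {
    stop("kmer24 must be a canonical 24-mer set")
  }
  mcs_set <- unique(mcs_set)
  if (!length(mcs_set)) stop("empty coding-sequence set")
  if (any(nchar(mcs_set) < 24L)) {
    stop("coding sequences must be at least 24 nt")
  }
  if (mode == "single" && length(mcs_set) != 1L) {
    stop("mode = 'single' requires exactly one coding sequence")
  }
  kmin_of <- function(m) {
    n <- nchar(m)
    wins <- substring(m, 1:(n - 23L), 24:n)
    cnt <- unname(kmer24$counts[canonical_kmer(wins)])
    cnt[is.na(cnt)] <- 0L
    min(cnt)
  }
  mcs_set <- sort(mcs_set)
  kmins <- vapply(mcs_set, kmin_of, numeric(1))
  i <- which.max(kmins)  # first max = lexicographically smallest tie
  list(kmin = as.numeric(kmins[i]),
       kphm = kmins[[i]] * 1e8 / kmer24$rtot,
       mcs = mcs_set[i])
}
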