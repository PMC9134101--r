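# Shared sequence helpers. Biostrings does the heavy lifting for
# translation, reverse complementation and degenerate matching; these
# wrappers keep the rest of the package working on plain character
# vectors.

`%||%` <- function(a, b) if (is.null(a)) b else a

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a random DNA sequence
#'
#' @param n Sequence length in nucleotides.
#' @return A single uppercase ACGT string.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Accepts IUPAC ambiguity codes (used for degenerate codon patterns).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate DNA in frame 0
#'
#' Trailing partial codons are trimmed; stop codons appear as `*`.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of amino acid strings (standard code).
#' @export
translate_nt <- function(x) {
  if (length(x) == 0L) return(character(0))
  n <- (nchar(x) %/% 3L) * 3L
  x <- substr(x, 1L, n)
  out <- character(length(x))
  ok <- n >= 3L
  if (any(ok)) {
    out[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(x[ok]),
      no.init.codon = TRUE
    ))
  }
  out
}

# codons coding each amino acid (standard table 1)
aa_codons <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  cods <- names(gc)[gc == aa]
  if (length(cods) == 0L) stop("unknown residue: ", aa)
  sort(cods)
}

.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
}

.IUPAC_FROM_SET <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

# minimal IUPAC degenerate codon covering all codons of one residue
degenerate_codon <- function(aa) {
  cods <- aa_codons(aa)
  m <- do.call(rbind, strsplit(cods, ""))
  code <- vapply(1:3, function(i) {
    .IUPAC_FROM_SET[[paste(sort(unique(m[, i])), collapse = "")]]
  }, character(1))
  paste(code, collapse = "")
}

# all k-length windows of a set of sequences (shorter sequences skipped)
sliding_kmers <- function(seqs, k) {
  if (length(seqs) == 0L) return(character(0))
  lens <- nchar(seqs)
  out <- list()
  for (len in sort(unique(lens))) {
    if (len < k) next
    ss <- seqs[lens == len]
    win <- vector("list", len - k + 1L)
    for (i in seq_len(len - k + 1L)) win[[i]] <- substr(ss, i, i + k - 1L)
    out[[length(out) + 1L]] <- unlist(win, use.names = FALSE)
  }
  if (length(out) == 0L) return(character(0))
  unlist(out, use.names = FALSE)
}

#' Canonical form of k-mers
#'
#' The lexicographic minimum of each k-mer and its reverse complement
#' (the key under which canonical k-mer sets store counts).
#'
#' @param x Character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  if (length(x) == 0L) return(character(0))
  pmin(x, revcomp(x))
}

# fixed-pattern occurrence count on both strands of a chromosome set
.count_occurrences <- function(pattern, chromosomes) {
  n <- 0L
  for (s in chromosomes) {
    subj <- Biostrings::DNAString(s)
    n <- n + Biostrings::countPattern(pattern, subj) +
      Biostrings::countPattern(revcomp(pattern), subj)
  }
  n
}
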