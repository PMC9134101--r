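# Independent brute-force oracles. These deliberately avoid the
# package's code paths (and Biostrings): hand-coded codon table,
# character-level loops, exhaustive scans.

# standard genetic code, codons enumerated in T/C/A/G order
.oracle_code <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  codons <- character(64)
  i <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1L
    codons[i] <- paste0(b1, b2, b3)
  }
  stats::setNames(aa, codons)
})

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  paste(vapply(seq_len(n), function(i)
    .oracle_code[[substr(nt, 3L * i - 2L, 3L * i)]], character(1)),
    collapse = "")
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# naive dictionary k-mer counting
oracle_count_kmers <- function(reads, k, canonical = FALSE) {
  env <- new.env(parent = emptyenv())
  for (r in reads) {
    if (nchar(r) < k) next
    for (i in seq_len(nchar(r) - k + 1L)) {
      km <- substr(r, i, i + k - 1L)
      if (grepl("[^ACGT]", km)) next
      if (canonical) {
        rc <- oracle_revcomp(km)
        if (rc < km) km <- rc
      }
      env[[km]] <- (env[[km]] %||% 0L) + 1L
    }
  }
  keys <- ls(env)
  stats::setNames(vapply(keys, function(k2) env[[k2]], integer(1)), keys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force subtraction by set comprehension
oracle_subtract <- function(tumor_counts, normal_counts_list,
                            max_count = 2L) {
  keep <- vapply(names(tumor_counts), function(km) {
    tot <- 0L
    for (nc in normal_counts_list) {
      v <- unname(nc[km])
      if (!is.na(v)) tot <- tot + v
    }
    tot < max_count
  }, logical(1))
  tumor_counts[keep]
}

# exhaustive scan over all candidate FDR thresholds
oracle_fdr <- function(records, fdr = 0.05) {
  targets <- records[!records$is_decoy, , drop = FALSE]
  best <- NULL
  for (t in sort(unique(records$score))) {
    nt <- sum(targets$score >= t)
    nd <- sum(records$score >= t & records$is_decoy)
    if (nt > 0L && nd / nt <= fdr) {
      best <- t
      break
    }
  }
  if (is.null(best)) return(targets[0, , drop = FALSE])
  targets[targets$score >= best, , drop = FALSE]
}

# number of coding sequences = product of per-residue codon counts
oracle_rt_count <- function(pep) {
  prod(vapply(strsplit(pep, "")[[1]], function(a)
    sum(.oracle_code == a), numeric(1)))
}

# explicit enumeration of all coding sequences of a peptide
oracle_rt_enumerate <- function(pep) {
  cods <- lapply(strsplit(pep, "")[[1]], function(a)
    names(.oracle_code)[.oracle_code == a])
  sort(Reduce(function(x, y) as.vector(outer(x, y, paste0)), cods))
}

random_read <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

# hand-built two-exon gene on a tiny chromosome, for junction and
# region tests: exon1 [100,160), intron, exon2 [400,460), '+' strand,
# CDS spliced [30, 90)
make_junction_genome <- function(seed = 42) {
  set.seed(seed)
  chrom <- random_read(600)
  cds_nt <- paste0(
    "ATG",
    paste(sample(names(.oracle_code)[.oracle_code != "*"],
                 18L, replace = TRUE), collapse = ""),
    "TAA"
  )  # 60 nt
  # spliced layout: UTR5 30 + CDS 60 + UTR3 30 = 120 nt over two exons
  spliced <- paste0(random_read(30), cds_nt, random_read(30))
  tx <- list(
    transcript_id = "JTX1", gene_id = "JG1",
    biotype = "protein_coding", chrom = "chrJ", strand = "+",
    exons = matrix(c(100L, 160L, 400L, 460L), 2L, 2L, byrow = TRUE,
                   dimnames = list(NULL, c("start0", "end0"))),
    cds = c(30L, 90L)
  )
  substr(chrom, 101, 160) <- substr(spliced, 1, 60)
  substr(chrom, 401, 460) <- substr(spliced, 61, 120)
  structure(
    list(
      chromosomes = c(chrJ = chrom),
      annotation = list(tx),
      germline_snps = data.frame(chrom = character(0), pos0 = integer(0),
                                 ref = character(0), alt = character(0),
                                 stringsAsFactors = FALSE)
    ),
    class = "toy_genome"
  )
}
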