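# Plain-text I/O: FASTA/FASTQ/GTF/TSV writers for synthetic studies,
# k-mer set persistence, and the bundled validated-antigen dataset.

#' Write a proteome database as FASTA
#'
#' @param db A `proteome_db` (or data frame with header/seq).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(db, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(db$seq, db$header))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Persist a k-mer set as TSV
#'
#' Sorted two-column table (kmer, count) under a one-line header
#' carrying k, the canonical flag and the library total.
#'
#' @param ks A `kmer_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_kmer_tsv <- function(ks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k=%d\tcanonical=%s\trtot=%.0f", ks$k,
                     ks$canonical, ks$rtot), con)
  keys <- sort(names(ks$counts))
  writeLines(sprintf("%s\t%d", keys, as.integer(ks$counts[keys])), con)
  invisible(path)
}

#' Read a k-mer set written by [write_kmer_tsv()]
#'
#' @param path Input file.
#' @return A `kmer_set`.
#' @export
read_kmer_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  fields <- strsplit(sub("^#", "", header), "\t")[[1]]
  kv <- strsplit(fields, "=")
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  df <- utils::read.table(path, skip = 1L, sep = "\t", col.names =
                            c("kmer", "count"), colClasses = c("character", "integer"))
  .kmer_set(as.integer(vals[["k"]]),
            stats::setNames(df$count, df$kmer),
            as.numeric(vals[["rtot"]]),
            as.logical(vals[["canonical"]]))
}

#' Write a read set as FASTQ
#'
#' Dummy maximal qualities ('I'), one record per read.
#'
#' @param readset A `read_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(readset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  r <- readset$reads
  if (length(r)) {
    writeLines(paste0("@", readset$sample_id, "_", seq_along(r), "\n",
                      r, "\n+\n",
                      vapply(nchar(r), function(n)
                        strrep("I", n), character(1))), con)
  }
  invisible(path)
}

#' Write a toy study to plain-text files
#'
#' Genome FASTA, minimal GTF and flat exon TSV, per-sample FASTQ, and
#' the ground truth as TSV (and JSON when jsonlite is installed).
#'
#' @param study Output of [toy_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- study$tumor_genome
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(g$chromosomes),
    file.path(dir, "tumor_genome.fa"), width = 60L
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(study$reference$chromosomes),
    file.path(dir, "reference_genome.fa"), width = 60L
  )
  # minimal GTF (exon features, 1-based closed) + flat exon TSV
  gtf <- file(file.path(dir, "annotation.gtf"), "w")
  exon_rows <- list()
  for (tx in g$annotation) {
    for (i in seq_len(nrow(tx$exons))) {
      writeLines(sprintf(
        "%s\ttsascan\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; biotype \"%s\";",
        tx$chrom, tx$exons[i, 1] + 1L, tx$exons[i, 2], tx$strand,
        tx$gene_id, tx$transcript_id, tx$biotype), gtf)
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        transcript_id = tx$transcript_id, gene_id = tx$gene_id,
        biotype = tx$biotype, chrom = tx$chrom, strand = tx$strand,
        exon = i, start0 = tx$exons[i, 1], end0 = tx$exons[i, 2],
        cds_start0 = if (is.null(tx$cds)) NA_integer_ else tx$cds[1],
        cds_end0 = if (is.null(tx$cds)) NA_integer_ else tx$cds[2],
        stringsAsFactors = FALSE
      )
    }
  }
  close(gtf)
  utils::write.table(do.call(rbind, exon_rows),
                     file.path(dir, "exons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in names(study$readsets)) {
    write_fastq(study$readsets[[s]], file.path(dir, paste0(s, ".fastq")))
  }
  utils::write.table(study$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                         dataframe = "rows", na = "null")
  }
  utils::write.table(study$idents, file.path(dir, "identifications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Bundled validated tumor antigens of a colorectal cancer study
#'
#' A curated table of validated tumor antigens from one colorectal
#' cancer immunopeptidomics study (four CRC cell lines and six matched
#' tumor/NAT tissue pairs): peptide sequence, antigen class (aeTSA,
#' mTSA, canonical/noncanonical TAA, or not assigned), sample,
#' endogenous tumor/NAT log-ratio, mean reporter intensity, SPS-MS3
#' 127N/126 intensity ratio (NA where not detected) and the synthetic
#' calibration-curve R^2.
#'
#' @return Data frame of antigen records.
#' @export
load_validated_antigens <- function() {
  utils::read.table(
    system.file("extdata", "validated_antigens.tsv", package = "tsascan",
                mustWork = TRUE),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE
  )
}

#' Bundled sample metadata for the validated-antigen table
#'
#' Sample type (cell line or tissue) and microsatellite status
#' (MSI/MSS) for each tumor sample.
#'
#' @return Data frame with sample_id, sample_type, msi_status.
#' @export
load_sample_metadata <- function() {
  utils::read.table(
    system.file("extdata", "sample_metadata.tsv", package = "tsascan",
                mustWork = TRUE),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE
  )
}

#' Tally a validated-antigen table
#'
#' Summary statistics over an antigen call table: total TSA calls
#' (aeTSA + mTSA rows), TSA calls in tissue samples, unique TSA
#' sequences with a successful SPS-MS3 quantification, aeTSA calls in
#' microsatellite-stable tissues, and the mean number of TSA calls per
#' tissue sample.
#'
#' @param antigens Data frame as returned by
#'   [load_validated_antigens()].
#' @param metadata Data frame as returned by
#'   [load_sample_metadata()].
#' @return Named list of tallies.
#' @export
antigen_tally <- function(antigens = load_validated_antigens(),
                          metadata = load_sample_metadata()) {
  is_tsa <- antigens$antigen_class %in% c("aeTSA", "mTSA")
  stype <- metadata$sample_type[match(antigens$sample_id,
                                      metadata$sample_id)]
  msi <- metadata$msi_status[match(antigens$sample_id,
                                   metadata$sample_id)]
  tissue <- stype == "tissue"
  n_tissues <- sum(metadata$sample_type == "tissue")
  list(
    total_tsas = sum(is_tsa),
    tissue_tsas = sum(is_tsa & tissue),
    quantified_tsas = length(unique(
      antigens$peptide[is_tsa & !is.na(antigens$sps_ms3_ratio)])),
    mss_tissue_aetsas = sum(antigens$antigen_class == "aeTSA" &
                              tissue & msi == "MSS"),
    mean_tsas_per_tissue = sum(is_tsa & tissue) / n_tissues
  )
}
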