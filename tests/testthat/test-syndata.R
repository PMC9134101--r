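test_that("toy genomes are deterministic, seed-sensitive and well-formed", {
  g1 <- make_toy_genome(1, n_chrom = 2, chrom_len = 50000, n_genes = 6)
  g2 <- make_toy_genome(1, n_chrom = 2, chrom_len = 50000, n_genes = 6)
  g3 <- make_toy_genome(2, n_chrom = 2, chrom_len = 50000, n_genes = 6)
  expect_identical(g1$chromosomes, g2$chromosomes)
  expect_identical(g1$annotation, g2$annotation)
  expect_false(identical(g1$chromosomes, g3$chromosomes))
  expect_true(all(grepl("^[ACGT]+$", g1$chromosomes)))
  expect_gte(length(g1$annotation), 6)

  for (tx in g1$annotation) {
    ex <- tx$exons
    expect_true(all(ex[, 1] < ex[, 2]))
    expect_true(all(ex[, 2] <= nchar(g1$chromosomes[[tx$chrom]])))
    if (nrow(ex) > 1) expect_true(all(ex[-1, 1] >= ex[-nrow(ex), 2]))
    if (!is.null(tx$cds)) {
      expect_equal((tx$cds[2] - tx$cds[1]) %% 3, 0)
      # CDS translates stop-free (independent codon-table oracle)
      cds_nt <- substr(spliced_seq(tx, g1), tx$cds[1] + 1, tx$cds[2])
      aa <- oracle_translate(cds_nt)
      expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
      expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
      expect_equal(substr(aa, 1, 1), "M")
    }
  }
  expect_error(make_toy_genome(1, chrom_len = 5000), "10,000")
  expect_error(make_toy_genome(1, chrom_len = 50000, n_genes = 40),
               "too short")
})

test_that("planted events are encoded once, with recorded truth", {
  g <- make_toy_genome(3, n_genes = 6)
  pl <- plant_events(g, c("aeTSA_intergenic", "mTSA_snv"), seed = 7)
  expect_equal(nrow(pl$truth), 2)

  inter <- pl$truth[pl$truth$kind == "aeTSA_intergenic", ]
  expect_equal(nchar(inter$peptide), 9)
  expect_equal(nchar(inter$mcs), 27)
  # the coding sequence occurs exactly once (substring-search oracle,
  # both strands)
  hits <- 0L
  for (chrom in pl$genome$chromosomes) {
    hits <- hits + lengths(regmatches(chrom, gregexpr(inter$mcs, chrom, fixed = TRUE))) +
      lengths(regmatches(chrom, gregexpr(oracle_revcomp(inter$mcs), chrom, fixed = TRUE)))
  }
  expect_equal(hits, 1L)
  expect_equal(oracle_translate(inter$mcs), inter$peptide)
  # aeTSA loci are shared by reference and tumor genome
  expect_identical(
    substr(pl$reference$chromosomes[[inter$chrom]], inter$start0 + 1, inter$end0),
    substr(pl$genome$chromosomes[[inter$chrom]], inter$start0 + 1, inter$end0)
  )

  snv <- pl$truth[pl$truth$kind == "mTSA_snv", ]
  ref_chrom <- pl$reference$chromosomes[[snv$chrom]]
  tum_chrom <- pl$genome$chromosomes[[snv$chrom]]
  ref_nt <- substr(ref_chrom, snv$start0 + 1, snv$end0)
  tum_nt <- substr(tum_chrom, snv$start0 + 1, snv$end0)
  if (snv$strand == "-") {
    ref_nt <- oracle_revcomp(ref_nt)
    tum_nt <- oracle_revcomp(tum_nt)
  }
  # tumor-allele translation differs at exactly one residue
  ref_aa <- strsplit(oracle_translate(ref_nt), "")[[1]]
  tum_aa <- strsplit(oracle_translate(tum_nt), "")[[1]]
  expect_equal(sum(ref_aa != tum_aa), 1)
  expect_equal(oracle_translate(tum_nt), snv$peptide)
  # exactly one genomic base differs, at the recorded position
  d <- which(strsplit(ref_chrom, "")[[1]] != strsplit(tum_chrom, "")[[1]])
  expect_equal(d - 1L, snv$snv_pos0)
  expect_equal(substr(tum_chrom, d, d), snv$snv_alt)
  expect_equal(substr(ref_chrom, d, d), snv$snv_ref)

  empty <- plant_events(g, event_requests(character(0)), seed = 7)
  expect_identical(empty$genome, g)
  expect_equal(nrow(empty$truth), 0)
})

test_that("aeTSA depth invariants are enforced", {
  req <- event_requests("aeTSA_intron")
  req$normal_depth <- 5
  g <- make_toy_genome(4, n_genes = 6)
  expect_error(plant_events(g, req, 1), "aeTSA")
  req2 <- event_requests("TAA_overexpressed")
  req2$normal_depth <- 5  # tumor 20 < 10 x 5
  expect_error(plant_events(g, req2, 1), "10 x|10 x normal|>= 10",
               fixed = FALSE)
})

test_that("simulated reads match the requested coverage", {
  g <- make_toy_genome(5, n_genes = 6)
  tx <- g$annotation[[1]]
  L <- spliced_length(tx)
  prof <- stats::setNames(10, tx$transcript_id)
  rs <- simulate_reads(g, prof, read_len = 75, seed = 1)
  expect_equal(length(rs$reads), round(10 * L / 75))
  expect_true(all(nchar(rs$reads) == 75))
  expect_equal(rs$total_reads, length(rs$reads))
  # all reads are substrings of the spliced sense sequence
  sp <- spliced_seq(tx, g)
  expect_true(all(vapply(rs$reads[1:20], function(r)
    grepl(r, sp, fixed = TRUE), logical(1))))

  rs0 <- simulate_reads(g, stats::setNames(0, tx$transcript_id),
                        read_len = 75, seed = 1)
  expect_equal(rs0$total_reads, 0)

  # planted aeTSA contributes nothing to a normal read set
  pl <- plant_events(g, "aeTSA_intergenic", seed = 2)
  normal <- simulate_reads(pl$reference, prof, read_len = 75, seed = 3)
  k24 <- count_kmers(normal, 24, canonical = TRUE)
  wins <- substring(pl$truth$mcs, 1:4, 24:27)
  expect_true(all(is.na(k24$counts[canonical_kmer(wins)])))
})

test_that("simulated identifications exercise the downstream filters", {
  g <- make_toy_genome(6, n_genes = 6)
  pl <- plant_events(g, c("aeTSA_intergenic", "aeTSA_intron", "mTSA_snv"),
                     seed = 1)
  prot <- canonical_proteome(g)
  ids <- simulate_identifications(pl$truth, prot, n_targets = 30,
                                  n_decoys = 15, seed = 1)
  targets <- ids[!ids$is_decoy, ]
  expect_true(all(pl$truth$peptide %in% targets$peptide))
  planted <- targets[targets$peptide %in% pl$truth$peptide, ]
  expect_true(all(planted$percent_rank <= 2))
  expect_gt(mean(targets$score), mean(ids$score[ids$is_decoy]))
  expect_true(all(nchar(targets$peptide) >= 7 & nchar(targets$peptide) <= 13))
  # n_decoys = 0: FDR undefined, everything returned under a warning
  ids0 <- simulate_identifications(pl$truth, prot, n_targets = 10,
                                   n_decoys = 0, seed = 1)
  expect_warning(kept <- fdr_filter(ids0, 0.05), "decoy")
  expect_equal(nrow(kept), 10)
  expect_error(simulate_identifications(pl$truth, prot, n_targets = 2,
                                        n_decoys = 0, seed = 1),
               "n_targets")
})
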