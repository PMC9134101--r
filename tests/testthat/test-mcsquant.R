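test_that("reverse translation counts and enumerates coding sequences", {
  mw <- reverse_translate("MW")
  expect_equal(mw$n_sequences, 1)
  expect_equal(mw$sequences, "ATGTGG")
  expect_equal(mw$degenerate, "ATGTGG")

  expect_equal(reverse_translate("KK")$n_sequences, 4)  # AAA/AAG each

  mkw <- reverse_translate("MKW")
  expect_equal(mkw$n_sequences, 2)
  expect_setequal(mkw$sequences, c("ATGAAATGG", "ATGAAGTGG"))

  expect_error(reverse_translate("MXK"), "residue")
  expect_error(reverse_translate("MJK"), "residue")

  set.seed(31)
  for (i in 1:50) {
    pep <- paste(sample(AA20, sample(2:4, 1), replace = TRUE),
                 collapse = "")
    rt <- reverse_translate(pep, max_enumeration = 1e4)
    expect_equal(rt$n_sequences, oracle_rt_count(pep))
    if (!is.null(rt$sequences)) {
      expect_equal(rt$sequences, oracle_rt_enumerate(pep))
      expect_equal(length(rt$sequences), rt$n_sequences)
    }
  }
  # enumeration is suppressed above the cap but the count stays exact
  ll <- reverse_translate("LLLLLLLL", max_enumeration = 10)
  expect_null(ll$sequences)
  expect_equal(ll$n_sequences, 6^8)
})

test_that("coding sequences are located exactly, including spliced hits", {
  g <- make_toy_genome(33, n_genes = 6)
  pl <- plant_events(g, c("aeTSA_intergenic", "aeTSA_intron"), seed = 2)
  for (i in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[i, ]
    hits <- map_mcs(tr$peptide, pl$genome)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$chrom, tr$chrom)
    expect_equal(hits$start0, tr$start0)
    expect_equal(hits$end0, tr$end0)
    expect_equal(hits$strand, tr$strand)
    expect_false(hits$spliced)
    expect_equal(hits$mcs, tr$mcs)
  }

  # a peptide absent from the genome yields no hits
  expect_equal(nrow(map_mcs("WWWWWWWW", g)), 0)

  # junction-spanning peptide: one spliced hit with two genomic blocks
  jg <- make_junction_genome()
  tx <- jg$annotation[[1]]
  sp <- spliced_seq(tx, jg)
  # codon-aligned 27-nt window crossing the exon boundary at spliced 60
  pep <- oracle_translate(substr(sp, 46, 72))
  expect_equal(nchar(pep), 9)
  hits <- map_mcs(pep, jg)
  spl <- hits[hits$spliced, ]
  expect_equal(nrow(spl), 1)
  expect_equal(spl$transcript_id, "JTX1")
  expect_equal(nrow(spl$blocks[[1]]), 2)
  expect_equal(spl$mcs, substr(sp, 46, 72))
  expect_equal(sum(spl$blocks[[1]][, 2] - spl$blocks[[1]][, 1]), 27)

  # every reported hit re-translates to its peptide
  for (i in seq_len(nrow(hits))) {
    m <- hits$mcs[i]
    expect_equal(oracle_translate(m), pep)
  }
})

test_that("RPHM counts reads fully containing a coding sequence", {
  set.seed(32)
  mcs <- paste(rep("ACG", 9), collapse = "")
  reads <- c(
    paste0(random_read(20), mcs, random_read(28)),  # contains
    paste0(random_read(48), mcs),                   # contains at edge
    random_read(75),                                # does not
    substr(mcs, 1, 20)                              # partial only
  )
  rs <- read_set("s", reads, total_reads = 1e8)
  q <- rphm_quantify("TTTTTTTTT", mcs, rs)
  expect_equal(q$read_count, 2)
  expect_equal(q$rphm, 2.0)

  q0 <- rphm_quantify("TTTTTTTTT", "GATTACAGATTACAGATTACAGATTACA", rs)
  expect_equal(q0$rphm, 0.0)

  expect_error(rphm_quantify("T", mcs, read_set("s", character(0))),
               "total_reads")

  # unstranded read sets also match the reverse complement
  rs_un <- read_set("s", revcomp(reads[1]), stranded = FALSE,
                    total_reads = 1e8)
  expect_equal(rphm_quantify("X", mcs, rs_un)$read_count, 1)
  rs_st <- read_set("s", revcomp(reads[1]), stranded = TRUE,
                    total_reads = 1e8)
  expect_equal(rphm_quantify("X", mcs, rs_st)$read_count, 0)
})

test_that("RPHM grows proportionally with coverage", {
  g <- make_toy_genome(34, n_genes = 6)
  pl <- plant_events(g, "aeTSA_intergenic", seed = 1)
  tr <- pl$truth
  rphm_at <- function(depth) {
    prof <- stats::setNames(depth, tr$event_id)
    rs <- simulate_reads(pl$genome, prof, read_len = 75, seed = 5,
                         truth = tr, library_size = 1e8)
    rphm_quantify(tr$peptide, tr$mcs, rs)$rphm
  }
  r <- vapply(c(5, 10, 20), rphm_at, numeric(1))
  expect_true(all(diff(r) > 0))
  expect_gt(r[2] / r[1], 1.3)   # ~2x per doubling, Poisson tolerance
  expect_lt(r[2] / r[1], 3.0)
  expect_gt(r[3] / r[2], 1.3)
  expect_lt(r[3] / r[2], 3.0)
})

test_that("KPHM is the minimum 24-mer occurrence over the coding sequence", {
  mcs <- paste(vapply(strsplit("KLMNPQRST", "")[[1]], function(a)
    names(.oracle_code)[.oracle_code == a][1], character(1)),
    collapse = "")
  wins <- substring(mcs, 1:4, 24:27)
  counts <- stats::setNames(c(9L, 8L, 7L, 9L), canonical_kmer(wins))
  ks <- structure(list(k = 24L, counts = counts, rtot = 1e8,
                       canonical = TRUE), class = "kmer_set")
  q <- kphm_quantify("KLMNPQRST", mcs, ks)
  expect_equal(q$kmin, 7)
  expect_equal(q$kphm, 7)

  # exact formula: kmin x 1e8 / rtot
  ks$counts[] <- 5L
  ks$rtot <- 2e8
  expect_equal(kphm_quantify("KLMNPQRST", mcs, ks)$kphm, 2.5)

  # absent k-mer -> kmin 0
  ks2 <- structure(list(k = 24L, counts = counts[-2], rtot = 1e8,
                        canonical = TRUE), class = "kmer_set")
  expect_equal(kphm_quantify("KLMNPQRST", mcs, ks2)$kmin, 0)

  # most-expressed convention: argmax over coding sequences of the min
  mcs2 <- chartr("ACGT", "TGCA", mcs)  # different sequence, absent
  q2 <- kphm_quantify("X", c(mcs2, mcs), ks)
  expect_equal(q2$mcs, mcs)

  expect_error(kphm_quantify("X", "ACGTACGT", ks), "24 nt")
  ks_bad <- structure(list(k = 24L, counts = counts, rtot = 1, canonical = FALSE),
                      class = "kmer_set")
  expect_error(kphm_quantify("X", mcs, ks_bad), "canonical")
})

test_that("KPHM and RPHM are invariant to library duplication", {
  g <- make_toy_genome(35, n_genes = 6)
  pl <- plant_events(g, "aeTSA_intergenic", seed = 1)
  tr <- pl$truth
  prof <- stats::setNames(15, tr$event_id)
  rs <- simulate_reads(pl$genome, prof, read_len = 75, seed = 6,
                       truth = tr, library_size = 1e6)
  rs2 <- read_set("dup", c(rs$reads, rs$reads), total_reads = 2e6)
  expect_equal(rphm_quantify(tr$peptide, tr$mcs, rs2)$rphm,
               rphm_quantify(tr$peptide, tr$mcs, rs)$rphm)
  k1 <- count_kmers(rs, 24, canonical = TRUE)
  k2 <- count_kmers(rs2, 24, canonical = TRUE)
  expect_equal(kphm_quantify(tr$peptide, tr$mcs, k2)$kphm,
               kphm_quantify(tr$peptide, tr$mcs, k1)$kphm)
})
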