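test_that("expression gate applies fold and normal-KPHM thresholds", {
  expect_true(expression_gate(30, 1.5)$pass)    # 20-fold, normal < 2
  expect_equal(expression_gate(30, 1.5)$fold, 20)
  expect_false(expression_gate(30, 2.5)$pass)   # normal >= 2 KPHM
  g <- expression_gate(5, 0)                    # division-free rule
  expect_true(g$pass)
  expect_equal(g$fold, Inf)
  # boundary: normal 1.999 passes, 2.0 fails (strict "< 2")
  expect_true(expression_gate(30, 1.999)$pass)
  expect_false(expression_gate(30, 2.0)$pass)
  # undetected candidate never passes
  expect_false(expression_gate(0, 0)$pass)
  # monotone: tightening thresholds never turns fail into pass
  set.seed(41)
  for (i in 1:50) {
    cancer <- stats::runif(1, 0, 40)
    normal <- stats::runif(1, 0, 4)
    loose <- expression_gate(cancer, normal, min_fold = 5,
                             max_normal_kphm = 3)$pass
    strict <- expression_gate(cancer, normal, min_fold = 10,
                              max_normal_kphm = 2)$pass
    expect_true(loose || !strict)
  }
})

test_that("I/L disambiguation keeps only the most expressed variant", {
  expect_equal(il_variants("MKTAYEAGW"), "MKTAYEAGW")  # no I/L
  v <- il_variants("SIIETVNSL")
  expect_equal(length(v), 2^3)
  expect_true("SIIETVNSL" %in% v)
  expect_warning(il_variants(strrep("IL", 6), cap = 10), "I/L")

  prof <- data.frame(
    variant = c("SIIETVNSL", "SLIETVNSL"),
    cancer_kphm = c(5, 50),
    normal_kphm = c(0, 0),
    stringsAsFactors = FALSE
  )
  # a more expressed variant exists -> candidate dropped
  expect_false(il_disambiguate("SIIETVNSL", prof)$keep)
  expect_equal(il_disambiguate("SIIETVNSL", prof)$top_variant, "SLIETVNSL")
  # candidate is itself the top variant and passes -> kept
  prof2 <- prof
  prof2$cancer_kphm <- c(50, 5)
  expect_true(il_disambiguate("SIIETVNSL", prof2)$keep)
  # top variant but failing the gate -> dropped
  prof3 <- prof2
  prof3$normal_kphm <- c(30, 0)
  expect_false(il_disambiguate("SIIETVNSL", prof3)$keep)
})

test_that("normal-tissue screen is strict with an MHC-low exemption", {
  expect_true(normal_screen(c(mtec = 0, colon = 0, lung = 0))$pass)
  # one tissue at exactly 8.55 fails (strict "< 8.55")
  expect_false(normal_screen(c(mtec = 0, colon = 8.55))$pass)
  expect_true(normal_screen(c(mtec = 0, colon = 8.549))$pass)
  # testis above threshold, exemption on: pass with CTA annotation
  scr <- normal_screen(c(testis = 20, colon = 0, mtec = 0),
                       mhc_low_tissues = c("brain", "nerve", "testis"))
  expect_true(scr$pass)
  expect_true(scr$cta)
  # without the exemption the same panel fails
  expect_false(normal_screen(c(testis = 20, colon = 0, mtec = 0))$pass)
  expect_error(normal_screen(numeric(0)), "empty")
})

test_that("localization screen assigns regions by precedence", {
  jg <- make_junction_genome()
  tx <- jg$annotation[[1]]
  sp <- spliced_seq(tx, jg)
  mk_hit <- function(s0, e0, pep = "X", strand = "+", chrom = "chrJ") {
    h <- data.frame(peptide = pep, mcs = "", chrom = chrom, start0 = s0,
                    end0 = e0, strand = strand, spliced = FALSE,
                    transcript_id = NA_character_,
                    sp_start0 = NA_integer_, stringsAsFactors = FALSE)
    h$blocks <- I(list(matrix(c(s0, e0), 1, 2)))
    h
  }
  # CDS-exon in annotated frame: spliced [33, 60) = genomic [133, 160)
  loc <- localization_screen(mk_hit(133L, 160L), jg$annotation)
  expect_true(loc$pass)
  expect_equal(loc$region, "exon")
  # +1 frame offset inside the CDS -> exon_frameshift
  expect_equal(localization_screen(mk_hit(134L, 158L),
                                   jg$annotation)$region,
               "exon_frameshift")
  # 5' UTR: spliced [0, 27) = genomic [100, 127)
  expect_equal(localization_screen(mk_hit(100L, 127L),
                                   jg$annotation)$region, "UTR5")
  # intronic hit
  expect_equal(localization_screen(mk_hit(200L, 227L),
                                   jg$annotation)$region, "intron")
  # intergenic hit
  expect_equal(localization_screen(mk_hit(500L, 527L),
                                   jg$annotation)$region, "intergenic")
  # opposite strand does not inherit the gene annotation
  expect_equal(localization_screen(mk_hit(133L, 160L, strand = "-"),
                                   jg$annotation)$region, "intergenic")

  # hypervariable interval excludes the candidate
  hv <- data.frame(chrom = "chrJ", start0 = 120L, end0 = 170L)
  expect_false(localization_screen(mk_hit(133L, 160L), jg$annotation,
                                   hypervariable = hv)$pass)
  # too many loci -> unclear localization
  many <- do.call(rbind, lapply(seq(0, 500, by = 100), function(s)
    mk_hit(s, s + 27L)))
  loc_many <- localization_screen(many, jg$annotation, max_loci = 5)
  expect_false(loc_many$pass)
  expect_equal(loc_many$reason, "unclear_localization")
  # no hits
  expect_equal(localization_screen(mk_hit(0L, 0L)[0, ],
                                   jg$annotation)$reason, "no_genomic_hit")
})

test_that("mutation check distinguishes somatic from germline variants", {
  jg <- make_junction_genome()
  tumor <- jg
  # introduce a substitution in the CDS at genomic 140 (spliced 40)
  ref_base <- substr(jg$chromosomes[["chrJ"]], 141, 141)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  substr(tumor$chromosomes[["chrJ"]], 141, 141) <- alt_base
  mcs <- substr(tumor$chromosomes[["chrJ"]], 134, 160)
  pep <- oracle_translate(mcs)
  hit <- list(peptide = pep, mcs = mcs, chrom = "chrJ", start0 = 133L,
              end0 = 160L, strand = "+", spliced = FALSE,
              blocks = matrix(c(133L, 160L), 1, 2))
  if (!grepl("\\*", pep)) {
    mc <- mutation_check(hit, jg)
    expect_true(mc$mutated)
    expect_false(mc$germline)
    # the same variant listed as a germline SNP is not somatic
    jg2 <- jg
    jg2$germline_snps <- data.frame(chrom = "chrJ", pos0 = 140L,
                                    ref = ref_base, alt = alt_base,
                                    stringsAsFactors = FALSE)
    expect_true(mutation_check(hit, jg2)$germline)
  }
  # reference-identical peptide is not mutated
  ref_mcs <- substr(jg$chromosomes[["chrJ"]], 134, 160)
  hit_ref <- hit
  hit_ref$mcs <- ref_mcs
  hit_ref$peptide <- oracle_translate(ref_mcs)
  expect_false(mutation_check(hit_ref, jg)$mutated)
})

test_that("final labels follow the threshold cascade", {
  lab <- function(...) final_label("PEP", "s", ...)$label
  # reference-identical, fold 20, mtec 0.1, nat 0.05 -> aeTSA
  expect_equal(lab(20, FALSE, FALSE, 0.1, 0.05), "aeTSA")
  # mtec 0.5 -> TAA
  expect_equal(lab(20, FALSE, FALSE, 0.5, 0.05), "TAA")
  # somatic variant -> mTSA regardless of mtec
  expect_equal(lab(20, TRUE, FALSE, 5, 5), "mTSA")
  # germline variant falls through to the expression rules
  expect_equal(lab(20, TRUE, TRUE, 0.1, 0.1), "aeTSA")
  # boundary: mtec 0.2 inclusive aeTSA, 0.2000001 -> TAA
  expect_equal(lab(20, FALSE, FALSE, 0.2, 0), "aeTSA")
  expect_equal(lab(20, FALSE, FALSE, 0.2000001, 0), "TAA")
  # nat drives TAA in tissue mode too
  expect_equal(lab(20, FALSE, FALSE, 0, 0.3), "TAA")
  # below fold -> excluded with reason
  fl <- final_label("PEP", "s", 5, FALSE, FALSE, 0, 0)
  expect_equal(fl$label, "excluded")
  expect_equal(fl$exclusion_reason, "below_fold_change")
  # infinite fold passes the fold test
  expect_equal(lab(Inf, FALSE, FALSE, 0, 0), "aeTSA")
})

test_that("source transcripts are assigned by expression with deterministic ties", {
  jg <- make_junction_genome()
  tx2 <- jg$annotation[[1]]
  tx2$transcript_id <- "JTX2"
  jg$annotation[[2]] <- tx2
  hit <- list(chrom = "chrJ", start0 = 133L, end0 = 160L, strand = "+")
  a <- assign_source_transcript(hit, jg$annotation,
                                c(JTX1 = 5, JTX2 = 50))
  expect_equal(a$transcript_id, "JTX2")
  expect_false(a$tie)
  t2 <- assign_source_transcript(hit, jg$annotation,
                                 c(JTX1 = 10, JTX2 = 10))
  expect_equal(t2$transcript_id, "JTX1")  # lexicographic tie-break
  expect_true(t2$tie)
  none <- assign_source_transcript(list(chrom = "chrJ", start0 = 580L,
                                        end0 = 590L, strand = "+"),
                                   jg$annotation, c(JTX1 = 10))
  expect_equal(none$biotype, "unannotated")
})
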