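# End-to-end synthetic study: a toy tumor/normal pair with planted
# antigen events, and the discovery pipeline that recovers them.

#' Generate the default synthetic antigen-discovery study
#'
#' Builds a two-chromosome toy genome with eight protein-coding genes
#' and two lncRNAs, plants six aberrant-expression events (two
#' intergenic, two intronic, one lncRNA, one 5' UTR), one somatic SNV
#' and two overexpressed TAAs, and simulates stranded read sets for
#' the tumor, the matched normal (NAT), an mTEC pool and three
#' normal-panel tissues, plus a search-engine identification table.
#'
#' Gene roles: four housekeeping genes expressed in every sample; one
#' tumor-only gene hosting the UTR event; one gene carrying the
#' somatic SNV (expressed everywhere, mutant allele in the tumor);
#' two TAA genes expressed in tumor and mTEC but absent from the
#' matched NAT and the panel tissues. Reads are materialized over
#' expressed features only, while the declared library sizes emulate
#' deep sequencing (1e8 reads for tumor/NAT, 4e8 for the pooled
#' mTEC/panel libraries), which puts the KPHM/RPHM thresholds on
#' their intended scale.
#'
#' @param seed Integer seed (all derived seeds stay close to it).
#' @param depth Mean coverage of expressed features (x).
#' @param panel_depth Housekeeping coverage in panel tissues (x).
#' @param read_len Read length in nt.
#' @param tumor_lib,normal_lib,mtec_lib,panel_lib Declared library
#'   sizes.
#' @param n_targets,n_decoys Identification-table sizes.
#' @return A list with `reference`, `tumor_genome`, `truth`,
#'   `readsets`, `idents`, `proteome`, `tpm`, `roles`.
#' @export
toy_study <- function(seed, depth = 20, panel_depth = 10,
                      read_len = 75L, tumor_lib = 1e8, normal_lib = 1e8,
                      mtec_lib = 4e8, panel_lib = 4e8,
                      n_targets = 45L, n_decoys = 25L) {
  genome <- make_toy_genome(seed, n_chrom = 2L, chrom_len = 50000L,
                            n_genes = 8L, n_lncrna = 2L)
  roles <- list(
    housekeeping = c("TX01", "TX02", "TX03", "TX04"),
    utr_host = "TX05", mtsa_host = "TX06",
    taa_hosts = c("TX07", "TX08"), lnc_host = "TX09"
  )
  req <- event_requests(
    c("aeTSA_intergenic", "aeTSA_intergenic", "aeTSA_intron",
      "aeTSA_intron", "aeTSA_lncRNA", "aeTSA_utr", "mTSA_snv",
      "TAA_overexpressed", "TAA_overexpressed"),
    host = c(NA, NA, roles$housekeeping[1], roles$housekeeping[2],
             roles$lnc_host, roles$utr_host, roles$mtsa_host,
             roles$taa_hosts)
  )
  req$tumor_depth <- depth
  req$normal_depth <- ifelse(req$kind == "mTSA_snv", depth, 0)
  req$mtec_depth <- ifelse(req$kind %in% c("mTSA_snv", "TAA_overexpressed"),
                           depth, 0)
  planted <- plant_events(genome, req, seed + 1L)
  truth <- planted$truth
  window_events <- truth$event_id[truth$feature == "window"]

  hk <- stats::setNames(rep(depth, length(roles$housekeeping)),
                        roles$housekeeping)
  tumor_profile <- c(
    hk,
    stats::setNames(depth, roles$utr_host),
    stats::setNames(depth, roles$mtsa_host),
    stats::setNames(rep(depth, 2L), roles$taa_hosts),
    stats::setNames(depth, roles$lnc_host),
    stats::setNames(rep(depth, length(window_events)), window_events)
  )
  nat_profile <- c(hk, stats::setNames(depth, roles$mtsa_host))
  mtec_profile <- c(hk, stats::setNames(depth, roles$mtsa_host),
                    stats::setNames(rep(depth, 2L), roles$taa_hosts))
  panel_profile <- stats::setNames(rep(panel_depth, length(roles$housekeeping)),
                                   roles$housekeeping)

  readsets <- list(
    tumor = simulate_reads(planted$genome, tumor_profile, read_len,
                           seed + 2L, truth = truth, sample_id = "tumor",
                           library_size = tumor_lib),
    nat = simulate_reads(planted$reference, nat_profile, read_len,
                         seed + 3L, sample_id = "nat",
                         library_size = normal_lib),
    mtec = simulate_reads(planted$reference, mtec_profile, read_len,
                          seed + 4L, sample_id = "mtec",
                          library_size = mtec_lib),
    colon = simulate_reads(planted$reference, panel_profile, read_len,
                           seed + 5L, sample_id = "colon",
                           library_size = panel_lib),
    liver = simulate_reads(planted$reference, panel_profile, read_len,
                           seed + 6L, sample_id = "liver",
                           library_size = panel_lib),
    lung = simulate_reads(planted$reference, panel_profile, read_len,
                          seed + 7L, sample_id = "lung",
                          library_size = panel_lib)
  )
  proteome <- canonical_proteome(planted$reference,
                                 c(roles$housekeeping, roles$mtsa_host))
  idents <- simulate_identifications(truth, proteome, n_targets,
                                     n_decoys, seed + 8L,
                                     sample_id = "tumor")
  expressed <- tumor_profile[!names(tumor_profile) %in% window_events]
  tpm <- 1e6 * expressed / sum(expressed)
  list(reference = planted$reference, tumor_genome = planted$genome,
       truth = truth, readsets = readsets, idents = idents,
       proteome = proteome, tpm = tpm, roles = roles)
}

#' Expected label and genomic region of each planted event kind
#'
#' @param truth Truth table from [plant_events()].
#' @return The truth table with `expected_label` and `expected_region`
#'   columns appended.
#' @export
expected_calls <- function(truth) {
  lab <- c(aeTSA_intergenic = "aeTSA", aeTSA_intron = "aeTSA",
           aeTSA_lncRNA = "aeTSA", aeTSA_utr = "aeTSA",
           mTSA_snv = "mTSA", mTSA_frameshift = "mTSA",
           TAA_overexpressed = "TAA")
  reg <- c(aeTSA_intergenic = "intergenic", aeTSA_intron = "intron",
           aeTSA_lncRNA = "lncRNA", aeTSA_utr = "UTR5",
           mTSA_snv = "exon", mTSA_frameshift = "exon_frameshift",
           TAA_overexpressed = "exon")
  truth$expected_label <- unname(lab[truth$kind])
  truth$expected_region <- unname(reg[truth$kind])
  truth
}

#' Run the TSA discovery cascade on a synthetic study
#'
#' Applies, in order: decoy-based FDR filtering; the 8-11 aa and
#' binding-rank filters; exact coding-sequence placement on the tumor
#' genome; the KPHM expression gate against the matched normal; I/L
#' disambiguation; the normal-panel RPHM screen (mTEC pool plus panel
#' tissues); the genomic localization screen; the reference-genome
#' mutation check; and the final mTSA/aeTSA/TAA labels with source
#' transcript assignment.
#'
#' @param study Output of [toy_study()].
#' @param fdr FDR bound for [fdr_filter()].
#' @param min_fold,max_normal_kphm Expression-gate thresholds.
#' @param aetsa_max aeTSA/TAA boundary in KPHM.
#' @param max_panel_rphm Normal-panel screen threshold.
#' @param max_loci Localization-screen placement cap.
#' @param hypervariable Optional data frame chrom/start0/end0.
#' @param mhc_low_tissues Panel tissues exempt from the RPHM screen.
#' @return Data frame of antigen calls, one row per candidate peptide:
#'   label, exclusion reason, region, source transcript/biotype, fold
#'   change and the expression values behind the decision.
#' @export
discover_antigens <- function(study, fdr = 0.05, min_fold = 10,
                              max_normal_kphm = 2.0, aetsa_max = 0.2,
                              max_panel_rphm = 8.55, max_loci = 5L,
                              hypervariable = NULL,
                              mhc_low_tissues = c("brain", "nerve", "testis")) {
  ann <- study$tumor_genome$annotation
  rec <- suppressWarnings(fdr_filter(study$idents, fdr))
  peps <- map_filter(rec)
  candidates <- sort(unique(unlist(lapply(peps, `[[`, "peptides"))))
  k24 <- list(
    tumor = count_kmers(study$readsets$tumor, 24L, canonical = TRUE),
    nat = count_kmers(study$readsets$nat, 24L, canonical = TRUE),
    mtec = count_kmers(study$readsets$mtec, 24L, canonical = TRUE)
  )
  panel_sets <- study$readsets[c("mtec", "colon", "liver", "lung")]

  out <- list()
  emit <- function(peptide, label, reason = NA_character_,
                   region = NA_character_, tx = NA_character_,
                   biotype = NA_character_, fold = NA_real_,
                   cancer = NA_real_, nat = NA_real_, mtec = NA_real_,
                   max_rphm = NA_real_, cta = FALSE, n_loci = NA_integer_) {
    out[[length(out) + 1L]] <<- data.frame(
      peptide = peptide, sample_id = "tumor", label = label,
      exclusion_reason = reason, region = region,
      source_transcript_id = tx, source_biotype = biotype,
      fold_change = fold, cancer_kphm = cancer, nat_kphm = nat,
      mtec_kphm = mtec, max_normal_rphm = max_rphm, cta = cta,
      n_loci = n_loci, stringsAsFactors = FALSE
    )
  }

  for (pep in candidates) {
    hits <- map_mcs(pep, study$tumor_genome, ann)
    if (!nrow(hits)) {
      emit(pep, "excluded", "no_genomic_hit")
      next
    }
    qt <- kphm_quantify(pep, hits$mcs, k24$tumor)
    qn <- kphm_quantify(pep, qt$mcs, k24$nat, mode = "single")
    qm <- kphm_quantify(pep, qt$mcs, k24$mtec, mode = "single")
    gate <- expression_gate(qt$kphm, qn$kphm, min_fold, max_normal_kphm)
    if (!gate$pass) {
      emit(pep, "excluded", "expression_gate", fold = gate$fold,
           cancer = qt$kphm, nat = qn$kphm, mtec = qm$kphm,
           n_loci = nrow(hits))
      next
    }
    vars <- il_variants(pep)
    if (length(vars) > 1L) {
      prof <- data.frame(variant = vars, cancer_kphm = NA_real_,
                         normal_kphm = 0, stringsAsFactors = FALSE)
      for (i in seq_along(vars)) {
        if (vars[i] == pep) {
          prof$cancer_kphm[i] <- qt$kphm
          prof$normal_kphm[i] <- qn$kphm
        } else {
          vh <- map_mcs(vars[i], study$tumor_genome, ann)
          prof$cancer_kphm[i] <- if (nrow(vh)) {
            kphm_quantify(vars[i], vh$mcs, k24$tumor)$kphm
          } else 0
        }
      }
      il <- il_disambiguate(pep, prof, min_fold, max_normal_kphm)
      if (!il$keep) {
        emit(pep, "excluded", "il_variant", fold = gate$fold,
             cancer = qt$kphm, nat = qn$kphm, mtec = qm$kphm,
             n_loci = nrow(hits))
        next
      }
    }
    panel <- vapply(panel_sets, function(rs)
      rphm_quantify(pep, hits, rs)$rphm, numeric(1))
    scr <- normal_screen(panel, max_panel_rphm, mhc_low_tissues)
    if (!scr$pass) {
      emit(pep, "excluded", "normal_panel_rphm", fold = gate$fold,
           cancer = qt$kphm, nat = qn$kphm, mtec = qm$kphm,
           max_rphm = max(panel), n_loci = nrow(hits))
      next
    }
    loc <- localization_screen(hits, ann, hypervariable, max_loci,
                               top_mcs = qt$mcs)
    if (!loc$pass) {
      emit(pep, "excluded", loc$reason, fold = gate$fold,
           cancer = qt$kphm, nat = qn$kphm, mtec = qm$kphm,
           max_rphm = max(panel), n_loci = nrow(hits))
      next
    }
    mut <- mutation_check(loc$top_hit, study$reference)
    lab <- final_label(pep, "tumor", gate$fold, mut$mutated,
                       mut$germline, qm$kphm, qn$kphm, min_fold,
                       aetsa_max)
    src <- assign_source_transcript(loc$top_hit, ann, study$tpm)
    emit(pep, lab$label, lab$exclusion_reason, region = loc$region,
         tx = src$transcript_id, biotype = src$biotype,
         fold = gate$fold, cancer = qt$kphm, nat = qn$kphm,
         mtec = qm$kphm, max_rphm = max(panel), cta = scr$cta,
         n_loci = nrow(hits))
  }
  calls <- do.call(rbind, out) %||% data.frame()
  rownames(calls) <- NULL
  calls
}

#' Cancer-specific database recovery of planted TSA peptides
#'
#' Builds the global cancer database from the study's tumor, NAT and
#' mTEC read sets (33-mer subtraction, assembly, three-frame
#' translation) and reports the fraction of planted TSA peptides
#' (aeTSA and mTSA kinds; TAAs are not tumor-specific and are
#' subtracted away) whose amino acid sequence appears in the
#' cancer-specific proteome.
#'
#' @param study Output of [toy_study()].
#' @return List with `recovered` (fraction), `db` (the `proteome_db`),
#'   `missing` (peptides not recovered).
#' @export
study_db_recovery <- function(study) {
  db <- build_cancer_db(study$readsets$tumor,
                        list(study$readsets$nat, study$readsets$mtec),
                        canonical = study$proteome)
  frags <- db_fragments(db)
  tsas <- study$truth$peptide[startsWith(study$truth$kind, "aeTSA") |
                                startsWith(study$truth$kind, "mTSA")]
  found <- vapply(tsas, function(p) any(grepl(p, frags, fixed = TRUE)),
                  logical(1))
  list(recovered = mean(found), db = db, missing = tsas[!found])
}
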