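# The TSA identification cascade: expression thresholds against
# matched normal, I/L disambiguation, normal-tissue RPHM screen,
# genomic localization screen and the final mTSA/aeTSA/TAA labels.

#' Cancer-versus-normal expression gate
#'
#' Passes a peptide whose coding-sequence expression is at least
#' `min_fold` higher in cancer than in normal and below
#' `max_normal_kphm` in normal. The rule is multiplicative, so a
#' normal KPHM of exactly 0 with any cancer expression passes with an
#' infinite fold change (no pseudocounts).
#'
#' @param cancer_kphm,normal_kphm KPHM values.
#' @param min_fold Minimum cancer/normal fold change.
#' @param max_normal_kphm Strict upper bound on normal KPHM.
#' @return List with `pass` and `fold` (`Inf` when normal is 0 and
#'   cancer is positive; `NA` when both are 0).
#' @export
expression_gate <- function(cancer_kphm, normal_kphm, min_fold = 10,
                            max_normal_kphm = 2.0) {
  stopifnot(cancer_kphm >= 0, normal_kphm >= 0)
  fold <- if (normal_kphm > 0) {
    cancer_kphm / normal_kphm
  } else if (cancer_kphm > 0) Inf else NA_real_
  pass <- cancer_kphm > 0 &&
    normal_kphm < max_normal_kphm &&
    cancer_kphm >= min_fold * normal_kphm
  list(pass = pass, fold = fold)
}

#' Enumerate isoleucine/leucine variants of a peptide
#'
#' I and L are isobaric and indistinguishable by MS. All `2^m`
#' substitution variants are enumerated for up to `cap` I/L residues;
#' beyond the cap only single-substitution variants are returned, with
#' a warning.
#'
#' @param peptide Amino acid sequence.
#' @param cap Maximum number of I/L positions for full enumeration.
#' @return Character vector of variants (including `peptide` itself).
#' @export
il_variants <- function(peptide, cap = 10L) {
  res <- strsplit(peptide, "")[[1]]
  pos <- which(res %in% c("I", "L"))
  m <- length(pos)
  if (m == 0L) return(peptide)
  if (m <= cap) {
    grid <- expand.grid(rep(list(c("I", "L")), m),
                        stringsAsFactors = FALSE)
    vars <- apply(grid, 1L, function(g) {
      r <- res
      r[pos] <- g
      paste(r, collapse = "")
    })
  } else {
    warning("more than ", cap, " I/L residues; ",
            "testing single substitutions only")
    vars <- vapply(pos, function(p) {
      r <- res
      r[p] <- if (r[p] == "I") "L" else "I"
      paste(r, collapse = "")
    }, character(1))
    vars <- c(peptide, vars)
  }
  sort(unique(vars))
}

#' I/L disambiguation rule
#'
#' A candidate with I/L variants is kept only if it is itself the most
#' expressed variant in cancer and passes the expression gate.
#'
#' @param peptide The candidate sequence.
#' @param profiles Data frame with columns `variant`, `cancer_kphm`,
#'   `normal_kphm`, covering every I/L variant (including the
#'   candidate).
#' @param min_fold,max_normal_kphm Gate parameters.
#' @return List with `keep`, `top_variant`, `gate`.
#' @export
il_disambiguate <- function(peptide, profiles, min_fold = 10,
                            max_normal_kphm = 2.0) {
  stopifnot(peptide %in% profiles$variant)
  ord <- order(-profiles$cancer_kphm, profiles$variant)
  top <- profiles$variant[ord[1L]]
  row <- profiles[profiles$variant == peptide, ][1L, ]
  gate <- expression_gate(row$cancer_kphm, row$normal_kphm,
                          min_fold, max_normal_kphm)
  list(keep = identical(top, peptide) && gate$pass,
       top_variant = top, gate = gate)
}

#' Normal-tissue RPHM screen
#'
#' Passes only if the coding-sequence expression is strictly below
#' `max_rphm` in every panel tissue. Tissues named in
#' `mhc_low_tissues` (low MHC class I expression, e.g. brain, nerve,
#' testis) can be exempted from the pass/fail decision; expression
#' above threshold in an exempt testis flags the candidate as a
#' potential cancer-testis antigen.
#'
#' @param panel Named numeric vector of per-tissue RPHM values
#'   (mTEC pool plus normal tissues).
#' @param max_rphm Strict threshold.
#' @param mhc_low_tissues Tissue names exempt from the screen.
#' @return List with `pass`, `failing` (named values at or above the
#'   threshold among screened tissues), `cta` (above threshold in an
#'   exempt testis).
#' @export
normal_screen <- function(panel, max_rphm = 8.55,
                          mhc_low_tissues = character(0)) {
  if (!length(panel)) stop("empty normal panel")
  stopifnot(all(panel >= 0))
  exempt <- names(panel) %in% mhc_low_tissues
  screened <- panel[!exempt]
  failing <- screened[screened >= max_rphm]
  cta <- any(exempt & grepl("testis", names(panel), ignore.case = TRUE) &
               panel >= max_rphm)
  list(pass = length(failing) == 0L, failing = failing, cta = cta)
}

# genomic region of one hit, by precedence:
# exon (annotated frame) / exon_frameshift > UTR5/UTR3 > lncRNA >
# intron > intergenic. Only same-strand transcripts are considered.
.region_of_hit <- function(hit, annotation) {
  prec <- c(exon = 1, exon_frameshift = 2, UTR5 = 3, UTR3 = 3,
            lncRNA = 4, intron = 5, intergenic = 6)
  best <- "intergenic"
  txs <- .overlapping_transcripts(annotation, hit$chrom, hit$start0,
                                  hit$end0, strand = hit$strand)
  for (tx in txs) {
    reg <- "intron"
    if (isTRUE(hit$spliced) && identical(hit$transcript_id, tx$transcript_id)) {
      sp <- hit$sp_start0
      w <- sum(hit$blocks[[1]][, 2] - hit$blocks[[1]][, 1])
      reg <- .exonic_region(tx, sp, sp + w)
    } else if (!isTRUE(hit$spliced)) {
      s <- genomic_to_spliced(tx, if (tx$strand == "+") hit$start0 else hit$end0 - 1L)
      e <- genomic_to_spliced(tx, if (tx$strand == "+") hit$end0 - 1L else hit$start0)
      if (!is.na(s) && !is.na(e) && e == s + (hit$end0 - hit$start0) - 1L) {
        reg <- .exonic_region(tx, s, e + 1L)
      }
    }
    if (prec[[reg]] < prec[[best]]) best <- reg
  }
  best
}

# region of a spliced interval [s, e) fully inside the exons of tx
.exonic_region <- function(tx, s, e) {
  if (tx$biotype == "lncRNA" || is.null(tx$cds)) return("lncRNA")
  if (e <= tx$cds[1]) return("UTR5")
  if (s >= tx$cds[2]) return("UTR3")
  if (s >= tx$cds[1] && e <= tx$cds[2]) {
    return(if ((s - tx$cds[1]) %% 3L == 0L) "exon" else "exon_frameshift")
  }
  # straddles a CDS/UTR boundary: treat as out-of-frame exonic
  "exon_frameshift"
}

#' Genomic localization screen
#'
#' Fails candidates with no perfect placement, with more than
#' `max_loci` distinct placements (unclear localization), or with any
#' placement inside a configured hypervariable region (HLA, Ig or TCR
#' genes). Otherwise assigns the genomic region of the top-expressed
#' placement by the precedence exon > UTR > lncRNA > intron >
#' intergenic; in-CDS hits off the annotated frame are labeled
#' `exon_frameshift`.
#'
#' @param hits [map_mcs()] output.
#' @param annotation Transcript models.
#' @param hypervariable Optional data frame chrom/start0/end0 of
#'   regions to exclude.
#' @param max_loci Maximum number of distinct placements.
#' @param top_mcs Coding sequence of the top-expressed placement
#'   (defaults to the first hit).
#' @return List with `pass`, `reason`, `region`, `top_hit` (a one-row
#'   hit data frame or `NULL`).
#' @export
localization_screen <- function(hits, annotation, hypervariable = NULL,
                                max_loci = 5L, top_mcs = NULL) {
  if (!nrow(hits)) {
    return(list(pass = FALSE, reason = "no_genomic_hit",
                region = NA_character_, top_hit = NULL))
  }
  if (nrow(hits) > max_loci) {
    return(list(pass = FALSE, reason = "unclear_localization",
                region = NA_character_, top_hit = NULL))
  }
  if (!is.null(hypervariable) && nrow(hypervariable)) {
    for (i in seq_len(nrow(hits))) {
      hv <- hypervariable[hypervariable$chrom == hits$chrom[i] &
                            hypervariable$start0 < hits$end0[i] &
                            hypervariable$end0 > hits$start0[i], ]
      if (nrow(hv)) {
        return(list(pass = FALSE, reason = "hypervariable_region",
                    region = NA_character_, top_hit = NULL))
      }
    }
  }
  ti <- if (!is.null(top_mcs)) match(top_mcs, hits$mcs) else 1L
  if (is.na(ti)) ti <- 1L
  top <- hits[ti, , drop = FALSE]
  region <- .region_of_hit(as.list(top), annotation)
  list(pass = TRUE, reason = NA_character_, region = region,
       top_hit = top)
}

#' Compare a placement against the reference genome
#'
#' Reconstructs the reference allele of the coding sequence at the hit
#' locus and reports whether the peptide differs from the reference
#' translation there, and whether every differing nucleotide is a
#' known germline polymorphism.
#'
#' @param hit One row of [map_mcs()] output (as a list or one-row data
#'   frame), located on the genome in which the peptide was found
#'   (e.g. the tumor genome).
#' @param reference The reference `toy_genome`.
#' @return List with `mutated` (peptide differs from the reference
#'   translation), `germline` (all nucleotide differences are listed
#'   germline SNPs).
#' @export
mutation_check <- function(hit, reference) {
  if (is.data.frame(hit)) hit <- as.list(hit[1L, ])
  blocks <- if (is.list(hit$blocks) && !is.matrix(hit$blocks)) {
    hit$blocks[[1]]
  } else hit$blocks
  chromseq <- reference$chromosomes[[hit$chrom]]
  parts <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    parts[i] <- substr(chromseq, blocks[i, 1] + 1L, blocks[i, 2])
  }
  ref_nt <- paste(parts, collapse = "")
  if (hit$strand == "-") ref_nt <- revcomp(ref_nt)
  mutated <- !identical(translate_nt(ref_nt), hit$peptide)
  germline <- FALSE
  if (mutated) {
    # genomic positions (ascending) covered by the hit
    gpos <- unlist(lapply(seq_len(nrow(blocks)), function(i)
      seq.int(blocks[i, 1], blocks[i, 2] - 1L)))
    obs_plus <- if (hit$strand == "+") hit$mcs else revcomp(hit$mcs)
    ref_plus <- paste(parts, collapse = "")
    obs_b <- strsplit(obs_plus, "")[[1]]
    ref_b <- strsplit(ref_plus, "")[[1]]
    diffs <- which(obs_b != ref_b)
    gs <- reference$germline_snps
    germline <- length(diffs) > 0 && all(vapply(diffs, function(d) {
      any(gs$chrom == hit$chrom & gs$pos0 == gpos[d] & gs$alt == obs_b[d])
    }, logical(1)))
  }
  list(mutated = mutated, germline = germline)
}

#' Final antigen label
#'
#' Applies the classification cascade to a candidate that has passed
#' the upstream gates: mutated TSA (mTSA) if the peptide differs from
#' the reference translation at its locus through a non-germline
#' variant; otherwise aberrantly expressed TSA (aeTSA) if the fold
#' change is at least `min_fold` and mTEC (and, in tissue mode, NAT)
#' expression is at most `aetsa_max` KPHM; otherwise tumor-associated
#' antigen (TAA) if the fold change passes but mTEC and/or NAT
#' expression exceeds `aetsa_max`; otherwise excluded.
#'
#' @param peptide,sample_id Candidate identity.
#' @param fold Cancer/normal fold change (may be `Inf`).
#' @param mutated,germline Output of [mutation_check()].
#' @param mtec_kphm mTEC-pool KPHM of the coding sequence.
#' @param nat_kphm Matched-NAT KPHM (`NULL` in cell-line mode).
#' @param min_fold Fold-change threshold.
#' @param aetsa_max Inclusive aeTSA ceiling / exclusive TAA floor.
#' @return List with `label` (`mTSA`, `aeTSA`, `TAA` or `excluded`)
#'   and `exclusion_reason`.
#' @export
final_label <- function(peptide, sample_id, fold, mutated, germline,
                        mtec_kphm, nat_kphm = NULL, min_fold = 10,
                        aetsa_max = 0.2) {
  nat <- nat_kphm %||% 0
  label <- "excluded"
  reason <- NA_character_
  if (mutated && !germline) {
    label <- "mTSA"
  } else if (!is.na(fold) && fold >= min_fold) {
    if (mtec_kphm <= aetsa_max && nat <= aetsa_max) {
      label <- "aeTSA"
    } else {
      label <- "TAA"
    }
  } else {
    reason <- if (mutated) "germline_variant" else "below_fold_change"
  }
  list(label = label, exclusion_reason = reason)
}

#' Assign the source transcript of an antigen
#'
#' Among same-strand transcripts overlapping the chosen locus, returns
#' the one with the highest expression (TPM); ties are broken by the
#' lexicographically smallest id and flagged. With no overlapping
#' transcript the biotype is `"unannotated"`.
#'
#' @param hit One row of [map_mcs()] output.
#' @param annotation Transcript models.
#' @param tpm Named numeric vector transcript_id -> TPM.
#' @return List with `transcript_id`, `biotype`, `tpm`, `tie`.
#' @export
assign_source_transcript <- function(hit, annotation, tpm) {
  if (is.data.frame(hit)) hit <- as.list(hit[1L, ])
  txs <- .overlapping_transcripts(annotation, hit$chrom, hit$start0,
                                  hit$end0, strand = hit$strand)
  if (!length(txs)) {
    return(list(transcript_id = NA_character_, biotype = "unannotated",
                tpm = NA_real_, tie = FALSE))
  }
  ids <- vapply(txs, `[[`, character(1), "transcript_id")
  vals <- unname(tpm[ids])
  vals[is.na(vals)] <- 0
  top <- max(vals)
  winners <- sort(ids[vals == top])
  tx <- txs[[match(winners[1L], ids)]]
  list(transcript_id = winners[1L], biotype = tx$biotype,
       tpm = top, tie = length(winners) > 1L)
}
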