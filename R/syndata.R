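# Synthetic study generator: a toy genome with annotated genes, planted
# antigen-generating events with a recorded ground truth, stranded
# error-free read sets and simulated MS identification tables. The
# generator defines the study conditions under which the downstream
# threshold cascade is exercised and validated.

#' Construct a toy genome with annotated genes
#'
#' Generates random chromosomes and writes multi-exon protein-coding
#' genes (UTR5/CDS/UTR3, internally stop-free CDS, 2-4 exons) and
#' lncRNAs into them, leaving intergenic gaps of at least 500 nt.
#' Coordinates are 0-based half-open throughout.
#'
#' @param seed Integer seed; identical seeds give identical genomes.
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in nt (>= 10,000).
#' @param n_genes Number of protein-coding genes (>= 4).
#' @param n_lncrna Number of lncRNA transcripts.
#' @return A `toy_genome`: list with `chromosomes` (named character
#'   vector), `annotation` (list of transcript models) and
#'   `germline_snps` (data frame chrom/pos0/ref/alt).
#' @export
make_toy_genome <- function(seed, n_chrom = 2L, chrom_len = 50000L,
                            n_genes = 6L, n_lncrna = 2L) {
  if (chrom_len < 10000L) stop("chrom_len must be >= 10,000 nt")
  if (n_genes < 4L) stop("n_genes must be >= 4")
  set.seed(seed)
  chroms <- vapply(seq_len(n_chrom), function(i) random_dna(chrom_len),
                   character(1))
  names(chroms) <- paste0("chr", seq_len(n_chrom))
  cursors <- stats::setNames(rep(1000L, n_chrom), names(chroms))
  annotation <- list()
  total <- n_genes + n_lncrna
  stops <- c("TAA", "TAG", "TGA")
  for (g in seq_len(total)) {
    is_lnc <- g > n_genes
    chrom <- names(chroms)[((g - 1L) %% n_chrom) + 1L]
    strand <- sample(c("+", "-"), 1L)
    if (!is_lnc) {
      utr5 <- sample(120:200, 1L)
      n_codon <- sample(80:160, 1L)
      utr3 <- sample(60:120, 1L)
      cds_nt <- paste0(
        "ATG",
        paste(sample(.sense_codons(), n_codon - 2L, replace = TRUE),
              collapse = ""),
        sample(stops, 1L)
      )
      sp <- paste0(random_dna(utr5), cds_nt, random_dna(utr3))
      cds <- c(utr5, utr5 + nchar(cds_nt))
      n_ex <- sample(2:4, 1L)
    } else {
      sp <- random_dna(sample(300:600, 1L))
      cds <- NULL
      n_ex <- sample(1:2, 1L)
    }
    S <- nchar(sp)
    # spliced chunk lengths: every exon >= 40 nt, and the first spliced
    # exon >= 90 nt so 5'-proximal features stay clear of read-coverage
    # edge effects
    for (try in 1:200) {
      bp <- if (n_ex > 1L) sort(sample(seq(90L, S - 40L), n_ex - 1L)) else integer(0)
      ex_len <- diff(c(0L, bp, S))
      if (min(ex_len) >= 40L) break
    }
    intr_len <- if (n_ex > 1L) sample(400:700, n_ex - 1L, replace = TRUE) else integer(0)
    span <- S + sum(intr_len)
    start <- cursors[[chrom]] + sample(0:300, 1L)
    if (start + span + 500L > chrom_len) {
      stop("chromosomes too short to place ", total,
           " genes; increase chrom_len")
    }
    # genomic exon order: transcript order for '+', reversed for '-'
    ex_len_g <- if (strand == "+") ex_len else rev(ex_len)
    ex <- matrix(0L, n_ex, 2L, dimnames = list(NULL, c("start0", "end0")))
    pos <- as.integer(start)
    for (i in seq_len(n_ex)) {
      ex[i, ] <- c(pos, pos + ex_len_g[i])
      pos <- ex[i, 2] + if (i < n_ex) intr_len[i] else 0L
    }
    # write spliced chunks into the chromosome
    chunks <- substring(sp, cumsum(c(1L, ex_len[-n_ex])),
                        cumsum(ex_len))
    for (i in seq_len(n_ex)) {
      j <- if (strand == "+") i else n_ex - i + 1L
      value <- if (strand == "+") chunks[i] else revcomp(chunks[i])
      substr(chroms[[chrom]], ex[j, 1] + 1L, ex[j, 2]) <- value
    }
    cursors[[chrom]] <- pos + sample(500:1500, 1L)
    annotation[[length(annotation) + 1L]] <- list(
      transcript_id = sprintf("TX%02d", g),
      gene_id = sprintf("GENE%02d", g),
      biotype = if (is_lnc) "lncRNA" else "protein_coding",
      chrom = chrom,
      strand = strand,
      exons = ex,
      cds = cds
    )
  }
  structure(
    list(
      chromosomes = chroms,
      annotation = annotation,
      germline_snps = data.frame(
        chrom = character(0), pos0 = integer(0),
        ref = character(0), alt = character(0),
        stringsAsFactors = FALSE
      )
    ),
    class = "toy_genome"
  )
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", length(x$chromosomes), "chromosome(s),",
      sum(nchar(x$chromosomes)), "nt,",
      length(x$annotation), "transcript model(s)\n")
  invisible(x)
}

#' Build event requests for `plant_events()`
#'
#' @param kinds Character vector of event kinds
#'   (`aeTSA_intergenic`, `aeTSA_intron`, `aeTSA_lncRNA`, `aeTSA_utr`,
#'   `mTSA_snv`, `mTSA_frameshift`, `TAA_overexpressed`).
#' @param len Peptide length(s), 8-11 aa (recycled).
#' @param host Host transcript id(s) or `NA` (recycled); required for
#'   lncRNA/UTR/mTSA/TAA kinds when the default (first suitable
#'   transcript) is not wanted.
#' @param tumor_depth,normal_depth,mtec_depth Mean read coverage of the
#'   event locus in tumor, matched normal and mTEC samples (recycled).
#'   Defaults: tumor 20x; normal/mTEC 0 for aeTSA kinds; mTEC 20x for
#'   TAA kinds; host-locus coverage 20x everywhere for mTSA kinds.
#' @return Data frame of event requests.
#' @export
event_requests <- function(kinds, len = 9L, host = NA_character_,
                           tumor_depth = 20, normal_depth = NA,
                           mtec_depth = NA) {
  n <- length(kinds)
  valid <- c("aeTSA_intergenic", "aeTSA_intron", "aeTSA_lncRNA",
             "aeTSA_utr", "mTSA_snv", "mTSA_frameshift",
             "TAA_overexpressed")
  if (!all(kinds %in% valid)) {
    stop("unknown event kind(s): ",
         paste(setdiff(kinds, valid), collapse = ", "))
  }
  req <- data.frame(
    kind = kinds,
    len = as.integer(rep_len(len, n)),
    host = rep_len(host, n),
    tumor_depth = rep_len(tumor_depth, n),
    normal_depth = rep_len(normal_depth, n),
    mtec_depth = rep_len(mtec_depth, n),
    stringsAsFactors = FALSE
  )
  is_mtsa <- startsWith(req$kind, "mTSA")
  is_taa <- startsWith(req$kind, "TAA")
  req$normal_depth[is.na(req$normal_depth)] <-
    ifelse(is_mtsa[is.na(req$normal_depth)], 20, 0)
  req$mtec_depth[is.na(req$mtec_depth)] <-
    ifelse((is_mtsa | is_taa)[is.na(req$mtec_depth)], 20, 0)
  if (any(req$len < 8L | req$len > 11L)) stop("peptide length must be 8-11 aa")
  req
}

.empty_truth <- function() {
  data.frame(
    event_id = character(0), kind = character(0), peptide = character(0),
    mcs = character(0), chrom = character(0), start0 = integer(0),
    end0 = integer(0), strand = character(0),
    host_transcript = character(0), feature = character(0),
    f_start0 = integer(0), f_end0 = integer(0),
    snv_pos0 = integer(0), snv_ref = character(0), snv_alt = character(0),
    tumor_depth = numeric(0), normal_depth = numeric(0),
    mtec_depth = numeric(0), stringsAsFactors = FALSE
  )
}

# random peptide + one concrete coding sequence absent from `chroms`
.random_peptide_mcs <- function(len, chroms, max_il = 2L) {
  for (try in 1:500) {
    pep <- paste(sample(AA20, len, replace = TRUE), collapse = "")
    res <- strsplit(pep, "")[[1]]
    if (sum(res %in% c("I", "L")) > max_il) next
    if (prod(vapply(res, function(a) length(aa_codons(a)), numeric(1))) > 1e5) next
    mcs <- paste(vapply(res, function(a) sample(aa_codons(a), 1L),
                        character(1)), collapse = "")
    if (.count_occurrences(mcs, chroms) == 0L) {
      return(list(peptide = pep, mcs = mcs))
    }
  }
  stop("could not generate a unique planted coding sequence")
}

# intergenic gaps (>= min_len) on each chromosome, away from genes and
# previously used intervals
.intergenic_gaps <- function(genome, used, chrom_len_of, min_len) {
  gaps <- list()
  for (chrom in names(genome$chromosomes)) {
    occ <- list(c(0L, 200L))
    for (tx in genome$annotation) {
      if (tx$chrom == chrom) {
        sp <- .tx_span(tx)
        occ[[length(occ) + 1L]] <- c(sp[1] - 100L, sp[2] + 100L)
      }
    }
    if (nrow(used)) {
      uu <- used[used$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(uu))) {
        occ[[length(occ) + 1L]] <- c(uu$start0[i] - 50L, uu$end0[i] + 50L)
      }
    }
    L <- nchar(genome$chromosomes[[chrom]])
    occ[[length(occ) + 1L]] <- c(L - 200L, L)
    m <- do.call(rbind, occ)
    m <- m[order(m[, 1]), , drop = FALSE]
    # merge and invert
    cur <- m[1, ]
    merged <- list()
    for (i in seq_len(nrow(m))[-1]) {
      if (m[i, 1] <= cur[2]) cur[2] <- max(cur[2], m[i, 2])
      else { merged[[length(merged) + 1L]] <- cur; cur <- m[i, ] }
    }
    merged[[length(merged) + 1L]] <- cur
    mm <- do.call(rbind, merged)
    for (i in seq_len(nrow(mm) - 1L)) {
      gs <- mm[i, 2]; ge <- mm[i + 1L, 1]
      if (ge - gs >= min_len) {
        gaps[[length(gaps) + 1L]] <- list(chrom = chrom, start0 = gs, end0 = ge)
      }
    }
  }
  gaps
}

# find a spliced sub-interval of length `w` fully inside one exon and
# inside the spliced window [lo, hi); returns spliced start or NA
.exon_contained_start <- function(tx, lo, hi, w, frame_anchor = NULL) {
  ch <- .tx_chunks(tx)
  lens <- ch[, 2] - ch[, 1]
  cum <- c(0L, cumsum(lens))
  cand <- integer(0)
  for (i in seq_along(lens)) {
    s <- max(lo, cum[i]); e <- min(hi, cum[i + 1L])
    if (e - s < w) next
    pos <- s:(e - w)
    if (!is.null(frame_anchor)) pos <- pos[(pos - frame_anchor) %% 3L == 0L]
    cand <- c(cand, pos)
  }
  if (!length(cand)) return(NA_integer_)
  if (length(cand) == 1L) cand else sample(cand, 1L)
}

#' Plant antigen-generating events into a toy genome
#'
#' Aberrant-expression (aeTSA) and TAA events are reference sequences
#' that are only aberrantly *expressed* in the tumor, so their coding
#' sequences are written into both the reference and the tumor genome;
#' mutated kinds (`mTSA_snv`, `mTSA_frameshift`) alter the tumor genome
#' only. Each event's coding sequence is checked to occur exactly once
#' in the genome.
#'
#' @param genome A `toy_genome` from [make_toy_genome()].
#' @param requests Data frame from [event_requests()] (or a character
#'   vector of kinds).
#' @param seed Integer seed.
#' @return List with `reference` (normal genome), `genome` (tumor
#'   genome) and `truth` (data frame, one row per planted event with
#'   peptide, coding sequence, locus, depths and SNV details).
#' @export
plant_events <- function(genome, requests, seed) {
  set.seed(seed)
  if (is.character(requests)) requests <- event_requests(requests)
  ref <- genome
  if (!nrow(requests)) {
    return(list(reference = ref, genome = ref, truth = .empty_truth()))
  }
  is_ae <- startsWith(requests$kind, "aeTSA")
  is_taa <- startsWith(requests$kind, "TAA")
  if (any(is_ae & (requests$normal_depth != 0 | requests$mtec_depth != 0))) {
    stop("aeTSA events must have normal_depth = 0 and mtec_depth = 0")
  }
  if (any(is_taa & requests$tumor_depth < 10 * requests$normal_depth)) {
    stop("TAA events must have tumor_depth >= 10 x normal_depth")
  }
  truth <- .empty_truth()
  used <- data.frame(chrom = character(0), start0 = integer(0),
                     end0 = integer(0), stringsAsFactors = FALSE)
  flank <- 150L
  pc <- Filter(function(tx) tx$biotype == "protein_coding", ref$annotation)
  lnc <- Filter(function(tx) tx$biotype == "lncRNA", ref$annotation)
  find_tx <- function(id) {
    for (tx in ref$annotation) if (tx$transcript_id == id) return(tx)
    stop("unknown host transcript: ", id)
  }
  tumor_extra <- list()  # mutated writes, applied after the loop

  for (r in seq_len(nrow(requests))) {
    kind <- requests$kind[r]
    len <- requests$len[r]
    w <- 3L * len
    ev_id <- sprintf("EV%02d_%s", r, kind)
    host <- NA_character_
    feature <- "window"
    f_start0 <- NA_integer_; f_end0 <- NA_integer_
    snv_pos0 <- NA_integer_; snv_ref <- NA_character_; snv_alt <- NA_character_

    if (kind == "aeTSA_intergenic") {
      pm <- .random_peptide_mcs(len, ref$chromosomes)
      need <- w + 2L * flank + 40L
      gaps <- .intergenic_gaps(ref, used, NULL, need)
      if (!length(gaps)) stop("no intergenic space left for ", ev_id)
      gp <- gaps[[sample(length(gaps), 1L)]]
      strand <- sample(c("+", "-"), 1L)
      f_start0 <- gp$start0 + sample(0:(gp$end0 - gp$start0 - need), 1L) + 20L
      start0 <- f_start0 + flank
      end0 <- start0 + w
      f_end0 <- end0 + flank
      value <- if (strand == "+") pm$mcs else revcomp(pm$mcs)
      substr(ref$chromosomes[[gp$chrom]], start0 + 1L, end0) <- value
      chrom <- gp$chrom
    } else if (kind == "aeTSA_intron") {
      pm <- .random_peptide_mcs(len, ref$chromosomes)
      hosts <- if (!is.na(requests$host[r])) list(find_tx(requests$host[r])) else pc
      placed <- FALSE
      need <- w + 2L * flank
      for (tx in sample(hosts)) {
        if (nrow(tx$exons) < 2L) next
        for (i in seq_len(nrow(tx$exons) - 1L)) {
          is0 <- tx$exons[i, 2]; ie0 <- tx$exons[i + 1L, 1]
          if (ie0 - is0 < need + 40L) next
          f_start0 <- is0 + 20L
          f_end0 <- f_start0 + need
          start0 <- f_start0 + flank
          end0 <- start0 + w
          strand <- tx$strand
          value <- if (strand == "+") pm$mcs else revcomp(pm$mcs)
          substr(ref$chromosomes[[tx$chrom]], start0 + 1L, end0) <- value
          chrom <- tx$chrom; host <- tx$transcript_id
          placed <- TRUE
          break
        }
        if (placed) break
      }
      if (!placed) stop("no intron large enough for ", ev_id)
    } else if (kind == "aeTSA_lncRNA" || kind == "aeTSA_utr") {
      pm <- .random_peptide_mcs(len, ref$chromosomes)
      tx <- if (!is.na(requests$host[r])) find_tx(requests$host[r]) else {
        if (kind == "aeTSA_lncRNA") {
          if (!length(lnc)) stop("genome has no lncRNA for ", ev_id)
          lnc[[1L]]
        } else pc[[1L]]
      }
      # stay >= 50 nt from the spliced ends: reads must fully contain
      # each 24-mer, so edge-proximal windows are undercovered
      edge <- 50L
      if (kind == "aeTSA_lncRNA") {
        lo <- edge; hi <- spliced_length(tx) - edge
      } else {
        if (is.null(tx$cds)) stop("aeTSA_utr host must be protein-coding")
        lo <- edge; hi <- tx$cds[1]   # 5' UTR
      }
      sp <- .exon_contained_start(tx, lo, hi, w)
      if (is.na(sp)) stop("no exon-contained room in host for ", ev_id)
      ref$chromosomes[[tx$chrom]] <-
        .write_spliced(ref$chromosomes[[tx$chrom]], tx, sp, pm$mcs)
      b <- genomic_blocks(tx, sp, sp + w)
      chrom <- tx$chrom; strand <- tx$strand
      start0 <- b[1, 1]; end0 <- b[nrow(b), 2]
      host <- tx$transcript_id
      feature <- "transcript"
    } else if (kind == "mTSA_snv") {
      tx <- if (!is.na(requests$host[r])) find_tx(requests$host[r]) else pc[[1L]]
      if (is.null(tx$cds)) stop("mTSA_snv host must be protein-coding")
      # in-frame window of `len` codons inside one exon, clear of the
      # start/stop codons
      sp <- .exon_contained_start(tx, tx$cds[1] + 3L, tx$cds[2] - 3L - w,
                                  w, frame_anchor = tx$cds[1])
      if (is.na(sp)) stop("no exon-contained CDS window for ", ev_id)
      wt_nt <- substr(spliced_seq(tx, ref), sp + 1L, sp + w)
      mid <- (len %/% 2L)                   # 0-based codon index in window
      wt_codon <- substr(wt_nt, 3L * mid + 1L, 3L * mid + 3L)
      cands <- list()
      for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"),
                                        substr(wt_codon, p, p))) {
        alt_codon <- wt_codon
        substr(alt_codon, p, p) <- nt
        if (Biostrings::GENETIC_CODE[[alt_codon]] != "*" &&
            Biostrings::GENETIC_CODE[[alt_codon]] !=
            Biostrings::GENETIC_CODE[[wt_codon]]) {
          cands[[length(cands) + 1L]] <- list(p = p, codon = alt_codon)
        }
      }
      pick <- cands[[sample(length(cands), 1L)]]
      mut_nt <- wt_nt
      substr(mut_nt, 3L * mid + pick$p, 3L * mid + pick$p) <-
        substr(pick$codon, pick$p, pick$p)
      if (.count_occurrences(mut_nt, ref$chromosomes) != 0L) {
        stop("mutated coding sequence collides with the reference")
      }
      pm <- list(peptide = translate_nt(mut_nt), mcs = mut_nt)
      sp_snv <- sp + 3L * mid + pick$p - 1L
      b1 <- genomic_blocks(tx, sp_snv, sp_snv + 1L)
      snv_pos0 <- b1[1, 1]
      snv_ref <- substr(ref$chromosomes[[tx$chrom]], snv_pos0 + 1L, snv_pos0 + 1L)
      tumor_extra[[length(tumor_extra) + 1L]] <-
        list(tx = tx, sp = sp, nt = mut_nt)
      snv_alt <- if (tx$strand == "+") {
        substr(pick$codon, pick$p, pick$p)
      } else revcomp(substr(pick$codon, pick$p, pick$p))
      b <- genomic_blocks(tx, sp, sp + w)
      chrom <- tx$chrom; strand <- tx$strand
      start0 <- b[1, 1]; end0 <- b[nrow(b), 2]
      host <- tx$transcript_id
      feature <- "transcript"
    } else if (kind == "mTSA_frameshift") {
      tx <- if (!is.na(requests$host[r])) find_tx(requests$host[r]) else pc[[1L]]
      if (is.null(tx$cds)) stop("mTSA_frameshift host must be protein-coding")
      placed <- FALSE
      for (try in 1:300) {
        pm_try <- .random_peptide_mcs(len, ref$chromosomes)
        sp <- .exon_contained_start(tx, tx$cds[1] + 4L, tx$cds[2] - 6L - w, w)
        if (is.na(sp)) stop("no exon-contained CDS window for ", ev_id)
        # +1/+2 frame relative to the CDS
        if ((sp - tx$cds[1]) %% 3L == 0L) sp <- sp + 1L
        mut_sp <- spliced_seq(tx, ref)
        substr(mut_sp, sp + 1L, sp + w) <- pm_try$mcs
        cds_aa <- translate_nt(substr(mut_sp, tx$cds[1] + 1L, tx$cds[2] - 3L))
        if (!grepl("*", cds_aa, fixed = TRUE)) {
          pm <- pm_try
          tumor_extra[[length(tumor_extra) + 1L]] <-
            list(tx = tx, sp = sp, nt = pm$mcs)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not plant a stop-free frameshift for ", ev_id)
      b <- genomic_blocks(tx, sp, sp + w)
      chrom <- tx$chrom; strand <- tx$strand
      start0 <- b[1, 1]; end0 <- b[nrow(b), 2]
      host <- tx$transcript_id
      feature <- "transcript"
    } else if (kind == "TAA_overexpressed") {
      tx <- if (!is.na(requests$host[r])) find_tx(requests$host[r]) else pc[[length(pc)]]
      if (is.null(tx$cds)) stop("TAA host must be protein-coding")
      sp <- .exon_contained_start(tx, tx$cds[1] + 3L, tx$cds[2] - 3L - w,
                                  w, frame_anchor = tx$cds[1])
      if (is.na(sp)) stop("no exon-contained CDS window for ", ev_id)
      nt <- substr(spliced_seq(tx, ref), sp + 1L, sp + w)
      pm <- list(peptide = translate_nt(nt), mcs = nt)
      b <- genomic_blocks(tx, sp, sp + w)
      chrom <- tx$chrom; strand <- tx$strand
      start0 <- b[1, 1]; end0 <- b[nrow(b), 2]
      host <- tx$transcript_id
      feature <- "transcript"
    }

    used <- rbind(used, data.frame(chrom = chrom, start0 = start0,
                                   end0 = end0, stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      event_id = ev_id, kind = kind, peptide = pm$peptide, mcs = pm$mcs,
      chrom = chrom, start0 = as.integer(start0), end0 = as.integer(end0),
      strand = strand, host_transcript = host, feature = feature,
      f_start0 = f_start0, f_end0 = f_end0,
      snv_pos0 = snv_pos0, snv_ref = snv_ref, snv_alt = snv_alt,
      tumor_depth = requests$tumor_depth[r],
      normal_depth = requests$normal_depth[r],
      mtec_depth = requests$mtec_depth[r],
      stringsAsFactors = FALSE
    ))
  }

  rownames(truth) <- NULL
  tumor <- ref
  for (tw in tumor_extra) {
    tumor$chromosomes[[tw$tx$chrom]] <-
      .write_spliced(tumor$chromosomes[[tw$tx$chrom]], tw$tx, tw$sp, tw$nt)
  }
  list(reference = ref, genome = tumor, truth = truth)
}

#' Construct a read set
#'
#' @param sample_id Sample label.
#' @param reads Character vector of fixed-length reads.
#' @param stranded Whether reads are in transcript (sense) orientation.
#' @param total_reads Library size used for per-hundred-million
#'   normalization; defaults to `length(reads)`. May be set larger to
#'   emulate a deep library of which only the reads over features of
#'   interest were materialized.
#' @return A `read_set` object.
#' @export
read_set <- function(sample_id, reads, stranded = TRUE,
                     total_reads = length(reads)) {
  structure(
    list(sample_id = sample_id, reads = reads,
         total_reads = total_reads, stranded = stranded),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set '", x$sample_id, "': ", length(x$reads), " reads (rtot ",
      format(x$total_reads, scientific = TRUE), ", ",
      if (x$stranded) "stranded" else "unstranded", ")\n", sep = "")
  invisible(x)
}

#' Simulate an error-free stranded read set
#'
#' Reads are drawn uniformly along each expressed feature's spliced
#' sequence in sense orientation (an optional fraction is flipped to
#' antisense). Features are transcript ids from the genome annotation
#' or event ids from a `plant_events()` truth table (window events are
#' read from their genomic window).
#'
#' @param genome The genome to read from (tumor or reference).
#' @param profile Named numeric vector: feature id -> mean coverage.
#' @param read_len Read length in nt.
#' @param seed Integer seed.
#' @param truth Optional truth table resolving event ids.
#' @param sample_id Sample label.
#' @param library_size Declared library size (see [read_set()]).
#' @param antisense_frac Fraction of reads emitted as reverse
#'   complements.
#' @return A `read_set`.
#' @export
simulate_reads <- function(genome, profile, read_len = 75L, seed = 1L,
                           truth = NULL, sample_id = "sample",
                           library_size = NULL, antisense_frac = 0) {
  set.seed(seed)
  if (any(profile < 0)) stop("depths must be >= 0")
  tx_ids <- vapply(genome$annotation, `[[`, character(1), "transcript_id")
  reads <- list()
  for (fid in names(profile)) {
    depth <- profile[[fid]]
    if (depth <= 0) next
    if (fid %in% tx_ids) {
      fs <- spliced_seq(genome$annotation[[match(fid, tx_ids)]], genome)
    } else if (!is.null(truth) && fid %in% truth$event_id) {
      tr <- truth[truth$event_id == fid, ]
      if (tr$feature != "window") {
        stop("event ", fid, " is expressed through its host transcript; ",
             "put the host transcript id in the profile")
      }
      s <- substr(genome$chromosomes[[tr$chrom]], tr$f_start0 + 1L, tr$f_end0)
      fs <- if (tr$strand == "+") s else revcomp(s)
    } else {
      stop("unknown feature in profile: ", fid)
    }
    L <- nchar(fs)
    if (read_len > L) stop("read_len exceeds feature length for ", fid)
    n <- round(depth * L / read_len)
    if (n == 0L) next
    starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
    r <- substring(fs, starts, starts + read_len - 1L)
    if (antisense_frac > 0) {
      flip <- stats::runif(n) < antisense_frac
      if (any(flip)) r[flip] <- revcomp(r[flip])
    }
    reads[[length(reads) + 1L]] <- r
  }
  reads <- if (length(reads)) unlist(reads, use.names = FALSE) else character(0)
  read_set(sample_id, reads, stranded = TRUE,
           total_reads = library_size %||% length(reads))
}

#' Canonical proteome of a toy genome
#'
#' Translates every annotated protein-coding CDS (reference alleles),
#' dropping the terminal stop.
#'
#' @param genome A `toy_genome`.
#' @param transcript_ids Optional subset of transcript ids.
#' @return Data frame with columns `header` and `seq`.
#' @export
canonical_proteome <- function(genome, transcript_ids = NULL) {
  rows <- list()
  for (tx in genome$annotation) {
    if (tx$biotype != "protein_coding" || is.null(tx$cds)) next
    if (!is.null(transcript_ids) && !(tx$transcript_id %in% transcript_ids)) next
    aa <- translate_nt(substr(spliced_seq(tx, genome),
                              tx$cds[1] + 1L, tx$cds[2]))
    aa <- sub("\\*$", "", aa)
    rows[[length(rows) + 1L]] <- data.frame(
      header = tx$transcript_id, seq = aa, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows) %||%
    data.frame(header = character(0), seq = character(0))
}

#' Simulate a search-engine identification table
#'
#' Every planted peptide appears as a high-scoring target with binding
#' rank below 2%; filler targets are substrings (7-13 aa) of the
#' supplied proteome; decoys are reversed sequences with a clearly
#' lower score distribution. Score ranges are separated so that planted
#' peptides always survive a 5% decoy-based FDR.
#'
#' @param truth Truth table from [plant_events()] (may have 0 rows).
#' @param proteome Data frame header/seq (canonical entries).
#' @param n_targets Total number of target records (>= planted count).
#' @param n_decoys Number of decoy records.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return Data frame of identification records (peptide, sample_id,
#'   score, is_decoy, best_allele, percent_rank, source_accession,
#'   db_origin).
#' @export
simulate_identifications <- function(truth, proteome, n_targets = 45L,
                                     n_decoys = 25L, seed = 1L,
                                     sample_id = "tumor") {
  set.seed(seed)
  planted <- unique(truth$peptide)
  if (n_targets < length(planted)) {
    stop("n_targets must be >= number of planted peptides")
  }
  n_fill <- n_targets - length(planted)
  fillers <- character(0)
  guard <- 0L
  while (length(fillers) < n_fill) {
    guard <- guard + 1L
    if (guard > 50L * n_fill + 100L) stop("proteome too small for fillers")
    e <- proteome$seq[sample(nrow(proteome), 1L)]
    len <- sample(7:13, 1L)
    if (nchar(e) < len) next
    s <- sample(nchar(e) - len + 1L, 1L)
    p <- substr(e, s, s + len - 1L)
    if (p %in% c(planted, fillers)) next
    fillers <- c(fillers, p)
  }
  targets <- data.frame(
    peptide = c(planted, fillers),
    sample_id = sample_id,
    score = c(stats::runif(length(planted), 80, 100),
              stats::runif(n_fill, 40, 70)),
    is_decoy = FALSE,
    best_allele = "HLA-A*02:01",
    percent_rank = c(stats::runif(length(planted), 0.05, 1.9),
                     stats::runif(n_fill, 0.1, 3.5)),
    source_accession = c(
      if (length(planted)) paste0("csdb|", truth$event_id[match(planted, truth$peptide)]) else character(0),
      rep("canonical", n_fill)
    ),
    db_origin = c(rep("cancer_specific", length(planted)),
                  rep("canonical", n_fill)),
    stringsAsFactors = FALSE
  )
  decoys <- if (n_decoys > 0L) {
    src <- sample(targets$peptide, n_decoys, replace = TRUE)
    data.frame(
      peptide = vapply(strsplit(src, ""), function(x)
        paste(rev(x), collapse = ""), character(1)),
      sample_id = sample_id,
      score = stats::runif(n_decoys, 5, 35),
      is_decoy = TRUE,
      best_allele = "HLA-A*02:01",
      percent_rank = stats::runif(n_decoys, 0.1, 5),
      source_accession = "decoy",
      db_origin = "decoy",
      stringsAsFactors = FALSE
    )
  } else NULL
  out <- rbind(targets, decoys)
  rownames(out) <- NULL
  out[sample(nrow(out)), , drop = FALSE]
}
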