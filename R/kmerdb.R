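# Cancer-specific database construction: k-mer counting, tumor-minus-
# normal subtraction, unitig contig assembly, three-frame translation
# and "JJ"-separated global database assembly.

#' Construct a k-mer set
#' @keywords internal
.kmer_set <- function(k, counts, rtot, canonical) {
  structure(
    list(k = as.integer(k), counts = counts, rtot = rtot,
         canonical = canonical),
    class = "kmer_set"
  )
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("kmer_set: k =", x$k, if (x$canonical) "(canonical)" else "",
      "|", length(x$counts), "distinct k-mers | rtot =",
      format(x$rtot, scientific = TRUE), "\n")
  invisible(x)
}

#' Count k-mers in a read set
#'
#' Slides a window of length `k` over every read; windows containing
#' non-ACGT characters are skipped. With `canonical = TRUE` a k-mer and
#' its reverse complement are merged under the lexicographically
#' smaller key (the usual `-C` convention of k-mer counters).
#'
#' @param reads A `read_set`, or a plain character vector of reads.
#' @param k K-mer length in nt (must not exceed the read length).
#' @param canonical Merge reverse complements.
#' @return A `kmer_set` with occurrence counts and the library total
#'   `rtot`.
#' @export
count_kmers <- function(reads, k, canonical = FALSE) {
  if (inherits(reads, "read_set")) {
    rtot <- reads$total_reads
    seqs <- reads$reads
  } else {
    rtot <- length(reads)
    seqs <- reads
  }
  if (length(seqs) && k > max(nchar(seqs))) {
    stop("k exceeds the read length")
  }
  wins <- sliding_kmers(seqs, k)
  if (length(wins)) {
    wins <- wins[!grepl("[^ACGT]", wins)]
    if (canonical) wins <- canonical_kmer(wins)
    tab <- table(wins)
    counts <- stats::setNames(as.integer(tab), names(tab))
  } else {
    counts <- stats::setNames(integer(0), character(0))
  }
  .kmer_set(k, counts, rtot, canonical)
}

#' Subtract normal k-mers from a tumor k-mer set
#'
#' Retains tumor k-mers whose occurrence across the normal libraries is
#' below `max_count` (default: present < 2, i.e. seen at most once).
#' Retained counts are the tumor counts.
#'
#' @param tumor A `kmer_set`.
#' @param normals A `kmer_set` or list of `kmer_set`s with matching `k`
#'   and canonical flag.
#' @param max_count Occurrence threshold; k-mers with normal occurrence
#'   `>= max_count` are removed.
#' @param mode `"pooled"` compares the summed occurrence across all
#'   normal libraries; `"per_sample"` compares the per-library maximum.
#' @return A `kmer_set` of cancer-specific k-mers.
#' @export
subtract_normal <- function(tumor, normals, max_count = 2L,
                            mode = c("pooled", "per_sample")) {
  mode <- match.arg(mode)
  if (inherits(normals, "kmer_set")) normals <- list(normals)
  for (nrm in normals) {
    if (nrm$k != tumor$k || nrm$canonical != tumor$canonical) {
      stop("k and canonical flag must match across k-mer sets")
    }
  }
  keys <- names(tumor$counts)
  agg <- numeric(length(keys))
  for (nrm in normals) {
    v <- unname(nrm$counts[keys])
    v[is.na(v)] <- 0L
    agg <- if (mode == "pooled") agg + v else pmax(agg, v)
  }
  keep <- agg < max_count
  .kmer_set(tumor$k, tumor$counts[keep], tumor$rtot, tumor$canonical)
}

#' Assemble k-mers into unitig contigs
#'
#' Builds the de Bruijn graph on (k-1)-mer overlaps of the distinct
#' k-mers and emits maximal non-branching paths: extension stops at any
#' node with in- or out-degree other than one. Every input k-mer
#' appears in exactly one contig. Isolated cycles are emitted once,
#' starting from their lexicographically smallest k-mer; output contigs
#' are sorted lexicographically.
#'
#' @param kmers A non-empty `kmer_set`.
#' @return Data frame with columns `sequence` and `n_kmers`.
#' @export
assemble_contigs <- function(kmers) {
  keys <- sort(names(kmers$counts))
  if (!length(keys)) stop("empty k-mer set")
  k <- kmers$k
  pre <- substr(keys, 1L, k - 1L)
  suf <- substr(keys, 2L, k)
  nodes <- unique(c(pre, suf))
  pre_i <- match(pre, nodes)
  suf_i <- match(suf, nodes)
  out_deg <- tabulate(pre_i, length(nodes))
  in_deg <- tabulate(suf_i, length(nodes))
  node11 <- in_deg == 1L & out_deg == 1L
  out_edge <- rep(NA_integer_, length(nodes))
  out_edge[pre_i] <- seq_along(keys)  # valid where out_deg == 1
  visited <- logical(length(keys))
  walk <- function(e0) {
    path <- e0
    visited[e0] <<- TRUE
    repeat {
      v <- suf_i[path[length(path)]]
      if (!node11[v]) break
      nxt <- out_edge[v]
      if (is.na(nxt) || visited[nxt]) break
      path <- c(path, nxt)
      visited[nxt] <<- TRUE
    }
    path
  }
  seqs <- character(0)
  nk <- integer(0)
  emit <- function(path) {
    ext <- if (length(path) > 1L) {
      paste(substr(keys[path[-1L]], k, k), collapse = "")
    } else ""
    seqs <<- c(seqs, paste0(keys[path[1L]], ext))
    nk <<- c(nk, length(path))
  }
  starts <- which(!node11[pre_i])
  for (e in starts) if (!visited[e]) emit(walk(e))
  # remaining edges lie on isolated cycles
  while (any(!visited)) {
    rem <- which(!visited)
    emit(walk(rem[order(keys[rem])[1L]]))
  }
  ord <- order(seqs)
  data.frame(sequence = seqs[ord], n_kmers = nk[ord],
             stringsAsFactors = FALSE)
}

#' Three-frame translation of a contig
#'
#' Translates the three sense-strand frames (the libraries are
#' stranded), splits at stop codons and drops fragments shorter than
#' `min_len`. Set `six_frame = TRUE` for unstranded input.
#'
#' @param contig A contig sequence (or one row of
#'   [assemble_contigs()] output).
#' @param min_len Minimum fragment length in aa.
#' @param six_frame Also translate the reverse-complement frames.
#' @return Character vector of peptide fragments (frame order, then
#'   position order).
#' @export
translate_3frame <- function(contig, min_len = 8L, six_frame = FALSE) {
  if (is.data.frame(contig)) contig <- contig$sequence
  stopifnot(length(contig) == 1L)
  strands <- if (six_frame) c(contig, revcomp(contig)) else contig
  frags <- character(0)
  for (s in strands) {
    for (f in 0:2) {
      if (nchar(s) - f < 3L) next
      aa <- translate_nt(substr(s, f + 1L, nchar(s)))
      parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
      frags <- c(frags, parts[nchar(parts) >= min_len])
    }
  }
  frags
}

#' Assemble the global cancer database
#'
#' Cancer-specific peptide fragments are sorted, then greedily packed
#' into entries of at most `target_len` residues using the two-
#' character separator `"JJ"` (recognizable downstream because `J` is
#' not a standard residue); canonical entries pass through untouched.
#'
#' @param canonical Data frame header/seq of canonical proteome
#'   entries (may be `NULL`).
#' @param fragments Character vector of cancer-specific aa fragments.
#' @param target_len Entry length cap in aa.
#' @return A `proteome_db`: data frame with columns `header`, `seq`,
#'   `origin` (`canonical` or `cancer_specific`).
#' @export
build_global_db <- function(canonical, fragments, target_len = 10000L) {
  if (is.null(canonical)) {
    canonical <- data.frame(header = character(0), seq = character(0),
                            stringsAsFactors = FALSE)
  }
  if (!length(fragments) && !nrow(canonical)) {
    stop("nothing to assemble: no fragments and no canonical entries")
  }
  if (any(grepl("J", fragments, fixed = TRUE))) {
    stop("fragments must not contain the separator residue 'J'")
  }
  entries <- character(0)
  if (length(fragments)) {
    fragments <- sort(fragments)
    cur <- fragments[1L]
    for (f in fragments[-1L]) {
      if (nchar(cur) + 2L + nchar(f) <= target_len) {
        cur <- paste0(cur, "JJ", f)
      } else {
        entries <- c(entries, cur)
        cur <- f
      }
    }
    entries <- c(entries, cur)
  }
  db <- rbind(
    if (nrow(canonical)) data.frame(header = canonical$header,
                                    seq = canonical$seq,
                                    origin = "canonical",
                                    stringsAsFactors = FALSE),
    if (length(entries)) data.frame(
      header = sprintf("csdb_%04d", seq_along(entries)),
      seq = entries, origin = "cancer_specific",
      stringsAsFactors = FALSE
    )
  )
  rownames(db) <- NULL
  structure(db, class = c("proteome_db", "data.frame"))
}

#' Recover the fragments packed into a global database
#'
#' Splits every cancer-specific entry on the `"JJ"` separator; the
#' round trip through [build_global_db()] is lossless.
#'
#' @param db A `proteome_db`.
#' @return Character vector of fragments.
#' @export
db_fragments <- function(db) {
  entries <- db$seq[db$origin == "cancer_specific"]
  if (!length(entries)) return(character(0))
  unlist(strsplit(entries, "JJ", fixed = TRUE), use.names = FALSE)
}

#' Build the cancer-specific proteome from read sets
#'
#' The full database-generation path: 33-nt k-mer counting of the
#' tumor library, subtraction of the normal libraries (occurrence
#' < `max_count`), unitig assembly, three-frame translation and
#' packing into a global database alongside the canonical proteome.
#'
#' @param tumor_reads A `read_set`.
#' @param normal_reads A `read_set` or list of `read_set`s.
#' @param canonical Data frame header/seq (canonical proteome).
#' @param k K-mer length (33 by default; non-canonical counting for
#'   stranded libraries).
#' @param max_count Subtraction threshold (see [subtract_normal()]).
#' @param min_fragment Minimum translated fragment length in aa.
#' @param target_len Database entry length cap in aa.
#' @return A `proteome_db`.
#' @export
build_cancer_db <- function(tumor_reads, normal_reads, canonical = NULL,
                            k = 33L, max_count = 2L, min_fragment = 8L,
                            target_len = 10000L) {
  if (inherits(normal_reads, "read_set")) normal_reads <- list(normal_reads)
  tum <- count_kmers(tumor_reads, k, canonical = FALSE)
  nrm <- lapply(normal_reads, count_kmers, k = k, canonical = FALSE)
  spec <- subtract_normal(tum, nrm, max_count = max_count)
  frags <- character(0)
  if (length(spec$counts)) {
    contigs <- assemble_contigs(spec)
    frags <- unlist(lapply(contigs$sequence, translate_3frame,
                           min_len = min_fragment), use.names = FALSE)
  }
  build_global_db(canonical, frags, target_len = target_len)
}
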