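---
title: "Proteogenomic discovery of tumor-specific antigens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic discovery of tumor-specific antigens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsascan)
```

## The problem

Tumor-specific antigens (TSAs) are MHC class I-associated peptides
(MAPs) presented at the surface of tumor cells and absent from normal
tissues, which makes them candidate targets for T-cell-based
immunotherapy. Most actionable TSAs do not come from somatic coding
mutations: they arise from *aberrant expression* of genomic regions
that are transcriptionally silent in normal tissues — introns,
intergenic regions, lncRNAs, UTRs and out-of-frame exonic reading
frames. Such peptides are invisible to annotation-driven variant
calling pipelines, so their discovery requires a proteogenomic
approach: a sample-specific protein database built directly from
tumor RNA-seq, searched against immunopeptidomic mass spectrometry,
followed by an expression-based cascade that separates genuine TSAs
from tumor-associated antigens (TAAs, overexpressed but not
tumor-exclusive) and from normally expressed background.

`tsascan` implements that full analysis path at desk scale, together
with a synthetic-study generator whose planted ground truth lets every
filter of the cascade be validated by parameter recovery.

## Cancer-specific database construction

Tumor RNA-seq reads are cut into 33-nt k-mers (non-canonical counting:
the libraries are stranded, so sense orientation is informative). Any
k-mer whose pooled occurrence across the normal libraries (matched
normal tissue, or an mTEC pool standing in for central-tolerance
expression) reaches 2 is discarded; the surviving tumor-specific
k-mers are assembled into unitigs — maximal non-branching paths of the
de Bruijn graph on (k-1)-mer overlaps — and three-frame translated on
the sense strand, splitting at stop codons and dropping fragments
shorter than 8 aa (the shortest MAP retained downstream). Fragments
are packed into database entries of at most 10,000 residues joined by
the two-character separator `JJ` (J is not a standard residue, so the
packing is losslessly reversible), and concatenated with the canonical
proteome into the global search database.

Design points worth noting:

* *Subtraction semantics.* "Occurrence below 2" is read as the pooled
  sum across all normal libraries (the strictest reading); a
  per-library maximum is available via `mode = "per_sample"` in
  `subtract_normal()`.
* *Assembly determinism.* Extension stops at any node with in- or
  out-degree other than one; isolated cycles are emitted once starting
  from their lexicographically smallest k-mer, and output is sorted
  lexicographically. A periodic source string whose k-mer multiset
  contains repeats is not uniquely reconstructible from the distinct
  k-mer set — the assembly tests therefore use non-repetitive sources,
  where reconstruction is exact.
* *Three frames, not six.* Stranded libraries put every read in
  transcript orientation; `six_frame = TRUE` exists for unstranded
  input.

## From identifications to an immunopeptidome

Search-engine output is filtered in this order: decoy-based FDR at 5%
(the lowest score threshold *t* with
`#decoys(score >= t) / #targets(score >= t) <= 0.05`; ties at the
threshold are kept, and the absence of decoys leaves the FDR undefined
— all targets are returned under a warning); then peptide length 8-11
aa inclusive; then predicted eluted-ligand rank at most 2%. FDR is
applied first because the downstream filters can only lower the
effective FDR of what remains. Peptide sets are compared with the
Jaccard index, and source genes are deduplicated per sample (a gene
generating several unique peptides counts once) before sharing
analysis.

## Quantifying peptide-coding sequences

A MAP-coding sequence (MCS) is any nucleotide sequence able to encode
a peptide. `reverse_translate()` reports the exact number of MCSs (the
product of per-residue codon degeneracies) and a positionwise
IUPAC-degenerate pattern. Because the positionwise pattern is a strict
superset of the true MCS set (e.g. `YTN` for Leu also covers Phe
codons), every degenerate match against the genome or the spliced
transcriptome is verified by translation before being reported — this
gives exactly the result of enumerating all MCSs, with bounded memory,
and replaces an external aligner since only perfect matches are kept
anyway. Transcriptome hits crossing an exon junction are projected
back to genomic blocks and flagged as spliced.

Two expression measures are attached to each peptide:

* **KPHM** (k-mers per hundred million reads): each located MCS is cut
  into 24-nt windows, looked up in a canonical 24-mer set of the
  sample (k-mer and reverse complement merged, matching `-C`-style
  counting), and summarized by its minimum occurrence `kmin` — an
  estimate of the number of reads fully overlapping the MCS, since a
  k-mer originates from a single read. Then
  `kphm = kmin * 1e8 / rtot`, with `rtot` the library size. When a
  peptide has several genomic MCSs the *most expressed* one (argmax of
  `kmin` in the cancer sample, ties broken lexicographically) is used,
  consistently across samples; `mode = "single"` pins a specific MCS.
* **RPHM** (reads per hundred million): the number of reads fully
  containing an MCS as an exact substring (sense strand; the reverse
  complement is also checked for unstranded sets), normalized as
  `rphm = reads * 1e8 / rtot`. Partial overlaps do not count.

Both are exactly invariant under duplicating the whole library while
doubling `rtot`.

## The classification cascade

Candidates surviving the immunopeptidome filters pass through, in
order:

1. **Expression gate** — coding-sequence expression at least 10-fold
   higher in cancer than in matched normal *and* below 2 KPHM in
   normal (strict). The rule is multiplicative and division-free: a
   normal KPHM of exactly 0 passes with an infinite fold change, no
   pseudocounts. An undetected candidate (cancer KPHM 0) never
   passes.
2. **I/L disambiguation** — isoleucine and leucine are isobaric, so
   all `2^m` I/L substitution variants are enumerated (capped at `m <=
   10`; beyond that, single substitutions with a warning) and the
   candidate is kept only if it is itself the most expressed variant
   in cancer and passes the gate.
3. **Normal-panel screen** — the MCS must stay strictly below 8.55
   RPHM in the mTEC pool and every panel tissue. Tissues with low MHC
   class I expression (brain, nerve, testis) can be exempted;
   above-threshold expression in an exempt testis annotates the
   candidate as a potential cancer-testis antigen rather than
   excluding it.
4. **Localization screen** — candidates with no perfect placement,
   with more than 5 distinct placements ("unclear localization",
   configurable), or overlapping a configured hypervariable region
   (HLA/Ig/TCR) are excluded. The genomic region of the top-expressed
   placement is assigned with precedence CDS-exon > UTR5/UTR3 > lncRNA
   > intron > intergenic; in-CDS hits off the annotated frame are
   `exon_frameshift`. Only same-strand transcript overlaps are
   considered (the libraries are stranded; purely antisense overlap
   classifies as intergenic).
5. **Final label** — the placement is compared with the reference
   genome: a peptide differing from the reference translation through
   a variant not listed as a germline polymorphism is an **mTSA**.
   Otherwise, with fold change at least 10: **aeTSA** if mTEC (and,
   for tissues, NAT) expression is at most 0.2 KPHM (inclusive), and
   **TAA** if it exceeds 0.2 KPHM (exclusive) — the boundary
   semantics are deliberate and tested at 0.2 versus 0.2000001.
   Candidate calls are emitted independently per (peptide, sample).
   One fold value (cancer versus matched normal) is reused throughout
   the cascade.

The source transcript is the most highly expressed (TPM)
transcript overlapping the chosen locus, ties broken by
lexicographically smallest id and flagged; peptides with no
overlapping transcript are `unannotated`.

## Intertumoral sharing

For cohort matrices of RPHM values, the normal baseline of a peptide
is the mean of `log10(rphm + 1)` over all pooled normal-panel and mTEC
columns, back-transformed (`10^mean - 1`); base 10 is the default
(`log_base` is configurable) and the fold comparison is performed on
the linear scale against the back-transformed baseline (a log-scale
option exists, since either arithmetic is defensible). A peptide is
counted in a tumor when its RPHM reaches 10-fold the baseline; with a
zero baseline the rule stays division-free and any positive expression
counts. The peptide is *shared* when that fraction reaches 5%
(inclusive).

## TMT quantitation

`labeling_efficiency()` is the labeled-over-total PSM proportion.
`ms3_ratio()` mirrors SPS-MS3 practice for the tissue TMT layout (NAT
in 126, tumor in 127N, 127C left empty as a contamination control):
PSMs with signal in the empty channel above an absolute tolerance
(default 0 — any real signal disqualifies) are dropped, only PSMs at
or above the 70th percentile of total reporter intensity are kept
(high-intensity PSMs are the reliable ones; the opposite reading is
available via `keep = "below"`), and the ratio is the mean 127N over
mean 126 intensity, `NA`/not-quantifiable when nothing survives. The
ratio is invariant to a global intensity scale.
`spectral_correlation()` computes Pearson r over square-root-scaled
intensities of fragments shared between an endogenous and a synthetic
spectrum (at least 3), validating a pair at `r >= 0.6`; it is
symmetric and invariant to per-spectrum positive scaling.

## The synthetic study: what it emulates and what it does not

`toy_study()` builds a self-contained study: a two-chromosome genome
(50 kb each) carrying eight multi-exon protein-coding genes and two
lncRNAs; nine planted events (two intergenic, two intronic, one
lncRNA, one 5'-UTR aberrant-expression event, one somatic SNV, two
overexpressed TAAs); stranded, error-free, single-end 75-nt read sets
for tumor, matched NAT, an mTEC pool and three panel tissues at 20x
mean coverage of expressed features (10x for panel housekeeping); and
a simulated identification table with decoys. These sizes are the
package's default study conditions; they keep the whole discovery
cascade, including 20-seed recovery suites, comfortably fast while
every filter still operates away from its trivial regime.

Aberrant-expression and TAA events are *reference* sequences written
into both the reference and tumor genome and expressed only where the
event says so — tumor specificity is transcriptional, exactly as for
real aeTSAs, so the reference-genome mutation check stays meaningful.
Only mutated kinds (SNV, frameshift) alter the tumor genome alone.
Planted coding sequences are verified to occur exactly once in the
genome, SNVs sit at the center of their peptide window (so every
24-mer of the mutant MCS covers the variant and normal libraries
contribute zero mutant k-mers), and lncRNA/UTR events are placed at
least 50 nt from spliced-transcript ends because a read must fully
contain a 24-mer — windows closer to a feature edge than roughly
`read_len - k` are systematically undercovered.

Reads are materialized only over expressed features, while each
sample declares a library size on the scale the per-hundred-million
thresholds assume: 1e8 reads for tumor and NAT and 4e8 for the pooled
mTEC and panel libraries, matching the order of magnitude of the deep
and pooled sequencing such thresholds are calibrated for. With a
truly toy denominator every detected k-mer would exceed 2 KPHM and
8.55 RPHM at once, collapsing the aeTSA/TAA distinction; the declared
library size keeps the cascade's operating point realistic, and
`total_reads` defaults to the materialized read count whenever no
library size is declared.

The generator deliberately omits sequencing errors, quality values,
PCR duplicates, paired ends, fragment-length distributions, diploid
phasing, isoform diversity, expression noise beyond uniform sampling,
and spectral simulation (identification tables are drawn with
well-separated score distributions so that decoy filtering is exact).
Passing recovery tests therefore demonstrates that the *logic* of the
cascade — thresholds, boundary semantics, coordinate arithmetic,
frame handling, subtraction and assembly — is correct, not that the
pipeline is robust to alignment artifacts, sequencing noise or search
ambiguity in real data.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open throughout; strands `+`/`-`.
* All tie-breaks are lexicographic (contig output order, most
  expressed MCS, source-transcript ties) so every result is
  deterministic and order-independent.
* KPHM/RPHM formulas are exact rational arithmetic in doubles; the
  tests assert them to machine precision.
* Zero denominators are handled by rule, not by pseudocount: normal
  KPHM 0 gives an infinite fold change; RPHM on an empty library is
  an error; a zero sharing baseline switches to the positive-count
  rule; an empty normal panel or PSM set is an error rather than a
  silent pass.
* `fdr_filter()` with no decoys warns and returns all targets
  (undefined FDR); all-decoy input returns an empty set.
* Fragments containing `J` are rejected at database build time, so
  the `JJ` separator is unambiguous.

## A minimal run

```{r example, eval = FALSE}
st <- toy_study(1)
calls <- discover_antigens(st)
merge(expected_calls(st$truth), calls,
      by = "peptide")[, c("kind", "label", "region")]
study_db_recovery(st)$recovered
```

## Known limitations

* Exact matching only: peptides whose coding sequence differs from
  the (personalized) genome by even one base are reported as having
  no placement; at real scale this corresponds to unindexed variants.
* The minor-allele-frequency rescue for germline-listed but
  tumor-restricted variants is not modeled; a variant present in the
  germline SNP list is simply not an mTSA.
* The I/L enumeration cap means candidates with more than 10 I/L
  residues are only screened against single substitutions.
* Scale: the in-memory k-mer sets and naive degenerate scans are
  sized for desk-scale genomes (megabases), not a full transcriptome.
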