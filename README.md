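# tsascan

Proteogenomic discovery of tumor-specific antigens (TSAs) from
immunopeptidomic and RNA-seq data, at desk scale.

Cancer immunotherapy needs peptides that tumor cells present on MHC
class I and normal cells do not. Most of these tumor-specific antigens
do not come from coding mutations — they arise from aberrant
expression of introns, intergenic regions, lncRNAs, UTRs and
out-of-frame exons, which annotation-driven pipelines never see. The
proteogenomic answer is to build a *cancer-specific* protein database
directly from tumor RNA-seq by k-mer subtraction of normal libraries,
identify MHC I-associated peptides (MAPs) against it by mass
spectrometry, and then push every candidate through an
expression-threshold cascade that separates mutated TSAs (mTSAs),
aberrantly expressed TSAs (aeTSAs) and tumor-associated antigens
(TAAs). `tsascan` implements that whole path for researchers who want
to study, test or teach the method's logic on fully controlled
synthetic data.

## The method in brief

* **Database construction** — tumor reads are cut into 33-nt k-mers;
  k-mers with pooled occurrence ≥ 2 in normal libraries are removed;
  survivors are assembled into unitig contigs, three-frame translated
  (stranded libraries), and packed into ~10,000-aa entries joined by
  the `JJ` separator alongside the canonical proteome.
* **Immunopeptidome filters** — decoy-based FDR ≤ 5%, peptide length
  8–11 aa, predicted eluted-ligand rank ≤ 2%.
* **Expression quantification** — every peptide is reverse-translated
  into all coding sequences (MCSs) and located exactly on the genome
  and spliced transcriptome. Expression is measured as

  `kphm = kmin × 10^8 / rtot` (minimum occurrence of the MCS's 24-nt
  k-mers, canonical counting) and `rphm = reads × 10^8 / rtot`
  (reads fully containing the MCS),

  with `rtot` the library size.
* **Classification** — a candidate must be ≥ 10-fold higher in cancer
  than matched normal and < 2 KPHM in normal; survive I/L variant
  disambiguation; stay < 8.55 RPHM in mTECs and a normal-tissue panel
  (MHC-low tissues exemptable); and have a clear, non-hypervariable
  genomic localization. It is then an **mTSA** if it differs from the
  reference translation through a non-germline variant, an **aeTSA**
  if mTEC/NAT expression is ≤ 0.2 KPHM, and a **TAA** if mTEC or NAT
  expression exceeds 0.2 KPHM.
* **Sharing and validation** — cohort sharing on log10(RPHM+1)
  baselines (≥ 10-fold above the pooled GTEx/mTEC mean in ≥ 5% of
  tumors), TMT labeling efficiency, SPS-MS3 127N/126 ratios with
  contamination and intensity-percentile filters, and Pearson
  correlation of root-scaled fragment intensities against synthetic
  peptides (validated at r ≥ 0.6).

A synthetic-study generator (`toy_study()`) plants aeTSA, mTSA and TAA
events with recorded ground truth into a toy genome and simulates
stranded read sets and identification tables, so the entire cascade is
testable by parameter recovery. See the vignette
(`vignettes/tsa-discovery.Rmd`) for the model, parameter and design
details.

## Worked example

```r
library(tsascan)

st <- toy_study(1)                 # genome + events + reads + identifications
calls <- discover_antigens(st)     # the full cascade
merge(expected_calls(st$truth), calls, by = "peptide")[,
      c("peptide", "kind", "label", "region", "nat_kphm", "mtec_kphm")]
```

```
   peptide              kind label     region nat_kphm mtec_kphm
 CLDLPQEID TAA_overexpressed   TAA       exon        0      4.75
 FMTNVYAEG         aeTSA_utr aeTSA       UTR5        0      0.00
 HVGNYEKLR      aeTSA_intron aeTSA     intron        0      0.00
 KSEMGKQIS  aeTSA_intergenic aeTSA intergenic        0      0.00
 PTFGTKRET      aeTSA_lncRNA aeTSA     lncRNA        0      0.00
 RGGITTNKV  aeTSA_intergenic aeTSA intergenic        0      0.00
 SLRGHPTLT TAA_overexpressed   TAA       exon        0      6.50
 STKKIWDFV          mTSA_snv  mTSA       exon        0      0.00
 YDASKPRAV      aeTSA_intron aeTSA     intron        0      0.00
```

Every planted event receives its planted label: the six
aberrant-expression events come back as aeTSAs with the correct
genomic region, the somatic SNV as an mTSA, and the two overexpressed
genes as TAAs (mTEC expression above the 0.2 KPHM boundary while the
matched-normal gate still passes). Canonical housekeeping peptides in
the same identification table are all excluded at the expression gate.
The database-construction route recovers the same peptides
independently:

```r
study_db_recovery(st)$recovered
#> [1] 1
```

The package also bundles a curated table of validated colorectal
tumor antigens with TMT quantification results:

```r
str(antigen_tally())
#> List of 5
#>  $ total_tsas          : int 19
#>  $ tissue_tsas         : int 18
#>  $ quantified_tsas     : int 7
#>  $ mss_tissue_aetsas   : int 8
#>  $ mean_tsas_per_tissue: num 3
```

— 19 TSA calls in total, 18 of them in tissue samples (a mean of 3
per tissue), 7 unique TSA sequences successfully quantified by
SPS-MS3, and 8 aeTSAs in microsatellite-stable tissues.

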