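Package: tsascan
Title: Proteogenomic Discovery of Tumor-Specific Antigens from
    Immunopeptidomic and RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale proteogenomic pipeline for discovering MHC
    class I tumor-specific antigens (TSAs). Builds cancer-specific
    peptide databases by k-mer subtraction of normal RNA-seq libraries
    (33-nt k-mer counting, tumor-minus-normal filtering, unitig contig
    assembly, three-frame translation, "JJ"-separated concatenation),
    filters mass-spectrometry identification tables into an
    immunopeptidome (decoy-based FDR, 8-11 aa length and MHC binding
    rank filters), reverse-translates peptides into all coding
    sequences and quantifies them in RNA-seq data as KPHM (minimum
    24-mer occurrence per 10^8 reads) and RPHM (containing reads per
    10^8 reads), classifies candidates into mutated TSAs, aberrantly
    expressed TSAs and tumor-associated antigens through an expression
    threshold cascade with I/L disambiguation, normal-tissue screens
    and genomic localization, measures intertumoral sharing on
    log(RPHM+1) cohort matrices, and provides TMT reporter-ion
    quantitation utilities (labeling efficiency, SPS-MS3 ratios,
    endogenous-versus-synthetic spectral correlation). Includes a
    fully self-contained synthetic study generator with planted
    antigen events and recorded ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
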