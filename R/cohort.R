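# Intertumoral sharing: log(RPHM+1) cohort matrices and the
# >= 10-fold-above-normal-baseline sharing statistic.

#' Construct a cohort expression matrix
#'
#' @param rphm Numeric matrix, peptides x samples (RPHM values).
#' @param sample_class Character vector per column: `tumor`,
#'   `normal_panel` or `mtec`.
#' @return A `cohort_matrix` object.
#' @export
cohort_matrix <- function(rphm, sample_class) {
  stopifnot(is.matrix(rphm), ncol(rphm) == length(sample_class),
            all(rphm >= 0),
            all(sample_class %in% c("tumor", "normal_panel", "mtec")))
  if (!any(sample_class == "tumor")) stop("no tumor columns")
  if (!any(sample_class %in% c("normal_panel", "mtec"))) {
    stop("no baseline (normal_panel/mtec) columns")
  }
  structure(list(rphm = rphm, sample_class = sample_class),
            class = "cohort_matrix")
}

#' Baseline normal expression of a peptide
#'
#' The mean of log(RPHM + 1) over all pooled normal-panel and mTEC
#' columns, back-transformed to the RPHM scale (`base^mean - 1`).
#' Base-10 logs by default (`log_base` is configurable).
#'
#' @param peptide Row name in the matrix.
#' @param matrix A `cohort_matrix`.
#' @param log_base Logarithm base.
#' @return Baseline RPHM value.
#' @export
baseline_value <- function(peptide, matrix, log_base = 10) {
  v <- matrix$rphm[peptide, matrix$sample_class %in% c("normal_panel", "mtec")]
  if (!length(v)) stop("no baseline columns")
  log_base^mean(log(v + 1, base = log_base)) - 1
}

#' Fraction of tumors sharing a peptide's expression
#'
#' The fraction of tumor columns expressing the peptide at least
#' `min_fold`-fold above its baseline; when the baseline is 0, any
#' positive tumor expression counts (the rule stays division-free).
#'
#' @param peptide Row name in the matrix.
#' @param matrix A `cohort_matrix`.
#' @param min_fold Fold threshold over the baseline.
#' @param log_scale Compare on the log(RPHM+1) scale instead of the
#'   linear scale.
#' @param log_base Logarithm base for the baseline.
#' @return Fraction in [0, 1].
#' @export
sharing_fraction <- function(peptide, matrix, min_fold = 10,
                             log_scale = FALSE, log_base = 10) {
  b <- baseline_value(peptide, matrix, log_base = log_base)
  tum <- matrix$rphm[peptide, matrix$sample_class == "tumor"]
  if (b <= 0) return(mean(tum > 0))
  if (log_scale) {
    mean(log(tum + 1, base = log_base) >=
           log(min_fold * b + 1, base = log_base))
  } else {
    mean(tum >= min_fold * b)
  }
}

#' Shared / not-shared call
#'
#' @param fraction Sharing fraction from [sharing_fraction()].
#' @param min_frac Inclusive sharing threshold ("in at least 5% of
#'   tumors").
#' @return Logical.
#' @export
shared_flag <- function(fraction, min_frac = 0.05) {
  fraction >= min_frac
}

#' Sharing summary for every peptide of a cohort matrix
#'
#' @param matrix A `cohort_matrix`.
#' @param min_fold,min_frac Thresholds (see [sharing_fraction()] and
#'   [shared_flag()]).
#' @return Data frame: peptide, baseline, fraction, shared.
#' @export
cohort_sharing <- function(matrix, min_fold = 10, min_frac = 0.05) {
  peps <- rownames(matrix$rphm)
  data.frame(
    peptide = peps,
    baseline = vapply(peps, baseline_value, numeric(1), matrix = matrix),
    fraction = vapply(peps, sharing_fraction, numeric(1), matrix = matrix,
                      min_fold = min_fold),
    shared = vapply(peps, function(p)
      shared_flag(sharing_fraction(p, matrix, min_fold), min_frac),
      logical(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
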