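# TMT quantitation utilities: labeling efficiency, SPS-MS3 relative
# quantification with contamination and intensity-percentile filters,
# and endogenous-versus-synthetic spectral correlation.

#' TMT labeling efficiency
#'
#' The proportion of TMT-labeled PSMs over all PSMs.
#'
#' @param psms Data frame with a logical `is_tmt_labeled` column, or a
#'   logical vector.
#' @return Fraction in [0, 1].
#' @export
labeling_efficiency <- function(psms) {
  lab <- if (is.data.frame(psms)) psms$is_tmt_labeled else psms
  if (!length(lab)) stop("labeling efficiency undefined for an empty PSM set")
  mean(lab)
}

#' SPS-MS3 relative quantification of one peptide
#'
#' PSMs with signal in the deliberately empty channel above
#' `contamination_tol` are excluded; of the rest, only PSMs whose
#' total reporter intensity reaches the `intensity_percentile`-th
#' percentile are kept (high-intensity PSMs are the reliable ones; the
#' opposite reading is available via `keep = "below"`). The ratio is
#' the mean tumor-channel intensity over the mean normal-channel
#' intensity of the surviving PSMs.
#'
#' @param psms Data frame of PSMs for one peptide, one numeric column
#'   per reporter channel.
#' @param tumor_channel,normal_channel,empty_channel Channel column
#'   names (TMT10plex tissue layout: tumor `"127N"`, NAT `"126"`,
#'   contamination control `"127C"`).
#' @param channels Channel columns defining the total intensity;
#'   defaults to all numeric columns.
#' @param contamination_tol Absolute noise floor for the empty
#'   channel (0 = any signal disqualifies).
#' @param intensity_percentile Percentile of total intensity used as
#'   the keep threshold.
#' @param keep Keep PSMs `"above"` (default) or `"below"` the
#'   percentile.
#' @return List with `ratio` (`NA` when not quantifiable), `n_used`,
#'   `quantifiable`.
#' @export
ms3_ratio <- function(psms, tumor_channel = "127N",
                      normal_channel = "126", empty_channel = "127C",
                      channels = NULL, contamination_tol = 0,
                      intensity_percentile = 70,
                      keep = c("above", "below")) {
  keep <- match.arg(keep)
  stopifnot(all(c(tumor_channel, normal_channel) %in% names(psms)))
  if (empty_channel %in% names(psms)) {
    psms <- psms[psms[[empty_channel]] <= contamination_tol, , drop = FALSE]
  }
  if (!nrow(psms)) {
    return(list(ratio = NA_real_, n_used = 0L, quantifiable = FALSE))
  }
  channels <- channels %||%
    names(psms)[vapply(psms, is.numeric, logical(1))]
  total <- rowSums(psms[, channels, drop = FALSE])
  thr <- stats::quantile(total, intensity_percentile / 100, names = FALSE)
  sel <- if (keep == "above") total >= thr else total <= thr
  psms <- psms[sel, , drop = FALSE]
  if (!nrow(psms) || mean(psms[[normal_channel]]) == 0) {
    return(list(ratio = NA_real_, n_used = nrow(psms),
                quantifiable = FALSE))
  }
  list(ratio = mean(psms[[tumor_channel]]) / mean(psms[[normal_channel]]),
       n_used = nrow(psms), quantifiable = TRUE)
}

#' Endogenous-versus-synthetic spectral correlation
#'
#' Pearson correlation of root-scaled (square-root) fragment
#' intensities over the fragments shared by the endogenous and
#' synthetic spectra; a pair is flagged validated at `r >= 0.6`.
#'
#' @param endogenous,synthetic Data frames with columns `fragment` and
#'   `intensity` (one row per fragment ion).
#' @param min_shared Minimum number of shared fragments.
#' @param r_threshold Validation threshold on Pearson r.
#' @return List with `r`, `p_value`, `conf_int`, `n_shared`,
#'   `validated`.
#' @export
spectral_correlation <- function(endogenous, synthetic, min_shared = 3L,
                                 r_threshold = 0.6) {
  shared <- intersect(endogenous$fragment, synthetic$fragment)
  if (length(shared) < min_shared) {
    stop("need at least ", min_shared, " shared fragments; got ",
         length(shared))
  }
  e <- sqrt(endogenous$intensity[match(shared, endogenous$fragment)])
  s <- sqrt(synthetic$intensity[match(shared, synthetic$fragment)])
  ct <- stats::cor.test(e, s, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, p_value = ct$p.value,
       conf_int = if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else c(NA, NA),
       n_shared = length(shared), validated = r >= r_threshold)
}
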