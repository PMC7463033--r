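#' Scoring and alignment parameters
#'
#' Builds the parameter set used by the segment-to-contig aligner and the
#' label-collapse model. Two instrument presets are provided, reflecting the
#' different label chemistries: `"irys"` (nickase labelling, motif
#' \code{GCTCTTC}) and `"saphyr"` (direct labelling, motif \code{CTTAAG}).
#' The newer direct-label chemistry has denser labels and a lower collapse
#' rate, hence the tighter collapse length scale and the higher minimum label
#' count for alignable segments.
#'
#' @param instrument `"saphyr"` (default) or `"irys"`.
#' @param c missing-label score (score units). The perfect single-step match
#'   score is `2c`; each unexplained label costs `c`.
#' @param k exponent applied to the absolute length difference (bp) between
#'   matched intervals. Values slightly above 1 penalise large sizing
#'   discrepancies super-linearly.
#' @param w label-collapse length scale (bp): two labels separated by more
#'   than `w` never merge. Defaults reflect the ~2 kbp imaging resolution.
#' @param t collapse shape exponent (dimensionless).
#' @param eta minimum bp span between two segment labels for the interior
#'   expected-label sum to be counted at all.
#' @param d band width of the alignment DP, in labels.
#' @param max_alignments_per_pair cap on the number of alignments of one
#'   segment to one contig found by iterative masking (default 12).
#' @param min_labels minimum number of labels a segment needs to be aligned
#'   in semi-global/overlap/detection mode (fitting mode needs only 2).
#' @param p_semiglobal,p_overlap,p_detection default p-value cutoffs for the
#'   three alignment modes.
#' @param mean_step_min,median_step_min per-label-pair step-score thresholds;
#'   significant alignments whose mean or median step score falls below these
#'   are discarded.
#' @param fallback_frac when the empirical E-value model is degenerate
#'   (too few contigs to calibrate), an alignment of a segment with `n_r`
#'   labels is significant if its score is at least
#'   `fallback_frac * 2c * (n_r - 1)`.
#' @param merge_as_printed logical; if `TRUE`, use the increasing form of the
#'   merge probability `min(1, (delta/w)^t)` instead of the default
#'   decreasing form `1 - min(1, (delta/w)^t)`.
#' @param label_offset constant bp offset added to each motif start when
#'   digesting (a constant shift cancels in all length-difference scores).
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(instrument = c("saphyr", "irys"),
                           c = 1500, k = 1.1,
                           w = NULL, t = 2, eta = NULL,
                           d = 6L,
                           max_alignments_per_pair = 12L,
                           min_labels = NULL,
                           p_semiglobal = 1e-4,
                           p_overlap = 1e-6,
                           p_detection = 1e-9,
                           mean_step_min = 0,
                           median_step_min = 0,
                           fallback_frac = 0.6,
                           merge_as_printed = FALSE,
                           label_offset = 0) {
  instrument <- match.arg(instrument)
  if (is.null(w)) w <- if (instrument == "saphyr") 1500 else 2000
  if (is.null(eta)) eta <- w
  if (is.null(min_labels)) min_labels <- if (instrument == "saphyr") 12L else 10L
  stopifnot(c > 0, k > 0, w > 0, t > 0, eta >= 0, d >= 1)
  structure(list(
    instrument = instrument,
    motif = if (instrument == "saphyr") "CTTAAG" else "GCTCTTC",
    c = c, k = k, w = w, t = t, eta = eta, d = as.integer(d),
    max_alignments_per_pair = as.integer(max_alignments_per_pair),
    min_labels = as.integer(min_labels),
    p_semiglobal = p_semiglobal, p_overlap = p_overlap,
    p_detection = p_detection,
    mean_step_min = mean_step_min, median_step_min = median_step_min,
    fallback_frac = fallback_frac,
    merge_as_printed = merge_as_printed,
    label_offset = label_offset
  ), class = "scoring_params")
}
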