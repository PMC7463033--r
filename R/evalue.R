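#' Calibrate the empirical E-value model for one segment
#'
#' Given the best alignment score of a segment against every contig in the
#' dataset, fits the extreme-value model `E(S) = K * m * n_r * exp(-lambda*S)`
#' empirically: the top 25 scores are removed (they may be true alignments,
#' violating the random-pairing assumption), the high-scoring pairs (HSPs)
#' are the remaining scores at or above their 85th percentile, each HSP gets
#' empirical E-value equal to its rank (highest score has rank 1), and
#' `log(E) = log(K*m*n_r) - lambda*S` is fit by linear regression.
#'
#' @param best_scores_per_contig numeric vector, one best score per contig.
#' @param m total number of labels in the contig collection.
#' @param n_r number of labels on the segment.
#' @param min_hsp minimum HSP count for a usable fit (default 10); below it
#'   (or for a non-positive fitted slope) the model is flagged degenerate
#'   and callers fall back to a fixed conservative cutoff.
#' @return list of class `evalue_model` with `K`, `lambda`, `m`, `n_r`,
#'   `n_hsp`, `degenerate`.
#' @export
calibrate_evalue <- function(best_scores_per_contig, m, n_r, min_hsp = 10L) {
  degenerate <- function() structure(
    list(K = NA_real_, lambda = NA_real_, m = m, n_r = n_r,
         n_hsp = 0L, degenerate = TRUE), class = "evalue_model")
  s <- sort(as.numeric(best_scores_per_contig), decreasing = TRUE)
  if (length(s) > 25) s <- s[-(1:25)] else return(degenerate())
  if (length(s) < min_hsp) return(degenerate())
  hsp <- s[s >= quantile(s, 0.85, names = FALSE)]
  if (length(hsp) < min_hsp || stats::sd(hsp) == 0) return(degenerate())
  rank <- seq_along(hsp)  # hsp already sorted descending; highest rank 1
  fit <- lm(log(rank) ~ hsp)
  lambda <- -unname(coef(fit)[2])
  if (!is.finite(lambda) || lambda <= 0) return(degenerate())
  K <- exp(unname(coef(fit)[1])) / (m * n_r)
  structure(list(K = K, lambda = lambda, m = m, n_r = n_r,
                 n_hsp = length(hsp), degenerate = FALSE),
            class = "evalue_model")
}

#' Score cutoff for a given p-value under an E-value model
#'
#' Inverts `P = 1 - exp(-E)` and `E = K*m*n_r*exp(-lambda*S)`:
#' `S* = -log(-log(1-P) / (K*m*n_r)) / lambda`.
#'
#' @param model an `evalue_model` (non-degenerate).
#' @param p_value probability in `(0, 1)`.
#' @return the score cutoff `S*`.
#' @export
score_cutoff <- function(model, p_value) {
  if (p_value <= 0 || p_value >= 1) stop("score_cutoff: p must be in (0,1)")
  if (isTRUE(model$degenerate)) stop("score_cutoff: degenerate model")
  -log(-log(1 - p_value) / (model$K * model$m * model$n_r)) / model$lambda
}

#' Significance cutoff for a segment, with conservative fallback
#'
#' Calibrates the empirical E-value model from the per-contig best scores
#' when enough contigs are available, otherwise (degenerate model) returns
#' the conservative fallback: `fallback_frac * 2c * (n_obs - 1)` when the
#' segment map is supplied (collapse-aware effective label count, see
#' [fallback_cutoff]), else with the raw label count `n_r`.
#'
#' @inheritParams calibrate_evalue
#' @param p_value significance level for [score_cutoff].
#' @param params a [scoring_params].
#' @param segment optional segment [label_map] for the collapse-aware
#'   fallback.
#' @return a score cutoff (numeric scalar).
#' @export
significance_cutoff <- function(best_scores_per_contig, m, n_r, p_value,
                                params, segment = NULL) {
  model <- calibrate_evalue(best_scores_per_contig, m, n_r)
  if (model$degenerate) {
    if (!is.null(segment)) fallback_cutoff(segment, params)
    else params$fallback_frac * 2 * params$c * (n_r - 1)
  } else {
    score_cutoff(model, p_value)
  }
}

#' Filter alignments on per-pair step-score quality
#'
#' Statistically significant alignments whose mean or median per-label-pair
#' step score falls below the configured thresholds are removed.
#'
#' @param alignments list of [segment_alignment].
#' @param params a [scoring_params] (fields `mean_step_min`,
#'   `median_step_min`).
#' @return the surviving alignments.
#' @export
filter_alignments <- function(alignments, params = scoring_params()) {
  keep <- vapply(alignments, function(a) {
    is.finite(a$mean_step) && is.finite(a$median_step) &&
      a$mean_step >= params$mean_step_min &&
      a$median_step >= params$median_step_min
  }, logical(1))
  alignments[keep]
}
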