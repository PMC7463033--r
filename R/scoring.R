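#' Probability that two labels separated by `delta_bp` merge into one
#'
#' Label collapse is the imaging error mode where two nearby labels are read
#' as a single label. The probability decreases with the separation and is
#' zero beyond the collapse length scale `w`:
#' `P_merge(delta) = 1 - min(1, (delta/w)^t)`.
#' Setting `params$merge_as_printed = TRUE` selects the increasing
#' convention `min(1, (delta/w)^t)` instead.
#'
#' @param delta_bp non-negative separation(s) in bp.
#' @param params a [scoring_params].
#' @return merge probability/ies in `[0, 1]`.
#' @export
merge_probability <- function(delta_bp, params) {
  if (any(delta_bp < 0)) stop("merge_probability: negative separation")
  base <- pmin(1, (delta_bp / params$w)^params$t)
  if (isTRUE(params$merge_as_printed)) base else 1 - base
}

#' Expected observable interior label counts of a segment
#'
#' For a digested segment with label positions `x`, precomputes, for every
#' pair of label indices `p < q`, the expected number of *observable*
#' interior labels between them: each interior label `k` counts
#' `(1 - P_merge(x[k] - x[k-1])) * (1 - P_merge(x[k+1] - x[k]))`, the
#' probability that it merges with neither neighbour. Boundary labels have
#' no missing-side neighbour (gap treated as infinite, i.e. observable).
#' Pairs spanning less than `eta` bp contribute 0.
#'
#' @param segment a [label_map].
#' @param params a [scoring_params].
#' @return object of class `collapse_map`; query it with [collapse_expected].
#' @export
build_collapse_map <- function(segment, params) {
  x <- segment$positions
  n <- length(x)
  if (n == 0) {
    obs <- numeric(0)
  } else {
    gaps <- diff(x)
    left <- c(Inf, gaps)   # gap to the left neighbour of label k
    right <- c(gaps, Inf)  # gap to the right neighbour
    pm <- function(g) ifelse(is.infinite(g), 0, merge_probability(g, params))
    obs <- (1 - pm(left)) * (1 - pm(right))
  }
  structure(list(positions = x, cum = c(0, cumsum(obs)), eta = params$eta),
            class = "collapse_map")
}

#' Expected observable interior labels between labels `p` and `q`
#'
#' @param M a `collapse_map` from [build_collapse_map].
#' @param p,q 1-based label indices, `p < q` (vectorised).
#' @return expected observable interior label count(s).
#' @export
collapse_expected <- function(M, p, q) {
  if (any(q <= p)) stop("collapse_expected: need p < q")
  span <- M$positions[q] - M$positions[p]
  ifelse(span >= M$eta, M$cum[q] - M$cum[p + 1], 0)
}

#' Expected retained label count of a segment under the collapse model
#'
#' Each merge event fuses two adjacent labels into one, removing one label.
#' The expected number of merge events over the segment's gaps follows the
#' left-to-right recursion `p_k = P_merge(g_k) * (1 - p_[k-1])` (a gap
#' cannot merge when its left neighbour already did), so the expected
#' retained count is `n - sum(p_k)`. This is the effective label count an
#' alignment of the segment can realistically pair.
#'
#' @param segment a [label_map].
#' @param params a [scoring_params].
#' @return expected retained label count (numeric scalar).
#' @export
expected_retained_labels <- function(segment, params) {
  x <- segment$positions
  n <- length(x)
  if (n < 2) return(n)
  pm <- merge_probability(diff(x), params)
  p_prev <- 0
  merges <- 0
  for (k in seq_along(pm)) {
    p_k <- pm[k] * (1 - p_prev)
    merges <- merges + p_k
    p_prev <- p_k
  }
  n - merges
}

#' Fallback significance cutoff for a segment
#'
#' `fallback_frac * 2c * (n_eff - 1)` with `n_eff` the expected retained
#' label count under the collapse model ([expected_retained_labels]):
#' segments with many close (collapse-prone) label pairs are not held to an
#' unreachable raw ideal score, while the cutoff stays high enough to
#' reject spurious chains.
#' @param segment a [label_map].
#' @param params a [scoring_params].
#' @return a score cutoff.
#' @export
fallback_cutoff <- function(segment, params) {
  params$fallback_frac * 2 * params$c *
    max(expected_retained_labels(segment, params) - 1, 1)
}

#' Score one pair of matching regions
#'
#' The step score for extending an alignment from pair `(i, p)` to pair
#' `(j, q)`: a base match reward `2c` minus (i) `f_n = c*(j - (i+1))` for
#' skipped contig labels, (ii) `f_p = c * e_ref` where `e_ref` is the
#' expected number of observable skipped segment labels (collapse-aware),
#' and (iii) `delta = |(b[j]-b[i]) - (x[q]-x[p])|^k`, the scaled length
#' difference of the two intervals.
#'
#' @param b,x contig and segment label positions (bp).
#' @param i,j contig label indices, `i < j`.
#' @param p,q segment label indices, `p < q`.
#' @param M `collapse_map` for the segment.
#' @param params a [scoring_params].
#' @return a list of class `score_breakdown` with elements `f_n`, `e_ref`,
#'   `f_p`, `delta`, `total`.
#' @export
score_matching_region <- function(b, x, i, j, p, q, M, params) {
  if (j <= i || q <= p) stop("score_matching_region: need i < j and p < q")
  f_n <- params$c * (j - (i + 1))
  e_ref <- collapse_expected(M, p, q)
  f_p <- params$c * e_ref
  delta <- abs((b[j] - b[i]) - (x[q] - x[p]))^params$k
  structure(list(f_n = f_n, e_ref = e_ref, f_p = f_p, delta = delta,
                 total = 2 * params$c - (f_n + f_p + delta)),
            class = "score_breakdown")
}
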