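#' Align a digested segment to a contig
#'
#' Banded dynamic-programming alignment of the segment's label pattern
#' against the contig's, in both orientations (the reverse alignment reverses
#' the segment's gap sequence, never the contig). Modes:
#' \describe{
#'   \item{semiglobal}{best-scoring chain anywhere (backtrack from the
#'     matrix argmax); requires at least `params$min_labels` labels.}
#'   \item{overlap}{as semiglobal; ends of the segment may extend past the
#'     contig because unaligned terminal labels are unpenalised.}
#'   \item{detection}{as semiglobal; used when searching unaligned contig
#'     regions against reference chromosomes.}
#'   \item{fitting}{both maps must be aligned end-to-end (first and last
#'     labels paired); requires only 2 labels.}
#' }
#'
#' @param segment,contig [label_map]s (the segment is the query).
#' @param mode alignment mode, see above.
#' @param params a [scoring_params].
#' @param used optional integer matrix with columns (contig label index,
#'   segment label index, original frame) of pairings that may not be
#'   reused.
#' @return a [segment_alignment], or `NULL` when no positive-scoring (or,
#'   for fitting, no feasible) alignment exists or the segment has too few
#'   labels.
#' @export
align_segment <- function(segment, contig,
                          mode = c("semiglobal", "fitting", "overlap",
                                   "detection"),
                          params = scoring_params(), used = NULL) {
  mode <- match.arg(mode)
  n <- n_labels(segment)
  m <- n_labels(contig)
  min_n <- if (mode == "fitting") 2L else params$min_labels
  if (n < min_n || m < 2L) return(NULL)

  b <- contig$positions
  fitting <- mode == "fitting"
  run <- function(orientation) {
    if (orientation == "+") {
      xmap <- segment
      remap <- function(q) q
    } else {
      xmap <- reverse_label_map(segment)
      remap <- function(q) n + 1L - q
    }
    M <- build_collapse_map(xmap, params)
    banned <- matrix(FALSE, m, n)
    if (!is.null(used) && nrow(used)) {
      banned[cbind(used[, 1], remap(used[, 2]))] <- TRUE
    }
    r <- segalign_dp(b, xmap$positions, M$cum, params$eta, params$c,
                     params$k, params$d, fitting, banned)
    r$orientation <- orientation
    r$remap <- remap
    r
  }
  res <- list(run("+"), run("-"))
  scores <- vapply(res, function(r) r$score, 0)
  best <- res[[which.max(scores)]]
  if (best$score <= -1e17 || is.null(best$pairs) || nrow(best$pairs) < 2)
    return(NULL)
  if (!fitting && best$score <= 0) return(NULL)
  pr <- best$pairs
  seg_idx <- best$remap(pr[, 2])
  segment_alignment(
    segment_id = segment$map_id, contig_id = contig$map_id,
    orientation = best$orientation,
    pairs = cbind(contig = pr[, 1], segment = seg_idx),
    score = best$score, mode = mode, step_scores = as.numeric(best$steps),
    seg_len = segment$length_bp, contig_len = contig$length_bp,
    seg_nlabels = n, contig_nlabels = m,
    contig_pos = b[pr[, 1]], seg_pos = segment$positions[seg_idx])
}

#' Iteratively extract alignments of one segment to one contig
#'
#' Repeats [align_segment], masking out the label pairings of each emitted
#' alignment, until the score drops below the significance cutoff or
#' `params$max_alignments_per_pair` alignments were found. This is how
#' multiple copies of a segment on one contig (duplications) are recovered.
#'
#' @inheritParams align_segment
#' @param cutoff minimum score for an alignment to be kept; defaults to the
#'   conservative collapse-aware fallback ([fallback_cutoff]).
#' @return list of [segment_alignment] (possibly empty), with the final
#'   used-pair matrix attached as attribute `"used"`.
#' @export
iterative_align <- function(segment, contig, mode = "semiglobal",
                            params = scoring_params(), cutoff = NULL,
                            used = NULL) {
  if (is.null(cutoff)) cutoff <- fallback_cutoff(segment, params)
  if (is.null(used)) used <- matrix(integer(0), 0, 2)
  out <- list()
  while (length(out) < params$max_alignments_per_pair) {
    a <- align_segment(segment, contig, mode, params, used = used)
    if (is.null(a) || a$score < cutoff) break
    out[[length(out) + 1L]] <- a
    used <- rbind(used, unname(a$pairs))
  }
  attr(out, "used") <- used
  out
}
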