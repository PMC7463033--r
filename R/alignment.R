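#' A scored label-pair alignment of a digested segment to a contig
#'
#' @param segment_id,contig_id map identifiers.
#' @param orientation `"+"` or `"-"`: orientation of the segment (query)
#'   relative to the contig (reference).
#' @param pairs integer matrix with columns `contig`, `segment`: 1-based
#'   label indices of the matched pairs. Contig indices are ascending;
#'   segment indices are in the segment's own frame, so they descend for a
#'   `"-"` alignment.
#' @param score total alignment score (sum of per-step scores).
#' @param mode one of `"semiglobal"`, `"fitting"`, `"overlap"`,
#'   `"detection"`.
#' @param step_scores numeric vector of per-step scores (length
#'   `nrow(pairs) - 1`).
#' @param seg_len,contig_len map lengths in bp.
#' @param seg_nlabels,contig_nlabels total label counts of the two maps.
#' @param contig_pos,seg_pos bp positions of the matched labels.
#' @return an object of class `segment_alignment`.
#' @export
segment_alignment <- function(segment_id, contig_id, orientation, pairs, score,
                              mode = "semiglobal", step_scores = numeric(0),
                              seg_len = NA_real_, contig_len = NA_real_,
                              seg_nlabels = NA_integer_,
                              contig_nlabels = NA_integer_,
                              contig_pos = NULL, seg_pos = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("contig", "segment")))
  if (nrow(pairs) >= 2) {
    if (any(diff(pairs[, "contig"]) <= 0))
      stop("segment_alignment: contig indices must be strictly increasing")
    dseg <- diff(pairs[, "segment"])
    if (orientation == "+" && any(dseg <= 0))
      stop("segment_alignment: segment indices must increase for '+'")
    if (orientation == "-" && any(dseg >= 0))
      stop("segment_alignment: segment indices must decrease for '-'")
  }
  ns <- length(step_scores)
  structure(list(segment_id = as.character(segment_id),
                 contig_id = as.character(contig_id),
                 orientation = orientation, pairs = pairs, score = score,
                 mode = mode, step_scores = step_scores,
                 mean_step = if (ns) mean(step_scores) else NA_real_,
                 median_step = if (ns) median(step_scores) else NA_real_,
                 seg_len = seg_len, contig_len = contig_len,
                 seg_nlabels = seg_nlabels, contig_nlabels = contig_nlabels,
                 contig_pos = contig_pos, seg_pos = seg_pos),
            class = "segment_alignment")
}

#' @export
print.segment_alignment <- function(x, ...) {
  cat(sprintf(
    "<segment_alignment> seg %s -> contig %s (%s, %s): %d pairs, score %.1f\n",
    x$segment_id, x$contig_id, x$orientation, x$mode, nrow(x$pairs), x$score))
  invisible(x)
}

#' First/last aligned contig label index of an alignment
#' @noRd
aln_contig_range <- function(a) range(a$pairs[, "contig"])
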