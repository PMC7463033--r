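#' Longest common substring of two oriented segment paths
#'
#' Tokens are `(segment_id, orientation)` pairs. The second path is also
#' compared in orientation-reversed form (a reconstruction read from the
#' other end is the same structure); cyclic paths are compared over all
#' rotations by doubling, with the match capped at the path length.
#'
#' @param a,b data.frames with `segment_id`, `orientation`.
#' @param cyclic_a,cyclic_b logical cyclicity flags.
#' @param allow_reverse compare `b` in reversed orientation too
#'   (default `TRUE`).
#' @return data.frame of the common run's elements (0 rows if none),
#'   with attribute `"full_cycle"` when it covers a whole cyclic path.
#' @export
lcs_paths <- function(a, b, cyclic_a = FALSE, cyclic_b = FALSE,
                      allow_reverse = TRUE) {
  ta <- path_tokens(a)
  na <- length(ta)
  nb <- nrow(b)
  cap <- min(na, nb)
  doubled <- function(tok, cyc) if (cyc && length(tok) > 1) c(tok, tok) else tok
  ta2 <- doubled(ta, cyclic_a)
  a2 <- if (cyclic_a && na > 1) rbind(a, a) else a

  best_len <- 0
  best_end_a <- 0
  run_one <- function(tb2) {
    # classic O(nm) longest-common-substring DP over tokens
    m <- length(ta2); n <- length(tb2)
    prev <- integer(n)
    for (i in seq_len(m)) {
      cur <- integer(n)
      for (j in seq_len(n)) {
        if (ta2[i] == tb2[j]) {
          cur[j] <- (if (j > 1) prev[j - 1] else 0) + 1
          len <- min(cur[j], cap)
          if (len > best_len) {
            best_len <<- len
            best_end_a <<- i
          }
        }
      }
      prev <- cur
    }
  }
  run_one(doubled(path_tokens(b), cyclic_b))
  if (allow_reverse)
    run_one(doubled(path_tokens(reverse_elements(b)), cyclic_b))
  if (best_len == 0)
    return(a[0, , drop = FALSE])
  out <- a2[(best_end_a - best_len + 1):best_end_a, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "full_cycle") <- (cyclic_a && best_len == na) ||
    (cyclic_b && best_len == nb)
  out
}

#' Path size under one of the three comparison metrics
#'
#' `length_bp` sums the segment lengths; `nsegs` counts elements;
#' `breakpoint` counts junctions (elements - 1 for a linear path, elements
#' for a cyclic one).
#'
#' @param elements oriented segment data.frame.
#' @param metric `"length_bp"`, `"nsegs"`, or `"breakpoint"`.
#' @param graph [breakpoint_graph] supplying segment lengths.
#' @param cyclic is the path cyclic (or, for an LCS fragment, does it cover
#'   a full cyclic path)?
#' @return numeric size.
#' @export
path_measure <- function(elements, metric = c("length_bp", "nsegs",
                                              "breakpoint"),
                         graph = NULL, cyclic = FALSE) {
  metric <- match.arg(metric)
  n <- nrow(elements)
  if (metric == "nsegs") return(n)
  if (metric == "breakpoint") return(if (cyclic) n else max(n - 1, 0))
  lens <- segment_lengths(graph)
  sum(lens[elements$segment_id])
}

#' Trim reference-trivial path ends
#'
#' Removes terminal elements that (i) join their neighbour by plain
#' reference adjacency (same orientation, abutting coordinates) and (ii) do
#' not occur in the ground-truth path in either orientation - such tails
#' are trivial read-through of the reference, not reconstruction signal.
#'
#' @param path a [reconstructed_path] (linear paths only are trimmed).
#' @param truth an `amplicon_truth` (or any list with `elements`).
#' @param graph [breakpoint_graph] with segment coordinates.
#' @return the trimmed [reconstructed_path].
#' @export
trim_trivial_ends <- function(path, truth, graph) {
  if (path$cyclic) return(path)
  segs <- graph$segments
  truth_tok <- c(path_tokens(truth$elements),
                 path_tokens(reverse_elements(truth$elements)))
  ref_adjacent <- function(e1, e2) {
    i <- match(e1$segment_id, segs$segment_id)
    j <- match(e2$segment_id, segs$segment_id)
    if (segs$chrom[i] != segs$chrom[j]) return(FALSE)
    if (e1$orientation != e2$orientation) return(FALSE)
    if (e1$orientation == "+") segs$end[i] + 1 == segs$start[j]
    else segs$end[j] + 1 == segs$start[i]
  }
  els <- path$elements
  repeat {
    n <- nrow(els)
    if (n < 2) break
    if (ref_adjacent(els[n - 1, ], els[n, ]) &&
        !(path_tokens(els[n, ]) %in% truth_tok)) {
      els <- els[-n, , drop = FALSE]
    } else break
  }
  repeat {
    n <- nrow(els)
    if (n < 2) break
    if (ref_adjacent(els[1, ], els[2, ]) &&
        !(path_tokens(els[1, ]) %in% truth_tok)) {
      els <- els[-1, , drop = FALSE]
    } else break
  }
  path$elements <- els
  path
}

#' Precision and recall of a reconstruction against the truth
#'
#' Per the LCS framework: among the reconstructed paths, the one whose LCS
#' with the truth is largest under the active metric is scored (ties by bp
#' length of the LCS, then by smaller reconstructed size);
#' `precision = M(LCS) / M(recon)`, `recall = M(LCS) / M(truth)`.
#' Reconstructed paths are first trimmed of reference-trivial ends.
#'
#' @param truth an `amplicon_truth`.
#' @param recon_paths list of [reconstructed_path].
#' @param metric see [path_measure].
#' @param graph [breakpoint_graph]; defaults to `truth$graph`.
#' @return list of class `eval_result`: `precision`, `recall`, `f1`,
#'   `metric`, `lcs_elements`, `scored_path`.
#' @export
precision_recall <- function(truth, recon_paths,
                             metric = c("length_bp", "nsegs", "breakpoint"),
                             graph = NULL) {
  metric <- match.arg(metric)
  graph <- graph %||% truth$graph
  if (!nrow(truth$elements)) stop("precision_recall: empty truth path")
  m_truth <- path_measure(truth$elements, metric, graph, truth$cyclic)
  if (!length(recon_paths)) {
    return(structure(list(precision = 0, recall = 0, f1 = 0, metric = metric,
                          lcs_elements = truth$elements[0, ],
                          scored_path = NULL), class = "eval_result"))
  }
  best <- NULL
  for (p in recon_paths) {
    p <- trim_trivial_ends(p, truth, graph)
    lcs <- lcs_paths(truth$elements, p$elements, truth$cyclic, p$cyclic)
    m_lcs <- path_measure(lcs, metric, graph,
                          cyclic = isTRUE(attr(lcs, "full_cycle")))
    m_rec <- path_measure(p$elements, metric, graph, p$cyclic)
    lcs_bp <- if (nrow(lcs)) path_measure(lcs, "length_bp", graph) else 0
    cand <- list(m_lcs = m_lcs, m_rec = m_rec, lcs = lcs, lcs_bp = lcs_bp,
                 path = p)
    if (is.null(best) || m_lcs > best$m_lcs ||
        (m_lcs == best$m_lcs && (lcs_bp > best$lcs_bp ||
          (lcs_bp == best$lcs_bp && m_rec < best$m_rec)))) {
      best <- cand
    }
  }
  precision <- if (best$m_rec > 0) best$m_lcs / best$m_rec else 0
  recall <- if (m_truth > 0) best$m_lcs / m_truth else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1,
                 metric = metric, lcs_elements = best$lcs,
                 scored_path = best$path),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: precision %.3f, recall %.3f, F1 %.3f\n",
              x$metric, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Mean F1 over a set of evaluation results
#'
#' Harmonic-mean F1 per amplicon (defined as 0 when precision and recall
#' are both 0), averaged.
#'
#' @param results list of `eval_result` (or data.frame with `precision`,
#'   `recall`).
#' @return mean F1 (numeric scalar).
#' @export
mean_f1 <- function(results) {
  if (is.data.frame(results)) {
    pr <- results$precision; rc <- results$recall
  } else {
    if (!length(results)) stop("mean_f1: empty result list")
    pr <- vapply(results, function(r) r$precision, 0)
    rc <- vapply(results, function(r) r$recall, 0)
  }
  if (!length(pr)) stop("mean_f1: empty result list")
  f1 <- ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)
  mean(f1)
}

#' Was an intra-amplicon duplication resolved?
#'
#' A duplication is resolved when the scored reconstruction contains the
#' duplicated block at the truth multiplicity with truth-consistent
#' flanking context: the truth sub-path running from one element before the
#' first copy to one element after the last copy must occur contiguously in
#' the reconstruction (rotation- and reversal-aware for cyclic paths).
#'
#' @param truth an `amplicon_truth` whose `dup_block` records the forced
#'   duplication (see [simulate_amplicon_structure]).
#' @param recon_paths list of [reconstructed_path].
#' @return logical.
#' @export
duplication_resolved <- function(truth, recon_paths) {
  if (is.null(truth$dup_block)) stop("duplication_resolved: truth has no duplication")
  block_tok <- path_tokens(truth$dup_block$block)
  tok <- path_tokens(truth$elements)
  n <- length(tok)
  span <- length(block_tok) * truth$dup_block$mult
  # locate the tandem copies in the truth
  hit <- NA
  reps <- rep(block_tok, truth$dup_block$mult)
  for (s in seq_len(n - span + 1)) {
    if (all(tok[s:(s + span - 1)] == reps)) { hit <- s; break }
  }
  if (is.na(hit)) {
    # the block may have been reordered by later ops; fall back to the
    # block itself at its multiplicity
    reps <- block_tok
    span <- length(block_tok)
    for (s in seq_len(n - span + 1)) {
      if (all(tok[s:(s + span - 1)] == reps)) { hit <- s; break }
    }
    if (is.na(hit)) return(FALSE)
  }
  lo <- max(1, hit - 1)
  hi <- min(n, hit + span)
  context <- tok[lo:hi]
  contains <- function(p) {
    pt <- path_tokens(p$elements)
    if (p$cyclic && length(pt) > 1) pt <- c(pt, pt)
    rt <- path_tokens(reverse_elements(p$elements))
    if (p$cyclic && length(rt) > 1) rt <- c(rt, rt)
    is_substring(context, pt) || is_substring(context, rt)
  }
  any(vapply(recon_paths, contains, logical(1)))
}
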