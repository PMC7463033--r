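#' Reconstruct amplicon structures from a breakpoint graph and OM contigs
#'
#' Runs the full pipeline: in silico digestion of the graph segments,
#' iterative banded alignment of every sufficiently-labeled segment against
#' every contig, significance filtering (empirical E-value model when
#' enough contigs are available, conservative fallback otherwise), scaffold
#' DAG construction per contig, breakpoint-graph gap imputation, heaviest
#' path extraction, cross-contig scaffold linking, copy-number-ratio
#' filtering, rotation-subsequence filtering, and cyclic/linear
#' classification.
#'
#' @param graph a [breakpoint_graph].
#' @param contigs list of contig [label_map]s.
#' @param reference optional named [Biostrings::DNAStringSet]; required
#'   unless `segment_maps` is given.
#' @param segment_maps optional precomputed digests of the graph segments.
#' @param params a [scoring_params].
#' @param impute impute gap paths (default `TRUE`).
#' @param detect search large unaligned contig regions against
#'   `reference_maps` and append hits to the graph as new segments.
#' @param reference_maps named list of chromosome [label_map]s (required
#'   when `detect = TRUE`).
#' @return object of class `amplicon_reconstruction` with elements `paths`
#'   (list of [reconstructed_path]), `scaffolds`, `alignments`, `graph`,
#'   `segment_maps`, `params`.
#' @export
reconstruct_amplicon <- function(graph, contigs, reference = NULL,
                                 segment_maps = NULL,
                                 params = scoring_params(), impute = TRUE,
                                 detect = FALSE, reference_maps = NULL) {
  if (is.null(segment_maps)) {
    if (is.null(reference))
      stop("reconstruct_amplicon: need reference or segment_maps")
    segment_maps <- digest_graph_segments(graph, reference, params$motif,
                                          params$label_offset)
  }
  names(contigs) <- vapply(contigs, function(m) m$map_id, "")

  run_alignments <- function(graph, segment_maps) {
    m_total <- sum(vapply(contigs, n_labels, 0L))
    alns <- list()
    for (sid in names(segment_maps)) {
      sm <- segment_maps[[sid]]
      n_r <- n_labels(sm)
      if (n_r < params$min_labels) next
      if (length(contigs) >= 40) {
        firsts <- lapply(contigs, align_segment, segment = sm,
                         mode = "semiglobal", params = params)
        best <- vapply(firsts, function(a) if (is.null(a)) -Inf else a$score, 0)
        cutoff <- significance_cutoff(best[is.finite(best)], m_total, n_r,
                                      params$p_semiglobal, params,
                                      segment = sm)
      } else {
        cutoff <- fallback_cutoff(sm, params)
      }
      for (cid in names(contigs)) {
        hits <- iterative_align(sm, contigs[[cid]], "semiglobal", params,
                                cutoff = cutoff)
        alns <- c(alns, hits)
      }
    }
    filter_alignments(alns, params)
  }

  alignments <- run_alignments(graph, segment_maps)

  build_all_scaffolds <- function(alignments) {
    by_contig <- split(alignments,
                       vapply(alignments, function(a) a$contig_id, ""))
    scaffolds <- list()
    for (cid in names(by_contig)) {
      sc <- build_scaffold(by_contig[[cid]], contigs[[cid]])
      if (impute) sc <- impute_scaffold(sc, graph, segment_maps, params)
      scaffolds[[cid]] <- sc
    }
    scaffolds
  }
  scaffolds <- build_all_scaffolds(alignments)

  if (detect && !is.null(reference_maps)) {
    regions <- detect_unaligned_regions(contigs, scaffolds)
    if (nrow(regions)) {
      new_graph <- detect_new_segments(regions, contigs, reference_maps,
                                       graph, params)
      if (nrow(new_graph$segments) > nrow(graph$segments)) {
        graph <- new_graph
        if (!is.null(reference))
          segment_maps <- digest_graph_segments(graph, reference,
                                                params$motif,
                                                params$label_offset)
        alignments <- run_alignments(graph, segment_maps)
        scaffolds <- build_all_scaffolds(alignments)
      }
    }
  }

  scaffold_paths <- unlist(lapply(scaffolds, heaviest_scaffold_paths),
                           recursive = FALSE)
  paths <- list()
  if (length(scaffold_paths)) {
    linked <- link_scaffolds(scaffold_paths)
    cands <- linked_graph_paths(linked)
    ok <- vapply(cands, function(p) cn_ratio_check(p$elements, graph),
                 logical(1))
    cands <- cands[ok]
    if (length(cands)) {
      bp <- vapply(cands, function(p)
        sum(segment_lengths(graph)[p$elements$segment_id]), 0)
      sc <- vapply(cands, function(p) p$score, 0)
      cands <- cands[order(-sc, -bp)]
      kept <- filter_subsequence_paths(cands)
      paths <- classify_and_emit(kept, graph)
    }
  }
  structure(list(paths = paths, scaffolds = scaffolds,
                 alignments = alignments, graph = graph,
                 segment_maps = segment_maps, params = params,
                 call = match.call()),
            class = "amplicon_reconstruction")
}

#' @export
print.amplicon_reconstruction <- function(x, ...) {
  cat(sprintf("<amplicon_reconstruction> %d path(s) from %d alignment(s) on %d contig(s)\n",
              length(x$paths), length(x$alignments), length(x$scaffolds)))
  for (p in head(x$paths, 5)) print(p)
  if (length(x$paths) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
summary.amplicon_reconstruction <- function(object, ...) {
  lens <- segment_lengths(object$graph)
  df <- do.call(rbind, lapply(seq_along(object$paths), function(i) {
    p <- object$paths[[i]]
    data.frame(path = i, n_elements = nrow(p$elements),
               length_bp = sum(lens[p$elements$segment_id]),
               cyclic = p$cyclic, score = p$total_alignment_score,
               contigs = paste(p$supporting_contigs, collapse = ","))
  }))
  if (is.null(df))
    df <- data.frame(path = integer(0), n_elements = integer(0),
                     length_bp = numeric(0), cyclic = logical(0),
                     score = numeric(0), contigs = character(0))
  structure(list(paths = df, n_alignments = length(object$alignments),
                 n_scaffolds = length(object$scaffolds)),
            class = "summary.amplicon_reconstruction")
}

#' @export
print.summary.amplicon_reconstruction <- function(x, ...) {
  cat(sprintf("Reconstruction summary: %d alignments, %d scaffolds\n",
              x$n_alignments, x$n_scaffolds))
  print(x$paths, row.names = FALSE)
  invisible(x)
}

#' Plot the scaffold layout of a reconstruction
#'
#' Draws, for each scaffold (contig), the contig as a horizontal line with
#' its label positions as ticks and each aligned segment as a coloured bar
#' over its aligned interval.
#'
#' @param x an `amplicon_reconstruction`.
#' @param max_scaffolds draw at most this many scaffolds (largest first).
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.amplicon_reconstruction <- function(x, max_scaffolds = 4, ...) {
  scs <- x$scaffolds[order(-vapply(x$scaffolds, function(s)
    length(s$nodes), 0L))]
  scs <- head(scs, max_scaffolds)
  if (!length(scs)) {
    graphics::plot.new()
    graphics::title("No scaffolds")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(length(scs), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  seg_ids <- x$graph$segments$segment_id
  cols <- grDevices::rainbow(length(seg_ids), s = 0.7, v = 0.85)
  names(cols) <- seg_ids
  for (sc in scs) {
    L <- sc$contig$length_bp
    graphics::plot(NA, xlim = c(0, L), ylim = c(0, 2), yaxt = "n",
                   xlab = "", ylab = sc$contig_id, bty = "n")
    graphics::segments(0, 0.4, L, 0.4)
    graphics::segments(sc$contig$positions, 0.3, sc$contig$positions, 0.5,
                       col = "grey40")
    for (a in sc$nodes) {
      r <- range(a$contig_pos)
      graphics::rect(r[1], 0.8, r[2], 1.4, col = cols[a$segment_id],
                     border = NA)
      graphics::text(mean(r), 1.7,
                     paste0(a$segment_id, a$orientation), cex = 0.7)
    }
  }
  invisible(x)
}
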