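#' Build the scaffold DAG for one contig
#'
#' Nodes are the significance-filtered alignments on one contig, ordered by
#' contig coordinate. A directed *allowed* edge connects a node to a later
#' node when the right endpoint of the source overlaps the left endpoint of
#' the destination by at most one label; pairs overlapping by more than one
#' label get a *forbidden* edge. The gap in bp between the source's last
#' aligned contig label and the destination's first is recorded on every
#' allowed edge.
#'
#' @param alignments list of [segment_alignment], all on one contig.
#' @param contig the contig [label_map].
#' @return object of class `scaffold_dag` with `nodes` (alignments sorted by
#'   contig start), `edges` (data.frame `from`, `to`, `kind`, `gap_bp`) and
#'   `imputed` (per-edge imputation slots).
#' @export
build_scaffold <- function(alignments, contig) {
  if (length(alignments)) {
    cid <- unique(vapply(alignments, function(a) a$contig_id, ""))
    if (length(cid) != 1 || cid != contig$map_id)
      stop("build_scaffold: alignments must all belong to the given contig")
  }
  first <- vapply(alignments, function(a) min(a$pairs[, "contig"]), 0)
  last <- vapply(alignments, function(a) max(a$pairs[, "contig"]), 0)
  ord <- order(first, last)
  nodes <- alignments[ord]
  first <- first[ord]; last <- last[ord]
  nn <- length(nodes)
  edges <- NULL
  if (nn >= 2) {
    # compatibility: right endpoint of u overlaps left endpoint of v by at
    # most one label
    compat <- matrix(FALSE, nn, nn)
    for (u in seq_len(nn)) for (v in seq_len(nn)) {
      if (u != v && first[u] <= first[v] && last[u] - first[v] + 1 <= 1)
        compat[u, v] <- TRUE
    }
    rows <- list()
    for (u in seq_len(nn - 1)) {
      for (v in (u + 1):nn) {
        if (compat[u, v]) {
          # adjacency: no compatible node sits strictly between u and v
          between <- any(compat[u, ] & compat[, v])
          if (!between) {
            rows[[length(rows) + 1L]] <- data.frame(
              from = u, to = v, kind = "allowed",
              gap_bp = contig$positions[first[v]] - contig$positions[last[u]])
          }
        } else if (!compat[v, u]) {
          rows[[length(rows) + 1L]] <- data.frame(
            from = u, to = v, kind = "forbidden", gap_bp = NA_real_)
        }
      }
    }
    edges <- do.call(rbind, rows)
  }
  if (is.null(edges))
    edges <- data.frame(from = integer(0), to = integer(0),
                        kind = character(0), gap_bp = numeric(0))
  structure(list(contig_id = contig$map_id, contig = contig, nodes = nodes,
                 edges = edges, imputed = vector("list", nrow(edges))),
            class = "scaffold_dag")
}

#' @export
print.scaffold_dag <- function(x, ...) {
  cat(sprintf("<scaffold_dag> contig %s: %d nodes, %d allowed / %d forbidden edges\n",
              x$contig_id, length(x$nodes), sum(x$edges$kind == "allowed"),
              sum(x$edges$kind == "forbidden")))
  invisible(x)
}

#' Find large unaligned contig regions
#'
#' On contigs that carry at least one segment alignment, reports the maximal
#' runs of contig labels not covered by any alignment with between
#' `min_labels` and `max_labels` unmatched labels and a region length
#' between `min_bp` and `max_bp`. These regions are candidates for
#' detection-mode alignment against the reference chromosomes.
#'
#' @param contigs named list of contig [label_map]s.
#' @param scaffolds named list of `scaffold_dag` (names = contig ids).
#' @param min_labels,max_labels unmatched-label bounds (default 20, 500).
#' @param min_bp,max_bp region length bounds (default 200 kbp, 5 Mbp).
#' @return data.frame with `contig_id`, `label_from`, `label_to`,
#'   `start_bp`, `end_bp`, `n_labels`, `length_bp`.
#' @export
detect_unaligned_regions <- function(contigs, scaffolds,
                                     min_labels = 20L, max_labels = 500L,
                                     min_bp = 2e5, max_bp = 5e6) {
  out <- list()
  for (sc in scaffolds) {
    if (!length(sc$nodes)) next
    contig <- contigs[[sc$contig_id]]
    m <- n_labels(contig)
    covered <- rep(FALSE, m)
    for (a in sc$nodes) {
      r <- aln_contig_range(a)
      covered[r[1]:r[2]] <- TRUE
    }
    r <- rle(covered)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1
    for (i in seq_along(r$values)) {
      if (r$values[i]) next
      nlab <- r$lengths[i]
      lo_bp <- if (lo[i] == 1) 0 else contig$positions[lo[i] - 1]
      hi_bp <- if (hi[i] == m) contig$length_bp else contig$positions[hi[i] + 1]
      len <- hi_bp - lo_bp
      if (nlab >= min_labels && nlab <= max_labels &&
          len >= min_bp && len <= max_bp) {
        out[[length(out) + 1L]] <- data.frame(
          contig_id = sc$contig_id, label_from = lo[i], label_to = hi[i],
          start_bp = lo_bp, end_bp = hi_bp, n_labels = nlab, length_bp = len)
      }
    }
  }
  if (!length(out))
    return(data.frame(contig_id = character(0), label_from = integer(0),
                      label_to = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_labels = integer(0),
                      length_bp = numeric(0)))
  do.call(rbind, out)
}

#' Search unaligned contig regions against reference chromosomes
#'
#' Runs detection-mode alignment of each unaligned region (as a query label
#' map) against each reference chromosome label map; significant hits are
#' appended to the breakpoint graph as new segments (copy number set to the
#' median amplified copy number of the existing graph).
#'
#' @param regions output of [detect_unaligned_regions].
#' @param contigs named list of contig [label_map]s.
#' @param reference_maps named list of chromosome [label_map]s (in silico
#'   digests of whole reference chromosomes).
#' @param graph a [breakpoint_graph] to extend.
#' @param params a [scoring_params].
#' @return the extended [breakpoint_graph].
#' @export
detect_new_segments <- function(regions, contigs, reference_maps, graph,
                                params = scoring_params()) {
  if (!nrow(regions)) return(graph)
  new_cn <- median(graph$segments$copy_number)
  next_id <- function() as.character(max(as.integer(graph$segments$segment_id),
                                         0L, na.rm = TRUE) + 1L)
  for (i in seq_len(nrow(regions))) {
    contig <- contigs[[regions$contig_id[i]]]
    idx <- regions$label_from[i]:regions$label_to[i]
    qpos <- contig$positions[idx] - regions$start_bp[i]
    query <- label_map(paste0(regions$contig_id[i], "_region", i),
                       regions$length_bp[i], qpos)
    best <- NULL
    scores <- numeric(0)
    for (chrom in names(reference_maps)) {
      a <- align_segment(query, reference_maps[[chrom]], mode = "detection",
                         params = params)
      scores <- c(scores, if (is.null(a)) -Inf else a$score)
      if (!is.null(a) && (is.null(best) || a$score > best$score)) {
        best <- a
        best$chrom <- chrom
      }
    }
    if (is.null(best)) next
    m_tot <- sum(vapply(reference_maps, n_labels, 0L))
    cutoff <- significance_cutoff(scores, m_tot, n_labels(query),
                                  params$p_detection, params,
                                  segment = query)
    if (best$score < cutoff) next
    ref <- reference_maps[[best$chrom]]
    hit_pos <- range(ref$positions[best$pairs[, "contig"]])
    graph$segments <- rbind(graph$segments, data.frame(
      segment_id = next_id(), chrom = best$chrom,
      start = floor(hit_pos[1]), end = ceiling(hit_pos[2]),
      copy_number = new_cn, stringsAsFactors = FALSE))
  }
  breakpoint_graph(graph$segments, graph$edges)
}
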