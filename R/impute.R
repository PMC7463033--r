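vertex_key <- function(id, side) paste0(id, "|", side)
other_side <- function(side) ifelse(side == "left", "right", "left")

# Adjacency list over (segment, side) vertices; breakpoint edges are
# traversable in both directions.
graph_adjacency <- function(graph) {
  adj <- list()
  add <- function(a_id, a_side, b_id, b_side) {
    k <- vertex_key(a_id, a_side)
    adj[[k]] <<- c(adj[[k]], list(list(id = b_id, side = b_side)))
  }
  ed <- graph$edges
  for (i in seq_len(nrow(ed))) {
    add(ed$from_id[i], ed$from_side[i], ed$to_id[i], ed$to_side[i])
    add(ed$to_id[i], ed$to_side[i], ed$from_id[i], ed$from_side[i])
  }
  adj
}

# Exit vertex of an aligned segment when the scaffold continues rightward,
# and entry vertex when it is reached from the left.
node_exit_vertex <- function(alignment) {
  list(id = alignment$segment_id,
       side = if (alignment$orientation == "+") "right" else "left")
}
node_entry_vertex <- function(alignment) {
  list(id = alignment$segment_id,
       side = if (alignment$orientation == "+") "left" else "right")
}

#' Enumerate breakpoint-graph paths across a scaffold gap
#'
#' Constrained depth-first search for all graph paths from the source
#' endpoint to the destination endpoint whose interior explains the gap.
#' Constraints: (1) per-segment multiplicity within the candidate never
#' exceeds the graph copy number; (2) a completed path must not be more than
#' `min(25000, 10000 * L_p)` bp shorter than the expected gap (`L_p` = path
#' length in segments); (3) a growing path must not exceed the expected gap
#' by more than the same bound; (4) at most `dfs_cap` candidates (default
#' 2^10) - when the DFS overflows, the search is re-run breadth-first with
#' the cap raised to `bfs_cap` (default 2^16); (5) no trivial cycles through
#' ultra-short segments (< 100 bp).
#'
#' @param graph a [breakpoint_graph].
#' @param source list `(id, side)`: vertex at which the source alignment
#'   exits its segment.
#' @param dest list `(id, side)`: vertex at which the destination alignment
#'   enters its segment.
#' @param expected_gap_bp expected interior length in bp.
#' @param dfs_cap,bfs_cap candidate-count caps for the two search phases.
#' @param max_expansions total state-expansion budget per search phase; an
#'   exhausted budget is treated like a candidate-cap overflow (the junction
#'   stays unimputed).
#' @return list of candidate paths, each a list with `elements` (data.frame
#'   `segment_id`, `orientation`), `bp_length`, `L_p`; empty when no path
#'   satisfies the constraints (or both search phases overflow).
#' @export
enumerate_gap_paths <- function(graph, source, dest, expected_gap_bp,
                                dfs_cap = 2^10, bfs_cap = 2^16,
                                max_expansions = 2e5) {
  adj <- graph_adjacency(graph)
  lens <- segment_lengths(graph)
  cns <- setNames(graph$segments$copy_number, graph$segments$segment_id)
  dest_key <- vertex_key(dest$id, dest$side)
  slack <- function(L_p) min(25000, 10000 * L_p)

  search <- function(cap, bfs) {
    out <- list()
    # growable frontier with head/top pointers (queue for BFS, stack for
    # DFS); states: exit vertex key, interior ids/orientations, bp length
    frontier <- vector("list", 1024)
    frontier[[1]] <- list(key = vertex_key(source$id, source$side),
                          ids = character(0), ors = character(0), bp = 0)
    head_i <- 1L
    tail_i <- 1L
    expansions <- 0L
    while (head_i <= tail_i) {
      expansions <- expansions + 1L
      if (expansions > max_expansions) return(list(overflow = TRUE))
      if (bfs) {
        st <- frontier[[head_i]]
        frontier[head_i] <- list(NULL)
        head_i <- head_i + 1L
      } else {
        st <- frontier[[tail_i]]
        frontier[tail_i] <- list(NULL)
        tail_i <- tail_i - 1L
      }
      for (nb in adj[[st$key]] %||% list()) {
        L_p <- length(st$ids)
        # reaching the destination entry completes a candidate
        if (vertex_key(nb$id, nb$side) == dest_key && L_p >= 1) {
          if (st$bp >= expected_gap_bp - slack(L_p)) {
            out[[length(out) + 1L]] <- list(
              elements = data.frame(segment_id = st$ids, orientation = st$ors,
                                    stringsAsFactors = FALSE),
              bp_length = st$bp, L_p = L_p)
            if (length(out) > cap) return(list(overflow = TRUE))
          }
        }
        # extend through nb as an interior segment
        seg_len <- lens[[nb$id]]
        if (is.null(seg_len)) next
        mult <- sum(st$ids == nb$id)
        if (mult + 1 > cns[[nb$id]]) next
        if (L_p >= 1 && st$ids[L_p] == nb$id && seg_len < 100) next
        new_bp <- st$bp + seg_len
        if (new_bp > expected_gap_bp + slack(L_p + 1)) next
        tail_i <- tail_i + 1L
        if (tail_i > length(frontier))
          frontier <- c(frontier, vector("list", length(frontier)))
        frontier[[tail_i]] <- list(
          key = vertex_key(nb$id, other_side(nb$side)),
          ids = c(st$ids, nb$id),
          ors = c(st$ors, side_to_sign(other_side(nb$side))),
          bp = new_bp)
      }
    }
    list(overflow = FALSE, paths = out)
  }

  r <- search(dfs_cap, bfs = FALSE)
  if (isTRUE(r$overflow)) r <- search(bfs_cap, bfs = TRUE)
  if (isTRUE(r$overflow)) return(list())
  r$paths
}

#' Score gap candidates by fitting alignment of a compound map
#'
#' Each candidate interior path is converted to a compound label map: the
#' source anchor label, the oriented digests of the interior segments laid
#' end to start with no inserted gap (breakpoint edges are direct
#' adjacencies), and the destination anchor label; the unaligned tail of the
#' source segment beyond its last aligned label and the head of the
#' destination segment before its first aligned label are accounted for as
#' unlabeled spacers. A fitting alignment of the compound map against the
#' contig interval between the two anchors scores the candidate. The best
#' candidate is returned only if it improves on the unimputed junction score
#' (all interior contig labels unexplained: `2c - c * n_interior`).
#'
#' @param candidates list from [enumerate_gap_paths].
#' @param contig the contig [label_map].
#' @param source_node,dest_node the flanking [segment_alignment]s.
#' @param segment_maps named list of segment [label_map]s.
#' @param params a [scoring_params].
#' @return list with `path` (the winning candidate), `score` and
#'   `unimputed_score`, or `NULL` when no candidate improves the junction.
#' @export
score_gap_candidates <- function(candidates, contig, source_node, dest_node,
                                 segment_maps, params = scoring_params()) {
  if (!length(candidates)) return(NULL)
  b_anchor_s <- max(source_node$pairs[, "contig"])
  b_anchor_t <- min(dest_node$pairs[, "contig"])
  if (b_anchor_t <= b_anchor_s) return(NULL)
  win_idx <- b_anchor_s:b_anchor_t
  wpos <- contig$positions[win_idx] - contig$positions[b_anchor_s] + 1
  n_int <- length(win_idx) - 2L
  unimputed <- 2 * params$c - params$c * n_int

  tail_bp <- function(a, end) {
    # unlabeled bp of the aligned segment beyond its outermost aligned label
    sp <- a$seg_pos
    if (a$orientation == "+") {
      if (end == "right") a$seg_len - max(sp) else min(sp)
    } else {
      if (end == "right") min(sp) else a$seg_len - max(sp)
    }
  }
  tail_s <- tail_bp(source_node, "right")
  head_t <- tail_bp(dest_node, "left")

  best <- NULL
  for (cand in candidates) {
    pos <- 1
    offset <- tail_s
    for (i in seq_len(nrow(cand$elements))) {
      sm <- segment_maps[[cand$elements$segment_id[i]]]
      if (is.null(sm)) { offset <- NA; break }
      p <- if (cand$elements$orientation[i] == "+") sm$positions
           else rev(sm$length_bp - sm$positions)
      pos <- c(pos, p + offset + 1)
      offset <- offset + sm$length_bp
    }
    if (is.na(offset)) next
    offset <- offset + head_t
    total_len <- offset + 2  # pad so no label sits exactly at either end
    pos <- c(pos, offset + 1)
    pos <- pos[pos > 0 & pos <= total_len]
    compound <- label_map("compound", total_len, sort(unique(pos)))
    window <- label_map("window", wpos[length(wpos)], wpos)
    a <- align_segment(compound, window, mode = "fitting", params = params)
    if (is.null(a)) next
    if (is.null(best) || a$score > best$score)
      best <- list(path = cand, score = a$score, unimputed_score = unimputed)
  }
  if (is.null(best) || best$score <= unimputed) return(NULL)
  best
}

#' Impute breakpoint-graph paths across scaffold gaps
#'
#' For every allowed edge with a positive gap below `max_gap_bp`, enumerates
#' candidate graph paths ([enumerate_gap_paths]) and keeps the best-scoring
#' one if it improves the junction ([score_gap_candidates]). The winning
#' path and its score are stored on the edge.
#'
#' @param scaffold a `scaffold_dag`.
#' @param graph a [breakpoint_graph].
#' @param segment_maps named list of segment [label_map]s.
#' @param params a [scoring_params].
#' @param max_gap_bp only gaps below this size are imputed (default 400 kbp).
#' @return the scaffold with `imputed` slots filled in.
#' @export
impute_scaffold <- function(scaffold, graph, segment_maps,
                            params = scoring_params(), max_gap_bp = 4e5) {
  ed <- scaffold$edges
  for (i in seq_len(nrow(ed))) {
    if (ed$kind[i] != "allowed") next
    gap <- ed$gap_bp[i]
    if (is.na(gap) || gap <= 0 || gap >= max_gap_bp) next
    src <- scaffold$nodes[[ed$from[i]]]
    dst <- scaffold$nodes[[ed$to[i]]]
    sv <- node_exit_vertex(src)
    dv <- node_entry_vertex(dst)
    tail_s <- {
      sp <- src$seg_pos
      if (src$orientation == "+") src$seg_len - max(sp) else min(sp)
    }
    head_t <- {
      sp <- dst$seg_pos
      if (dst$orientation == "+") min(sp) else dst$seg_len - max(sp)
    }
    expected <- gap - tail_s - head_t
    cands <- enumerate_gap_paths(graph, sv, dv, expected)
    res <- score_gap_candidates(cands, scaffold$contig, src, dst,
                                segment_maps, params)
    if (!is.null(res)) scaffold$imputed[[i]] <- res
  }
  scaffold
}
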