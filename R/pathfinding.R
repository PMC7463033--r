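#' Heaviest source-to-sink paths of a scaffold DAG
#'
#' Maximum-weight paths over allowed edges, where the weight of a path is
#' the summed bp length of its nodes' segments; computed by DP in node
#' order (nodes are sorted by contig coordinate, so the DAG is acyclic by
#' construction). All ties are retained.
#'
#' @param scaffold a `scaffold_dag`.
#' @return list of scaffold paths; each is a list with `contig_id`,
#'   `node_ids` (indices into `scaffold$nodes`), `elements` (oriented
#'   segment data.frame, imputed gap paths expanded in place),
#'   `weight_bp`, `score` (summed alignment scores plus imputation scores).
#' @export
heaviest_scaffold_paths <- function(scaffold) {
  nodes <- scaffold$nodes
  nn <- length(nodes)
  if (!nn) return(list())
  w <- vapply(nodes, function(a) a$seg_len, 0)
  ed <- scaffold$edges[scaffold$edges$kind == "allowed", , drop = FALSE]
  best <- w
  preds <- vector("list", nn)  # all argmax predecessors (ties retained)
  for (v in seq_len(nn)) {
    inc <- ed[ed$to == v, , drop = FALSE]
    if (nrow(inc)) {
      tot <- best[inc$from] + w[v]
      mx <- max(tot)
      if (mx > best[v]) {
        best[v] <- mx
        preds[[v]] <- inc$from[tot == mx]
      }
    }
  }
  mx <- max(best)
  ends <- which(best == mx)
  # backtrack all tied paths (capped defensively)
  paths <- list()
  expand <- function(v, acc) {
    acc <- c(v, acc)
    if (is.null(preds[[v]])) {
      paths[[length(paths) + 1L]] <<- acc
    } else {
      for (u in preds[[v]]) {
        if (length(paths) >= 16) return()
        expand(u, acc)
      }
    }
  }
  for (e in ends) expand(e, integer(0))
  lapply(paths, function(p) expand_scaffold_path(scaffold, p))
}

# Turn a node-index path into an oriented segment sequence, splicing in any
# imputed gap paths stored on the traversed edges.
expand_scaffold_path <- function(scaffold, node_ids) {
  nodes <- scaffold$nodes
  ed <- scaffold$edges
  elements <- NULL
  score <- 0
  for (i in seq_along(node_ids)) {
    v <- node_ids[i]
    a <- nodes[[v]]
    score <- score + a$score
    if (i > 1) {
      u <- node_ids[i - 1]
      ei <- which(ed$from == u & ed$to == v & ed$kind == "allowed")
      if (length(ei) == 1 && !is.null(scaffold$imputed[[ei]])) {
        imp <- scaffold$imputed[[ei]]
        elements <- rbind(elements, imp$path$elements)
        score <- score + max(imp$score, 0)
      }
    }
    elements <- rbind(elements,
                      data.frame(segment_id = a$segment_id,
                                 orientation = a$orientation,
                                 stringsAsFactors = FALSE))
  }
  # clip evidence at the path ends: how many segment labels of the terminal
  # alignments lie beyond the aligned part in the direction of travel (a
  # segment truncated by the contig end is evidence that the structure
  # continues on another contig)
  clip_of <- function(a, end) {
    s <- a$pairs[, "segment"]
    if ((a$orientation == "+") == (end == "last"))
      a$seg_nlabels - max(s)
    else
      min(s) - 1
  }
  first_a <- nodes[[node_ids[1]]]
  last_a <- nodes[[node_ids[length(node_ids)]]]
  list(contig_id = scaffold$contig_id, node_ids = node_ids,
       elements = elements,
       weight_bp = sum(vapply(nodes[node_ids], function(a) a$seg_len, 0)),
       score = score,
       clip_start = clip_of(first_a, "first"),
       clip_end = clip_of(last_a, "last"))
}

path_tokens <- function(elements)
  paste0(elements$segment_id, elements$orientation)

reverse_elements <- function(elements) {
  data.frame(segment_id = rev(elements$segment_id),
             orientation = ifelse(rev(elements$orientation) == "+", "-", "+"),
             stringsAsFactors = FALSE)
}

# Is `small` a contiguous substring of `big` (token-wise)?
is_substring <- function(small, big) {
  ns <- length(small); nb <- length(big)
  if (ns == 0) return(TRUE)
  if (ns > nb) return(FALSE)
  for (s in 0:(nb - ns)) {
    if (all(big[s + seq_len(ns)] == small)) return(TRUE)
  }
  FALSE
}

#' Link scaffold paths across contigs
#'
#' Two scaffold paths from different contigs are linked when a suffix of one
#' equals a prefix of the other (as oriented segment sequences) - evidence
#' that the same graph segment(s) anchor both contigs. Because a contig may
#' be assembled in either direction, each path is considered in both its
#' forward and reverse-complement form.
#'
#' @param scaffold_paths list of scaffold paths
#'   (from [heaviest_scaffold_paths], possibly over several contigs).
#' @return object of class `linked_scaffold_graph`: `nodes` (the paths in
#'   both orientations) and `links` (data.frame `from`, `to`, `overlap`).
#' @export
link_scaffolds <- function(scaffold_paths) {
  nodes <- list()
  for (i in seq_along(scaffold_paths)) {
    p <- scaffold_paths[[i]]
    nodes[[length(nodes) + 1L]] <- c(p, list(base = i, dir = "+"))
    q <- p
    q$elements <- reverse_elements(p$elements)
    q$clip_start <- p$clip_end %||% 0
    q$clip_end <- p$clip_start %||% 0
    nodes[[length(nodes) + 1L]] <- c(q, list(base = i, dir = "-"))
  }
  links <- list()
  # clip evidence threshold: under the standard noise model a terminal
  # label is effectively lost (missed or collapsed) with probability ~0.25,
  # so requiring 5 consecutive unaligned terminal labels keeps the false
  # link-evidence rate near 0.1% while genuine contig truncations (tens of
  # labels) always qualify
  min_clip <- 5L
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (nodes[[i]]$base == nodes[[j]]$base) next
      # evidence requirement: the shared terminal segment must be truncated
      # by the contig end on at least one side of the join
      if ((nodes[[i]]$clip_end %||% 0) < min_clip &&
          (nodes[[j]]$clip_start %||% 0) < min_clip) next
      ti <- path_tokens(nodes[[i]]$elements)
      tj <- path_tokens(nodes[[j]]$elements)
      for (o in seq(min(length(ti), length(tj)) - 0, 1)) {
        if (o >= length(ti) && o >= length(tj)) next  # identical containment
        if (identical(tail(ti, o), head(tj, o))) {
          links[[length(links) + 1L]] <- data.frame(from = i, to = j,
                                                    overlap = o)
          break
        }
      }
    }
  }
  links <- if (length(links)) do.call(rbind, links)
           else data.frame(from = integer(0), to = integer(0),
                           overlap = integer(0))
  structure(list(nodes = nodes, links = links),
            class = "linked_scaffold_graph")
}

#' Enumerate candidate reconstruction paths in the linked scaffold graph
#'
#' Searches all simple chains starting at endpoint nodes (nodes with no
#' incoming link), using each underlying scaffold at most once per chain,
#' and merges the member paths with their overlaps. Individual scaffold
#' paths are always included as candidates.
#'
#' @param linked a `linked_scaffold_graph`.
#' @param max_chains search budget (default 5000).
#' @return list of candidate paths (same shape as scaffold paths, with
#'   `supporting_contigs`).
#' @export
linked_graph_paths <- function(linked, max_chains = 5000) {
  nodes <- linked$nodes
  links <- linked$links
  out <- list()
  emit <- function(chain) {
    els <- nodes[[chain[1]]]$elements
    score <- nodes[[chain[1]]]$score
    if (length(chain) > 1) {
      for (k in 2:length(chain)) {
        o <- links$overlap[links$from == chain[k - 1] & links$to == chain[k]][1]
        nx <- nodes[[chain[k]]]$elements
        if (o < nrow(nx)) els <- rbind(els, nx[(o + 1):nrow(nx), ])
        score <- score + nodes[[chain[k]]]$score
      }
    }
    out[[length(out) + 1L]] <<- list(
      elements = els, score = score,
      supporting_contigs = unique(vapply(chain, function(i)
        nodes[[i]]$contig_id, "")))
  }
  has_incoming <- unique(links$to)
  starts <- setdiff(seq_along(nodes), has_incoming)
  if (!length(starts)) starts <- seq_along(nodes)
  walk <- function(chain, used_bases) {
    if (length(out) >= max_chains) return()
    emit(chain)
    nxt <- links$to[links$from == chain[length(chain)]]
    for (v in nxt) {
      if (nodes[[v]]$base %in% used_bases) next
      walk(c(chain, v), c(used_bases, nodes[[v]]$base))
    }
  }
  for (s in starts) walk(s, nodes[[s]]$base)
  # drop exact duplicates (each base path appears in two orientations)
  keys <- vapply(out, function(p) paste(path_tokens(p$elements),
                                        collapse = " "), "")
  rkeys <- vapply(out, function(p)
    paste(path_tokens(reverse_elements(p$elements)), collapse = " "), "")
  keep <- !duplicated(pmin(keys, rkeys))
  out[keep]
}

#' Copy-number ratio check for a candidate path
#'
#' For every segment `n` in the path with multiplicity `n_p` and every
#' integer level `c` with `0 < c < n_p` at which some path segment sits
#' (`m_g` = the maximum graph copy number among segments with multiplicity
#' exactly `c`), the multiplicity ratio must be consistent with the copy
#' number ratio: `n_p <= max(c, c * n_g / m_g) + 1`, i.e. each segment may
#' exceed the ratio-implied copy count by at most one.
#'
#' @param elements oriented segment data.frame (`segment_id`,
#'   `orientation`).
#' @param graph a [breakpoint_graph] providing copy numbers.
#' @return `TRUE` when every (segment, level) pair passes.
#' @export
cn_ratio_check <- function(elements, graph) {
  cns <- setNames(graph$segments$copy_number, graph$segments$segment_id)
  ids <- elements$segment_id
  if (!all(ids %in% names(cns)))
    stop("cn_ratio_check: path segment missing from graph")
  if (any(cns[unique(ids)] <= 0))
    stop("cn_ratio_check: path segment has non-positive copy number")
  mult <- table(ids)
  n_p <- as.numeric(mult)
  names(n_p) <- names(mult)
  for (seg in names(n_p)) {
    np <- n_p[[seg]]
    if (np <= 1) next
    for (c_lvl in seq_len(np - 1)) {
      at_level <- names(n_p)[n_p == c_lvl]
      if (!length(at_level)) next
      m_g <- max(cns[at_level])
      if (np > max(c_lvl, c_lvl * cns[[seg]] / m_g) + 1) return(FALSE)
    }
  }
  TRUE
}

#' Greedy filtering of rotation-subsequence paths
#'
#' Paths must arrive sorted by decreasing total alignment score. Each path
#' is kept unless some rotation of it (or of its orientation-reversed form)
#' is a contiguous substring of an already-kept path.
#'
#' @param paths list of candidate paths (lists with `elements`, `score`).
#' @return the kept paths, in input order.
#' @export
filter_subsequence_paths <- function(paths) {
  kept <- list()
  kept_tokens <- list()
  rotations <- function(tok) {
    n <- length(tok)
    lapply(seq_len(n), function(s) tok[((seq_len(n) + s - 2) %% n) + 1])
  }
  for (p in paths) {
    tok <- path_tokens(p$elements)
    rtok <- path_tokens(reverse_elements(p$elements))
    forms <- c(rotations(tok), rotations(rtok))
    contained <- any(vapply(kept_tokens, function(kt)
      any(vapply(forms, is_substring, logical(1), big = kt)), logical(1)))
    if (!contained) {
      kept[[length(kept) + 1L]] <- p
      kept_tokens[[length(kept_tokens) + 1L]] <- tok
    }
  }
  kept
}

#' Classify candidate paths as cyclic or linear and emit reconstructions
#'
#' A path is cyclic when its head and tail repeat the same scaffold
#' elements (the contig wraps past the origin of a circular structure):
#' the largest overlap `o >= 1` with `head(o) == tail(o)` is folded away,
#' provided the path has more than 2 elements - singletons and length-2
#' repeats (segmental tandem duplications) stay linear.
#'
#' @param paths list of candidate paths (with `elements`, `score`,
#'   optionally `supporting_contigs`).
#' @param graph a [breakpoint_graph] (used for copy-count annotation).
#' @return list of [reconstructed_path].
#' @export
classify_and_emit <- function(paths, graph = NULL) {
  lapply(paths, function(p) {
    tok <- path_tokens(p$elements)
    n <- length(tok)
    cyclic <- FALSE
    els <- p$elements
    if (n >= 3) {
      for (o in seq(floor(n / 2), 1)) {
        if (n - o < 2) next
        if (identical(tok[seq_len(o)], tok[(n - o + 1):n])) {
          cyclic <- TRUE
          els <- p$elements[seq_len(n - o), , drop = FALSE]
          break
        }
      }
    }
    cn <- if (!is.null(graph)) {
      cns <- setNames(graph$segments$copy_number, graph$segments$segment_id)
      round(median(cns[els$segment_id]))
    } else 1
    reconstructed_path(els, cyclic = cyclic,
                       total_alignment_score = p$score,
                       supporting_contigs = p$supporting_contigs %||%
                         p$contig_id %||% character(0),
                       copy_count = cn)
  })
}

#' Cluster split-molecule alignments into putative integration points
#'
#' Single-linkage clustering of split alignments (one partial alignment
#' inside the amplicon, one outside): two molecules support the same
#' junction when both breakpoint coordinates agree within `tol_bp` on the
#' same chromosome pair. Clusters supported by at least `min_molecules`
#' molecules are reported with median coordinates.
#'
#' @param splits data.frame with columns `molecule_id`, `inside_chrom`,
#'   `inside_pos`, `outside_chrom`, `outside_pos`.
#' @param tol_bp linkage tolerance per side (default 25 kbp).
#' @param min_molecules minimum cluster support (default 10).
#' @return data.frame of clusters: `inside_chrom`, `inside_pos`,
#'   `outside_chrom`, `outside_pos` (medians), `n_molecules`.
#' @export
cluster_integration_points <- function(splits, tol_bp = 25000,
                                       min_molecules = 10L) {
  empty <- data.frame(inside_chrom = character(0), inside_pos = numeric(0),
                      outside_chrom = character(0), outside_pos = numeric(0),
                      n_molecules = integer(0))
  n <- nrow(splits)
  if (!n) return(empty)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (splits$inside_chrom[i] == splits$inside_chrom[j] &&
          splits$outside_chrom[i] == splits$outside_chrom[j] &&
          abs(splits$inside_pos[i] - splits$inside_pos[j]) <= tol_bp &&
          abs(splits$outside_pos[i] - splits$outside_pos[j]) <= tol_bp) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  out <- list()
  for (r in unique(roots)) {
    idx <- which(roots == r)
    if (length(idx) < min_molecules) next
    out[[length(out) + 1L]] <- data.frame(
      inside_chrom = splits$inside_chrom[idx[1]],
      inside_pos = median(splits$inside_pos[idx]),
      outside_chrom = splits$outside_chrom[idx[1]],
      outside_pos = median(splits$outside_pos[idx]),
      n_molecules = length(idx))
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}
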