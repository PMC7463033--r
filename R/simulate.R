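#' Simulation configuration
#'
#' Collects every tunable of the amplicon/optical-map simulator. Defaults
#' are the package's standard study conditions: 10\% label miss, label
#' collapse below the ~2 kbp imaging scale via the merge model, and Gaussian
#' per-interval sizing error with sd = 2\% of the interval length.
#'
#' @param n_segments number of graph segments of the amplicon.
#' @param total_bp total amplicon length in bp.
#' @param cyclic logical; circular (ecDNA-like) or linear structure.
#' @param copy_number amplicon copy number (default 20).
#' @param label_miss_rate per-label Bernoulli miss probability.
#' @param sizing_sd relative sd of the Gaussian per-interval sizing error.
#' @param collapse logical; apply label collapse with the merge model.
#' @param coverage fold coverage for molecule simulation.
#' @param molecule_median_bp,molecule_sdlog molecule length model
#'   (log-normal, truncated below at `molecule_min_bp`).
#' @param molecule_min_bp minimum molecule length (assembly input cutoff).
#' @param contig_break_rate contig breaks per Mbp (0 = spanning contigs).
#' @param false_edge_fraction proportion of true edges to add as false
#'   discordant edges.
#' @param min_seg_bp minimum interior segment length.
#' @param terminal_seg_bp minimum length of the terminal segments of linear
#'   structures (and of the rotation origin of cyclic ones), so that path
#'   ends carry enough labels to anchor an alignment.
#' @param n_rearrangements number of rearrangement operations; default
#'   `1 + rpois(1, 2)`.
#' @param ensure_duplication force a tandem duplication of a 1-3 segment
#'   block of roughly `dup_block_bp` total length.
#' @param dup_block_bp target duplicated-block length (default 280 kbp).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_segments = 9L, total_bp = 2e6, cyclic = TRUE,
                       copy_number = 20, label_miss_rate = 0.10,
                       sizing_sd = 0.02, collapse = TRUE, coverage = 40,
                       molecule_median_bp = 244e3, molecule_sdlog = 0.35,
                       molecule_min_bp = 150e3, contig_break_rate = 0,
                       false_edge_fraction = 0, min_seg_bp = 15e3,
                       terminal_seg_bp = 120e3, n_rearrangements = NULL,
                       ensure_duplication = FALSE, dup_block_bp = 280e3) {
  stopifnot(label_miss_rate >= 0, label_miss_rate <= 1, sizing_sd >= 0,
            n_segments >= 1, total_bp > 0, copy_number >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic reference genome
#'
#' I.i.d. random bases at uniform composition, which gives a realistic
#' density of 6-7 bp label motifs (roughly one DLE-1 site per 4 kbp). The
#' sequence is deterministic given the RNG state.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len length of each chromosome (bp).
#' @return a named [Biostrings::DNAStringSet] (`chr1`, `chr2`, ...).
#' @export
random_reference <- function(n_chrom = 2L, chrom_len = 6e6) {
  seqs <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = "")
  }, "")
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- paste0("chr", seq_len(n_chrom))
  ref
}

#' Simulate a rearranged amplicon structure and its breakpoint graph
#'
#' Partitions a random reference region into segments, applies random
#' rearrangement operations (inversions, duplications - optionally inverted
#' - and block translocations) to the identity path, and emits the true
#' oriented segment path together with its implied breakpoint graph. Graph
#' copy numbers are exact: per-segment path multiplicity times the amplicon
#' copy number. Cyclic structures are rotated so that the longest segment
#' comes first (any rotation is an equivalent representation of the
#' circle); linear structures place long segments at both termini.
#'
#' @param config a [sim_config].
#' @param reference a named [Biostrings::DNAStringSet].
#' @param partition optional precomputed segment partition (list with
#'   `chrom`, `starts`, `ends`, `lens`), used when several related
#'   structures must share one segment set (heterogeneous mixtures).
#' @return list of class `amplicon_truth`: `elements`, `cyclic`, `graph`,
#'   `region` (chrom/start/end), `copy_number`, and `dup_block` (when a
#'   duplication was forced: `first`, `len`, `mult`).
#' @export
simulate_amplicon_structure <- function(config, reference, partition = NULL) {
  n <- config$n_segments
  total <- config$total_bp
  if (is.null(partition)) {
    chrom <- sample(names(reference), 1)
    clen <- length(reference[[chrom]])
    if (total >= clen) stop("simulate_amplicon_structure: amplicon larger than reference")
    need <- if (config$cyclic) config$terminal_seg_bp + (n - 1) * config$min_seg_bp
            else min(2, n) * config$terminal_seg_bp +
                 max(n - 2, 0) * config$min_seg_bp
    if (total < need)
      stop("simulate_amplicon_structure: total_bp too small for segment minimums")
    start <- floor(runif(1, 1, clen - total))

    # segment length partition with minimum floors
    floors <- rep(config$min_seg_bp, n)
    big_idx <- if (config$cyclic) sample.int(n, 1) else sample.int(n, min(2, n))
    floors[big_idx] <- config$terminal_seg_bp
    extra <- total - sum(floors)
    wts <- runif(n)
    lens <- floor(floors + extra * wts / sum(wts))
    lens[n] <- lens[n] + (total - sum(lens))
    ends <- start - 1 + cumsum(lens)
    starts <- c(start, head(ends, -1) + 1)
  } else {
    chrom <- partition$chrom
    starts <- partition$starts
    ends <- partition$ends
    lens <- partition$lens
    n <- length(lens)
    start <- starts[1]
    total <- sum(lens)
  }

  elements <- data.frame(segment_id = as.character(seq_len(n)),
                         orientation = rep("+", n), stringsAsFactors = FALSE)
  seg_len_of <- function(els) lens[as.integer(els$segment_id)]

  n_ops <- if (n < 2) 0 else config$n_rearrangements %||% (1 + rpois(1, 2))
  for (op in seq_len(n_ops)) {
    len_path <- nrow(elements)
    if (sum(seg_len_of(elements)) > 1.5 * total) break
    kind <- sample(c("inversion", "duplication", "translocation"), 1,
                   prob = c(0.4, 0.3, 0.3))
    span <- sample.int(max(1, min(3, len_path - 1)), 1)
    at <- sample.int(len_path - span + 1, 1)
    block <- elements[at:(at + span - 1), , drop = FALSE]
    rest_pre <- elements[seq_len(at - 1), , drop = FALSE]
    rest_post <- if (at + span <= len_path)
      elements[(at + span):len_path, , drop = FALSE] else elements[0, ]
    if (kind == "inversion") {
      elements <- rbind(rest_pre, reverse_elements(block), rest_post)
    } else if (kind == "duplication") {
      dup <- if (runif(1) < 0.3) reverse_elements(block) else block
      elements <- rbind(rest_pre, block, dup, rest_post)
    } else {
      gap_positions <- 0:nrow(rbind(rest_pre, rest_post))
      ins <- sample(gap_positions, 1)
      rem <- rbind(rest_pre, rest_post)
      elements <- rbind(rem[seq_len(ins), , drop = FALSE], block,
                        if (ins < nrow(rem))
                          rem[(ins + 1):nrow(rem), , drop = FALSE])
    }
    rownames(elements) <- NULL
  }

  # orient path ends onto well-labeled segments
  if (config$cyclic) {
    anchor <- which(elements$segment_id == as.character(which.max(lens)))[1]
    if (is.na(anchor)) anchor <- 1
    idx <- ((seq_len(nrow(elements)) + anchor - 2) %% nrow(elements)) + 1
    elements <- elements[idx, , drop = FALSE]
    rownames(elements) <- NULL
  } else {
    big2 <- order(lens, decreasing = TRUE)[seq_len(min(2, n))]
    place <- function(seg, pos) {
      j <- which(elements$segment_id == as.character(seg))[1]
      if (!is.na(j) && j != pos) {
        tmp <- elements[j, ]; elements[j, ] <<- elements[pos, ]
        elements[pos, ] <<- tmp
      }
    }
    place(big2[1], 1L)
    if (length(big2) > 1) place(big2[2], nrow(elements))
    ft <- path_tokens(elements)
    if (ft[1] == ft[length(ft)] && nrow(elements) > 1)
      elements$orientation[nrow(elements)] <-
        ifelse(elements$orientation[nrow(elements)] == "+", "-", "+")
  }

  # force a tandem duplication of an interior block close to the target
  # size; done after end placement so the copies stay contiguous
  dup_block <- NULL
  if (config$ensure_duplication) {
    len_path <- nrow(elements)
    best <- NULL
    for (span in 1:min(3, len_path)) {
      lo_at <- if (len_path - span >= 1) 2L else 1L
      hi_at <- max(lo_at, len_path - span)
      for (at in lo_at:hi_at) {
        bl <- sum(seg_len_of(elements[at:(at + span - 1), , drop = FALSE]))
        d <- abs(bl - config$dup_block_bp)
        if (is.null(best) || d < best$d) best <- list(at = at, span = span, d = d)
      }
    }
    at <- best$at; span <- best$span
    block <- elements[at:(at + span - 1), , drop = FALSE]
    elements <- rbind(elements[seq_len(at + span - 1), , drop = FALSE], block,
                      if (at + span <= nrow(elements))
                        elements[(at + span):nrow(elements), , drop = FALSE])
    rownames(elements) <- NULL
    dup_block <- list(block = block, mult = 2L)
  }

  truth_graph <- implied_graph(elements, chrom, starts, ends, lens,
                               config$copy_number, config$cyclic)
  structure(list(elements = elements, cyclic = config$cyclic,
                 graph = truth_graph,
                 region = list(chrom = chrom, start = start,
                               end = start - 1 + total),
                 copy_number = config$copy_number, dup_block = dup_block,
                 partition = list(chrom = chrom, starts = starts, ends = ends,
                                  lens = lens),
                 inserts = NULL),
            class = "amplicon_truth")
}

# Breakpoint graph implied by a truth path: segments with CN = multiplicity
# x amplicon copy number; one edge per distinct junction (wrap included for
# cyclic paths), concordant when the junction matches reference adjacency.
implied_graph <- function(elements, chrom, starts, ends, lens, copy_number,
                          cyclic) {
  n <- length(lens)
  mult <- table(factor(elements$segment_id, levels = as.character(seq_len(n))))
  segs <- data.frame(segment_id = as.character(seq_len(n)), chrom = chrom,
                     start = starts, end = ends,
                     copy_number = as.numeric(mult) * copy_number,
                     stringsAsFactors = FALSE)
  juncs <- list()
  np <- nrow(elements)
  idx_pairs <- if (np >= 2) cbind(1:(np - 1), 2:np) else NULL
  if (cyclic) idx_pairs <- rbind(idx_pairs, c(np, 1))
  for (r in seq_len(NROW(idx_pairs))) {
    a <- elements[idx_pairs[r, 1], ]
    b <- elements[idx_pairs[r, 2], ]
    ai <- as.integer(a$segment_id); bi <- as.integer(b$segment_id)
    from_side <- if (a$orientation == "+") "right" else "left"
    to_side <- if (b$orientation == "+") "left" else "right"
    concordant <- (a$orientation == "+" && b$orientation == "+" &&
                     ends[ai] + 1 == starts[bi]) ||
                  (a$orientation == "-" && b$orientation == "-" &&
                     ends[bi] + 1 == starts[ai])
    key <- paste(sort(c(vertex_key(a$segment_id, from_side),
                        vertex_key(b$segment_id, to_side))), collapse = "~")
    if (is.null(juncs[[key]])) {
      juncs[[key]] <- data.frame(
        from_id = a$segment_id, from_side = from_side,
        to_id = b$segment_id, to_side = to_side,
        type = if (concordant) "concordant" else "discordant",
        multiplicity = 1, stringsAsFactors = FALSE)
    } else {
      juncs[[key]]$multiplicity <- juncs[[key]]$multiplicity + 1
    }
  }
  breakpoint_graph(segs, if (length(juncs)) do.call(rbind, juncs) else NULL)
}

#' Build the bp sequence of a truth path
#'
#' Concatenates the oriented segment sequences (and any unlabeled inserts).
#' For cyclic truths, `wrap = TRUE` appends the first path element again so
#' a spanning contig covers the circle past its origin.
#'
#' @param truth an `amplicon_truth`.
#' @param reference the reference [Biostrings::DNAStringSet].
#' @param wrap logical; append the first element once more (cyclic only).
#' @return a [Biostrings::DNAString].
#' @export
truth_sequence <- function(truth, reference, wrap = truth$cyclic) {
  segs <- truth$graph$segments
  build_one <- function(i) {
    el <- truth$elements[i, ]
    j <- match(el$segment_id, segs$segment_id)
    s <- segment_sequence(reference, segs$chrom[j], segs$start[j],
                          segs$end[j], el$orientation)
    ins <- truth$inserts
    if (!is.null(ins)) {
      ii <- which(ins$after_index == i)
      if (length(ii))
        s <- Biostrings::xscat(s, Biostrings::DNAString(
          paste(sample(c("A", "T"), ins$length_bp[ii[1]], replace = TRUE),
                collapse = "")))
    }
    s
  }
  parts <- lapply(seq_len(nrow(truth$elements)), build_one)
  if (wrap && truth$cyclic) parts <- c(parts, parts[1])
  out <- parts[[1]]
  for (k in seq_along(parts)[-1]) out <- Biostrings::xscat(out, parts[[k]])
  Biostrings::DNAString(out)
}

#' Apply the optical-map noise model to a digest
#'
#' In order: label collapse (adjacent labels merge to their midpoint with
#' probability [merge_probability] of their gap), label miss (i.i.d.
#' Bernoulli), and sizing error (each inter-label interval, including the
#' terminal ones, is rescaled by `1 + N(0, sizing_sd)`, truncated to stay
#' positive).
#'
#' @param map a [label_map].
#' @param config a [sim_config].
#' @param params a [scoring_params] (supplies the merge model).
#' @return a noisy [label_map].
#' @export
apply_om_noise <- function(map, config, params = scoring_params()) {
  pos <- map$positions
  if (config$collapse && length(pos) >= 2) {
    keep <- rep(TRUE, length(pos))
    i <- 1
    while (i < length(pos)) {
      if (keep[i]) {
        gap <- pos[i + 1] - pos[i]
        if (gap < params$w && runif(1) < merge_probability(gap, params)) {
          pos[i] <- (pos[i] + pos[i + 1]) / 2
          keep[i + 1] <- FALSE
          i <- i + 2
          next
        }
      }
      i <- i + 1
    }
    pos <- pos[keep]
  }
  if (config$label_miss_rate > 0 && length(pos)) {
    pos <- pos[runif(length(pos)) > config$label_miss_rate]
  }
  if (config$sizing_sd > 0) {
    iv <- diff(c(0, pos, map$length_bp))
    iv <- pmax(1e-3, iv * (1 + rnorm(length(iv), 0, config$sizing_sd)))
    cum <- cumsum(iv)
    len <- cum[length(cum)]
    pos <- head(cum, -1)
  } else {
    len <- map$length_bp
  }
  label_map(map$map_id, len, pos)
}

#' Simulate noisy consensus contigs from a truth path
#'
#' Digests the truth sequence and applies the noise model once - a direct
#' stand-in for the molecule-simulation + de novo assembly pipeline that
#' produces real consensus maps. With `contig_break_rate > 0`, the spanning
#' contig is additionally fragmented at Poisson break points to emulate
#' assembly failure.
#'
#' @param truth an `amplicon_truth`.
#' @param reference the reference genome.
#' @param config a [sim_config].
#' @param params a [scoring_params] (motif and merge model).
#' @param id_prefix contig id prefix.
#' @return list of contig [label_map]s.
#' @export
simulate_contigs <- function(truth, reference, config,
                             params = scoring_params(),
                             id_prefix = "contig") {
  seqn <- truth_sequence(truth, reference)
  digest <- digest_sequence(seqn, params$motif, map_id = paste0(id_prefix, "_1"),
                            offset = params$label_offset)
  pieces <- list(digest)
  if (config$contig_break_rate > 0) {
    nb <- rpois(1, config$contig_break_rate * digest$length_bp / 1e6)
    if (nb > 0) {
      cuts <- sort(runif(nb, 0, digest$length_bp))
      bounds <- cbind(c(0, cuts), c(cuts, digest$length_bp))
      pieces <- list()
      for (i in seq_len(nrow(bounds))) {
        lo <- bounds[i, 1]; hi <- bounds[i, 2]
        if (hi - lo < config$molecule_min_bp) next
        sel <- digest$positions > lo & digest$positions <= hi
        pieces[[length(pieces) + 1L]] <- label_map(
          paste0(id_prefix, "_", length(pieces) + 1L), hi - lo,
          digest$positions[sel] - lo)
      }
    }
  }
  lapply(pieces, apply_om_noise, config = config, params = params)
}

#' Simulate single optical-map molecules from a truth path
#'
#' Random substrings of the truth sequence at the configured coverage, with
#' log-normal lengths (median `molecule_median_bp`, truncated at
#' `molecule_min_bp`) and the same noise model as contigs. For cyclic
#' truths, molecules may span the circle origin.
#'
#' @inheritParams simulate_contigs
#' @return list of molecule [label_map]s.
#' @export
simulate_molecules <- function(truth, reference, config,
                               params = scoring_params(),
                               id_prefix = "mol") {
  if (config$coverage <= 0) return(list())
  seqn <- truth_sequence(truth, reference, wrap = FALSE)
  digest <- digest_sequence(seqn, params$motif, map_id = "t",
                            offset = params$label_offset)
  L <- digest$length_bp
  pos <- digest$positions
  n_mol <- max(1L, round(config$coverage * L / config$molecule_median_bp))
  out <- vector("list", n_mol)
  for (i in seq_len(n_mol)) {
    ml <- max(config$molecule_min_bp,
              rlnorm(1, log(config$molecule_median_bp), config$molecule_sdlog))
    ml <- min(ml, L)
    st <- runif(1, 0, if (truth$cyclic) L else max(L - ml, 1))
    p <- if (truth$cyclic) {
      pp <- (pos - st) %% L
      sort(pp[pp <= ml & pp > 0])
    } else {
      pos[pos > st & pos <= st + ml] - st
    }
    out[[i]] <- apply_om_noise(label_map(paste0(id_prefix, "_", i), ml, p),
                               config, params)
  }
  out
}

#' Add false discordant edges to a breakpoint graph
#'
#' Adds `round(fraction * n_edges)` random discordant edges between
#' existing segment endpoints, none duplicating an existing edge.
#'
#' @param graph a [breakpoint_graph].
#' @param fraction proportion of the current edge count to add.
#' @return the corrupted [breakpoint_graph].
#' @export
inject_false_edges <- function(graph, fraction) {
  if (fraction < 0) stop("inject_false_edges: fraction must be >= 0")
  n_new <- round(fraction * nrow(graph$edges))
  if (n_new == 0) return(graph)
  ids <- graph$segments$segment_id
  sides <- c("left", "right")
  all_pairs <- expand.grid(a = seq_along(ids), as_ = sides,
                           b = seq_along(ids), bs = sides,
                           stringsAsFactors = FALSE)
  key_of <- function(id1, s1, id2, s2)
    paste(pmin(vertex_key(id1, s1), vertex_key(id2, s2)),
          pmax(vertex_key(id1, s1), vertex_key(id2, s2)), sep = "~")
  existing <- with(graph$edges, key_of(from_id, from_side, to_id, to_side))
  cand_keys <- key_of(ids[all_pairs$a], all_pairs$as_,
                      ids[all_pairs$b], all_pairs$bs)
  ok <- !(cand_keys %in% existing) & !duplicated(cand_keys) &
    !(ids[all_pairs$a] == ids[all_pairs$b] & all_pairs$as_ == all_pairs$bs)
  cand <- all_pairs[ok, , drop = FALSE]
  if (nrow(cand) < n_new)
    stop("inject_false_edges: not enough distinct endpoint pairs")
  pick <- cand[sample.int(nrow(cand), n_new), , drop = FALSE]
  new_edges <- data.frame(from_id = ids[pick$a], from_side = pick$as_,
                          to_id = ids[pick$b], to_side = pick$bs,
                          type = "discordant", multiplicity = 1,
                          stringsAsFactors = FALSE)
  breakpoint_graph(graph$segments, rbind(graph$edges, new_edges))
}

#' Pool data from several amplicons into a heterogeneous mixture
#'
#' Simulates one spanning consensus contig per amplicon and a molecule pool
#' downsampled in proportion to the amplicon copy numbers; merges the
#' implied breakpoint graphs (shared segments get the CN sum).
#'
#' @param truths list of `amplicon_truth` sharing one segment partition.
#' @param cns per-amplicon copy numbers.
#' @param reference the reference genome.
#' @param config a [sim_config].
#' @param params a [scoring_params].
#' @param molecules logical; also simulate pooled molecules.
#' @return list with `graph` (merged), `contigs`, `molecules`, `truths`.
#' @export
make_mixture <- function(truths, cns, reference, config,
                         params = scoring_params(), molecules = FALSE) {
  stopifnot(length(truths) == length(cns))
  contigs <- list()
  mols <- list()
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    tr$copy_number <- cns[i]
    contigs <- c(contigs, simulate_contigs(tr, reference, config, params,
                                           id_prefix = paste0("amp", i)))
    if (molecules) {
      cfg <- config
      cfg$coverage <- config$coverage * cns[i] / max(cns)
      mols <- c(mols, simulate_molecules(tr, reference, cfg, params,
                                         id_prefix = paste0("amp", i, "_mol")))
    }
  }
  names(contigs) <- vapply(contigs, function(m) m$map_id, "")
  # merged graph: same partition -> same segment table; CN = sum over
  # amplicons of multiplicity x amplicon CN; edges unioned
  segs <- truths[[1]]$graph$segments
  cn_tot <- setNames(rep(0, nrow(segs)), segs$segment_id)
  edges <- NULL
  for (i in seq_along(truths)) {
    g <- truths[[i]]$graph
    mult <- table(factor(truths[[i]]$elements$segment_id,
                         levels = segs$segment_id))
    cn_tot <- cn_tot + as.numeric(mult) * cns[i]
    edges <- rbind(edges, g$edges)
  }
  key <- with(edges, paste(pmin(vertex_key(from_id, from_side),
                                vertex_key(to_id, to_side)),
                           pmax(vertex_key(from_id, from_side),
                                vertex_key(to_id, to_side))))
  edges <- edges[!duplicated(key), , drop = FALSE]
  segs$copy_number <- as.numeric(cn_tot)
  list(graph = breakpoint_graph(segs, edges), contigs = contigs,
       molecules = mols, truths = truths)
}

#' Insert an unlabeled element into a truth path
#'
#' Emulates integration of a motif-free insert (e.g. a small viral genome):
#' an A/T-only random sequence of the given length is spliced in after a
#' random path element, so the digest of the modified structure shows an
#' inter-label gap grown by the insert length.
#'
#' @param truth an `amplicon_truth`.
#' @param insert_length_bp insert length (0 = identity).
#' @return the modified `amplicon_truth`.
#' @export
insert_unlabeled_element <- function(truth, insert_length_bp) {
  if (insert_length_bp <= 0) return(truth)
  at <- sample.int(max(nrow(truth$elements) - 1, 1), 1)
  truth$inserts <- rbind(truth$inserts,
                         data.frame(after_index = at,
                                    length_bp = insert_length_bp))
  truth
}
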