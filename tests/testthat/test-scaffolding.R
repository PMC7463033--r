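sp <- scoring_params("saphyr")

# build a synthetic alignment occupying contig label indices [from, to]
fake_aln <- function(seg_id, contig, from, to, orientation = "+",
                     seg_len = 5e4, seg_nlabels = to - from + 1,
                     score = 1e5) {
  n <- to - from + 1
  seg_idx <- if (orientation == "+") seq_len(n) else rev(seq_len(n))
  segment_alignment(seg_id, contig$map_id, orientation,
                    pairs = cbind(contig = from:to, segment = seg_idx),
                    score = score, step_scores = rep(2 * sp$c, n - 1),
                    seg_len = seg_len, contig_len = contig$length_bp,
                    seg_nlabels = seg_nlabels,
                    contig_nlabels = n_labels(contig),
                    contig_pos = contig$positions[from:to],
                    seg_pos = seq(1000, by = 4000, length.out = n))
}

test_that("scaffold edges follow the one-label-overlap rule", {
  contig <- label_map("c", 2e5, seq(2000, 198000, by = 4000))
  a1 <- fake_aln("1", contig, 1, 10)
  a2 <- fake_aln("2", contig, 12, 20)   # disjoint
  a3 <- fake_aln("3", contig, 10, 18)   # 1-label overlap with a1
  a4 <- fake_aln("4", contig, 8, 15)    # 3-label overlap with a1

  sc <- build_scaffold(list(a1, a2), contig)
  expect_equal(nrow(sc$edges), 1)
  expect_equal(sc$edges$kind, "allowed")
  expect_gt(sc$edges$gap_bp, 0)

  sc2 <- build_scaffold(list(a1, a3), contig)
  expect_equal(sc2$edges$kind, "allowed")

  sc3 <- build_scaffold(list(a1, a4), contig)
  expect_equal(sc3$edges$kind, "forbidden")
})

test_that("unaligned regions are reported within the label and bp bounds", {
  # contig with 700 labels every 4 kbp; alignments cover both ends so the
  # only unaligned run is the configured interior gap
  contig <- label_map("c", 2.9e6, seq(2000, by = 4000, length.out = 700))
  mk_scaffold <- function(covered_to, resume_at) {
    a1 <- fake_aln("1", contig, 1, covered_to)
    a2 <- fake_aln("2", contig, resume_at, 700)
    build_scaffold(list(a1, a2), contig)
  }
  # 10 unmatched labels: below the minimum of 20
  r <- detect_unaligned_regions(list(c = contig),
                                list(mk_scaffold(100, 111)))
  expect_equal(nrow(r), 0)
  # 100 unmatched labels over ~400 kbp: reported
  r <- detect_unaligned_regions(list(c = contig),
                                list(mk_scaffold(100, 201)))
  expect_equal(nrow(r), 1)
  expect_equal(r$n_labels, 100)
  expect_gt(r$length_bp, 2e5)
  # 600 unmatched labels: above the maximum of 500
  contig2 <- label_map("c", 4e6, seq(2000, by = 4000, length.out = 900))
  a1 <- fake_aln("1", contig2, 1, 100)
  a2 <- fake_aln("2", contig2, 701, 900)
  sc <- build_scaffold(list(a1, a2), contig2)
  r <- detect_unaligned_regions(list(c = contig2), list(sc))
  expect_equal(nrow(r), 0)
})

# toy breakpoint graph used for gap-path enumeration:
# segments 1..6, edges forming 1r->2l, 2r->3l, 3r->4l, 2r->5l, 5r->3l,
# and a self-cycle on 4 via 4r->4l
toy_graph <- function(cn = c(10, 10, 10, 3, 10, 10)) {
  segs <- data.frame(segment_id = as.character(1:6), chrom = "chr1",
                     start = c(1, 20001, 50001, 80001, 120001, 200001),
                     end = c(20000, 50000, 80000, 120000, 200000, 260000),
                     copy_number = cn)
  edges <- data.frame(
    from_id = c("1", "2", "3", "2", "5", "4"),
    from_side = rep("right", 6),
    to_id = c("2", "3", "4", "5", "3", "4"),
    to_side = rep("left", 6),
    type = "discordant", multiplicity = 1)
  breakpoint_graph(segs, edges)
}

test_that("gap-path enumeration respects graph structure and constraints", {
  g <- toy_graph()
  # unique interior path 1 -> [2,3] -> 4 for a gap of ~60 kbp
  cands <- enumerate_gap_paths(g, list(id = "1", side = "right"),
                               list(id = "4", side = "left"),
                               expected_gap_bp = 60000)
  keys <- vapply(cands, function(p)
    paste0(p$elements$segment_id, p$elements$orientation, collapse = ","), "")
  expect_true("2+,3+" %in% keys)
  # the alternative 2,5,3 (110 kbp + slack) is too long for this gap
  expect_false("2+,5+,3+" %in% keys)
  # with a matching expected gap (2:30k + 5:80k + 3:30k = 140 kbp) it appears
  cands2 <- enumerate_gap_paths(g, list(id = "1", side = "right"),
                                list(id = "4", side = "left"),
                                expected_gap_bp = 150000)
  keys2 <- vapply(cands2, function(p)
    paste0(p$elements$segment_id, p$elements$orientation, collapse = ","), "")
  expect_true("2+,5+,3+" %in% keys2)

  # no connecting edges -> empty
  expect_length(enumerate_gap_paths(g, list(id = "6", side = "right"),
                                    list(id = "1", side = "left"), 5e4), 0)

  # cycle multiplicity bounded by copy number (segment 4, CN 3)
  cands3 <- enumerate_gap_paths(g, list(id = "3", side = "right"),
                                list(id = "4", side = "left"),
                                expected_gap_bp = 3 * 40000)
  mults <- vapply(cands3, function(p) sum(p$elements$segment_id == "4"), 0)
  expect_true(all(mults <= 3))
  expect_true(any(mults > 1))
})

test_that("candidate scoring picks the true gap path on noiseless data", {
  set.seed(33)
  ref <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), 6e5, replace = TRUE), collapse = ""))
  names(ref) <- "chr1"
  # anchors 1 (150 kbp) and 4 (150 kbp) flank interior segments 2+,3+
  # (30 kbp each); a decoy segment 5 of mismatched length also connects
  segs <- data.frame(segment_id = as.character(1:5), chrom = "chr1",
                     start = c(1, 150001, 180001, 210001, 400001),
                     end = c(150000, 180000, 210000, 360000, 520000),
                     copy_number = 20)
  edges <- data.frame(
    from_id = c("1", "2", "3", "1", "5"), from_side = "right",
    to_id = c("2", "3", "4", "5", "4"), to_side = "left",
    type = "discordant", multiplicity = 1)
  g <- breakpoint_graph(segs, edges)
  segmaps <- digest_graph_segments(g, ref, sp$motif)
  whole <- digest_sequence(Biostrings::subseq(ref[["chr1"]], 1, 360000),
                           sp$motif, map_id = "c")
  alns <- list()
  for (sid in c("1", "4")) {
    a <- align_segment(segmaps[[sid]], whole, "semiglobal", sp)
    expect_false(is.null(a))
    alns[[sid]] <- a
  }
  cands <- enumerate_gap_paths(g, list(id = "1", side = "right"),
                               list(id = "4", side = "left"), 60000)
  res <- score_gap_candidates(cands, whole, alns[["1"]], alns[["4"]],
                              segmaps, sp)
  expect_false(is.null(res))
  expect_equal(paste0(res$path$elements$segment_id,
                      res$path$elements$orientation, collapse = ","), "2+,3+")
  expect_gt(res$score, res$unimputed_score)

  # a grossly mismatched single candidate (120 kbp where ~60 kbp fit) is
  # rejected as no improvement
  bad <- list(list(elements = data.frame(segment_id = "5",
                                         orientation = "+"),
                   bp_length = 120000, L_p = 1))
  expect_null(score_gap_candidates(bad, whole, alns[["1"]], alns[["4"]],
                                   segmaps, sp))
})

test_that("full scaffold imputation recovers a small unalignable segment", {
  set.seed(34)
  ref <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), 6e5, replace = TRUE), collapse = ""))
  names(ref) <- "chr1"
  # A (150 kbp) - b (18 kbp, too few labels) - C (150 kbp)
  segs <- data.frame(segment_id = c("1", "2", "3"), chrom = "chr1",
                     start = c(1, 150001, 168001),
                     end = c(150000, 168000, 318000), copy_number = 20)
  edges <- data.frame(from_id = c("1", "2"), from_side = "right",
                      to_id = c("2", "3"), to_side = "left",
                      type = "concordant", multiplicity = 1)
  g <- breakpoint_graph(segs, edges)
  segmaps <- digest_graph_segments(g, ref, sp$motif)
  expect_lt(n_labels(segmaps[["2"]]), sp$min_labels)
  contig <- digest_sequence(Biostrings::subseq(ref[["chr1"]], 1, 318000),
                            sp$motif, map_id = "c1")
  recon <- reconstruct_amplicon(g, list(contig), ref, params = sp)
  expect_length(recon$paths, 1)
  expect_equal(paste0(recon$paths[[1]]$elements$segment_id,
                      recon$paths[[1]]$elements$orientation, collapse = ","),
               "1+,2+,3+")
})
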