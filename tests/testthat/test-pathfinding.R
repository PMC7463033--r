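mk_path <- function(tokens, score = 100, contig = "c1") {
  list(elements = data.frame(
    segment_id = sub("[+-]$", "", tokens),
    orientation = sub("^.*([+-])$", "\\1", tokens),
    stringsAsFactors = FALSE), score = score, contig_id = contig)
}

test_that("heaviest scaffold path maximises summed segment length", {
  contig <- label_map("c", 1e6, seq(2000, 998000, by = 4000))
  sp_ <- scoring_params("saphyr")
  mk <- function(id, from, to, seg_len) {
    n <- to - from + 1
    segment_alignment(id, "c", "+",
                      pairs = cbind(contig = from:to, segment = 1:n),
                      score = 1e5, step_scores = rep(2 * sp_$c, n - 1),
                      seg_len = seg_len, contig_len = 1e6,
                      seg_nlabels = n, contig_nlabels = 249,
                      contig_pos = contig$positions[from:to],
                      seg_pos = seq(1000, by = 4000, length.out = n))
  }
  # single node
  sc1 <- build_scaffold(list(mk("1", 1, 10, 3e5)), contig)
  p1 <- heaviest_scaffold_paths(sc1)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$elements$segment_id, "1")

  # two parallel overlapping branches: 300 kbp vs 500 kbp
  sc2 <- build_scaffold(list(mk("1", 1, 20, 1e5),
                             mk("2", 25, 60, 3e5),
                             mk("3", 30, 70, 5e5)), contig)
  p2 <- heaviest_scaffold_paths(sc2)
  expect_equal(p2[[1]]$elements$segment_id, c("1", "3"))
  expect_equal(p2[[1]]$weight_bp, 6e5)
})

test_that("heaviest path DP equals brute-force enumeration on random DAGs", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    w <- sample(1:100, n, replace = TRUE) * 1000
    edges <- NULL
    for (u in 1:(n - 1)) for (v in (u + 1):n) {
      if (runif(1) < 0.4)
        edges <- rbind(edges, data.frame(from = u, to = v))
    }
    if (is.null(edges)) edges <- data.frame(from = integer(0),
                                            to = integer(0))
    # direct DP mirror of heaviest_scaffold_paths on this abstract DAG
    best <- w
    for (v in seq_len(n)) {
      inc <- edges$from[edges$to == v]
      if (length(inc)) best[v] <- max(best[v], max(best[inc]) + w[v])
    }
    expect_equal(max(best), oracle_heaviest(n, edges, w)$weight)
  }
})

test_that("copy-number ratio check matches hand evaluation and brute force", {
  g2 <- function(cns) breakpoint_graph(data.frame(
    segment_id = names(cns), chrom = "chr1",
    start = seq(1, by = 1e5, length.out = length(cns)),
    end = seq(1e5, by = 1e5, length.out = length(cns)),
    copy_number = as.numeric(cns)))
  els <- function(ids) data.frame(segment_id = ids, orientation = "+")

  # all multiplicities 1: nothing to check
  expect_true(cn_ratio_check(els(c("A", "B")), g2(c(A = 5, B = 9))))
  # {A:2, B:1}, CN {40, 20}: 2 <= max(1, 40/20) + 1 = 3
  expect_true(cn_ratio_check(els(c("A", "A", "B")), g2(c(A = 40, B = 20))))
  # {A:4, B:1}, CN {20, 20}: 4 > max(1, 20/20) + 1 = 2
  expect_false(cn_ratio_check(els(c("A", "A", "A", "A", "B")),
                              g2(c(A = 20, B = 20))))
  # the published lung-cancer amplicon layout: multiplicities 4,2,2,1 with
  # copy numbers 46,25,25,12 are ratio-consistent and must pass
  expect_true(cn_ratio_check(
    els(c(rep("A", 4), rep("B", 2), rep("C", 2), "D")),
    g2(c(A = 46, B = 25, C = 25, D = 12))))

  set.seed(43)
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    ids <- LETTERS[1:k]
    mult <- sample(1:4, k, replace = TRUE)
    cns <- setNames(sample(c(5, 10, 20, 40), k, replace = TRUE), ids)
    path_ids <- rep(ids, mult)
    got <- cn_ratio_check(els(path_ids), g2(cns))
    want <- oracle_cn_check(as.list(setNames(mult, ids)), as.list(cns))
    expect_equal(got, want, info = paste(mult, collapse = ","))
  }
  expect_error(cn_ratio_check(els("Z"), g2(c(A = 5))), "missing")
})

test_that("subsequence-path filtering is rotation-aware and matches brute force", {
  p1 <- mk_path(c("1+", "2+", "3+"), score = 30)
  p2 <- mk_path(c("2+", "3+"), score = 20)
  kept <- filter_subsequence_paths(list(p1, p2))
  expect_length(kept, 1)
  expect_equal(path_tokens(kept[[1]]$elements), c("1+", "2+", "3+"))

  # a rotation of a kept path is discarded
  p3 <- mk_path(c("3+", "1+", "2+"), score = 10)
  kept2 <- filter_subsequence_paths(list(p1, p3))
  expect_length(kept2, 1)

  # orientation-reversed form is also discarded
  p4 <- mk_path(c("3-", "2-", "1-"), score = 5)
  expect_length(filter_subsequence_paths(list(p1, p4)), 1)

  set.seed(44)
  for (rep in 1:25) {
    paths <- lapply(1:sample(3:6, 1), function(i) {
      n <- sample(1:5, 1)
      mk_path(paste0(sample(1:4, n, replace = TRUE),
                     sample(c("+", "-"), n, replace = TRUE)),
              score = 100 - i)
    })
    kept <- filter_subsequence_paths(paths)
    keep_idx <- oracle_filter_paths(lapply(paths, function(p)
      path_tokens(p$elements)))
    expect_equal(lapply(kept, function(p) path_tokens(p$elements)),
                 lapply(paths[keep_idx], function(p)
                   path_tokens(p$elements)))
  }
})

test_that("cyclic classification folds repeated ends per the length rule", {
  g <- breakpoint_graph(data.frame(
    segment_id = c("1", "2", "3"), chrom = "chr1",
    start = c(1, 1e5 + 1, 2e5 + 1), end = c(1e5, 2e5, 3e5),
    copy_number = 10))
  out <- classify_and_emit(list(mk_path(c("1+", "2+", "3+", "1+"))), g)
  expect_true(out[[1]]$cyclic)
  expect_equal(path_tokens(out[[1]]$elements), c("1+", "2+", "3+"))

  out2 <- classify_and_emit(list(mk_path(c("1+", "1+"))), g)
  expect_false(out2[[1]]$cyclic)
  expect_equal(nrow(out2[[1]]$elements), 2)

  out3 <- classify_and_emit(list(mk_path("1+")), g)
  expect_false(out3[[1]]$cyclic)
})

test_that("scaffold linking needs a clipped shared endpoint segment", {
  base <- mk_path(c("5+", "6+", "7+"))
  nxt <- mk_path(c("7+", "8+", "9+"), contig = "c2")
  base$weight_bp <- nxt$weight_bp <- 3e5
  # both terminal alignments complete: no link evidence
  base$clip_start <- 0; base$clip_end <- 0
  nxt$clip_start <- 0; nxt$clip_end <- 0
  lg <- link_scaffolds(list(base, nxt))
  expect_equal(nrow(lg$links), 0)
  # the shared segment is truncated by the end of contig 1: link
  base$clip_end <- 5
  lg2 <- link_scaffolds(list(base, nxt))
  expect_true(any(vapply(seq_len(nrow(lg2$links)), function(i) {
    f <- lg2$nodes[[lg2$links$from[i]]]
    t <- lg2$nodes[[lg2$links$to[i]]]
    f$dir == "+" && t$dir == "+" && lg2$links$overlap[i] == 1
  }, logical(1))))
  cands <- linked_graph_paths(lg2)
  toks <- lapply(cands, function(p) path_tokens(p$elements))
  expect_true(list(c("5+", "6+", "7+", "8+", "9+")) %in% toks)

  # reverse-assembled second contig still links (orientation flip)
  rev_nxt <- mk_path(c("9-", "8-", "7-"), contig = "c2")
  rev_nxt$clip_start <- 0; rev_nxt$clip_end <- 5
  lg3 <- link_scaffolds(list(base, rev_nxt))
  cands3 <- linked_graph_paths(lg3)
  toks3 <- lapply(cands3, function(p) path_tokens(p$elements))
  expect_true(list(c("5+", "6+", "7+", "8+", "9+")) %in% toks3)

  # no shared endpoint segment: no links regardless of clipping
  far <- mk_path(c("10+", "11+"), contig = "c3")
  far$clip_start <- 9; far$clip_end <- 9
  base2 <- base; base2$clip_end <- 9
  expect_equal(nrow(link_scaffolds(list(base2, far))$links), 0)
})

test_that("integration-point clustering applies the 25 kbp / 10-molecule rule", {
  mk_splits <- function(n, in_pos, out_pos, jitter = 8000) {
    data.frame(molecule_id = paste0("m", seq_len(n)),
               inside_chrom = "chr8", inside_pos = in_pos +
                 runif(n, -jitter, jitter),
               outside_chrom = "chr12", outside_pos = out_pos +
                 runif(n, -jitter, jitter))
  }
  set.seed(45)
  cl <- cluster_integration_points(mk_splits(12, 129410000, 7660000))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_molecules, 12)
  expect_lt(abs(cl$inside_pos - 129410000), 25000)

  # 9 molecules: below the support threshold
  expect_equal(nrow(cluster_integration_points(
    mk_splits(9, 129410000, 7660000))), 0)

  # two junction groups 60 kbp apart on the inside coordinate
  two <- rbind(mk_splits(11, 100000, 500000, jitter = 3000),
               mk_splits(13, 160000, 500000, jitter = 3000))
  cl2 <- cluster_integration_points(two)
  expect_equal(nrow(cl2), 2)
  expect_setequal(cl2$n_molecules, c(11, 13))
})
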