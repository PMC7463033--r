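sp <- scoring_params("saphyr")

test_that("merge probability is a capped decreasing power law", {
  p <- scoring_params("saphyr", w = 2000, t = 2)
  expect_equal(merge_probability(0, p), 1)
  expect_equal(merge_probability(2000, p), 0)
  expect_equal(merge_probability(5000, p), 0)
  expect_equal(merge_probability(1000, p), 0.75)  # 1 - (1/2)^2
  d <- seq(0, 3000, by = 50)
  expect_true(all(diff(merge_probability(d, p)) <= 0))
  expect_error(merge_probability(-1, p), "negative")
  p2 <- scoring_params("saphyr", w = 2000, t = 2, merge_as_printed = TRUE)
  expect_equal(merge_probability(1000, p2), 0.25)
})

test_that("collapse map matches the naive double-loop sum", {
  p <- scoring_params("saphyr", w = 1500, t = 2, eta = 1500)
  # adjacent labels: empty interior sum
  m1 <- build_collapse_map(label_map("s", 1e4, c(1000, 5000)), p)
  expect_equal(collapse_expected(m1, 1, 2), 0)
  # three labels, all gaps >= w, span >= eta -> fully observable interior
  m2 <- build_collapse_map(label_map("s", 1e4, c(1000, 4000, 8000)), p)
  expect_equal(collapse_expected(m2, 1, 3), 1)

  set.seed(21)
  pm <- function(g) 1 - min(1, (g / p$w)^p$t)
  for (rep in 1:20) {
    x <- sort(sample.int(5e4, sample(3:12, 1)))
    lm <- label_map("s", 5e4, x)
    M <- build_collapse_map(lm, p)
    n <- length(x)
    for (pp in 1:(n - 1)) for (qq in (pp + 1):n) {
      naive <- 0
      if (x[qq] - x[pp] >= p$eta && qq - pp >= 2) {
        for (k in (pp + 1):(qq - 1)) {
          pl <- pm(x[k] - x[k - 1])
          pr <- pm(x[k + 1] - x[k])
          naive <- naive + (1 - pl) * (1 - pr)
        }
      }
      expect_equal(collapse_expected(M, pp, qq), naive, tolerance = 1e-12)
    }
  }
})

test_that("matching-region scores follow the penalty decomposition", {
  p <- scoring_params("saphyr", w = 1500, eta = 1500)
  b <- c(1000, 5000, 9000, 15000)
  x <- c(500, 4500, 8500, 14500)
  M <- build_collapse_map(label_map("s", 2e4, x), p)
  # perfect step: equal gaps, no skips
  s1 <- score_matching_region(b, x, 1, 2, 1, 2, M, p)
  expect_equal(s1$total, 2 * p$c)
  # one skipped contig label, equal flanking gap lengths
  b2 <- c(1000, 3000, 5000)
  x2 <- c(500, 4500)
  M2 <- build_collapse_map(label_map("s", 2e4, x2), p)
  s2 <- score_matching_region(b2, x2, 1, 3, 1, 2, M2, p)
  expect_equal(s2$total, p$c)  # 2c - c
  # arbitrary indices vs independent evaluation
  s3 <- score_matching_region(b, x, 1, 4, 1, 4, M, p)
  e_ref <- collapse_expected(M, 1, 4)
  expect_equal(s3$total,
               2 * p$c - (p$c * 2 + p$c * e_ref +
                            abs((b[4] - b[1]) - (x[4] - x[1]))^p$k))
  expect_error(score_matching_region(b, x, 2, 1, 1, 2, M, p), "i < j")
})

test_that("self-alignment of a noiseless digest is perfect", {
  set.seed(3)
  x <- sort(sample.int(2e5, 25))
  seg <- label_map("s", 2e5, x)
  ctg <- label_map("c", 2e5, x)
  a <- align_segment(seg, ctg, "semiglobal", sp)
  expect_equal(a$score, 2 * sp$c * (length(x) - 1))
  expect_equal(a$pairs[, "contig"], a$pairs[, "segment"], ignore_attr = TRUE)
  expect_equal(a$orientation, "+")
  expect_true(all(abs(a$step_scores - 2 * sp$c) < 1e-9))
})

test_that("banded DP equals the exhaustive unbanded oracle on small instances", {
  set.seed(31)
  p <- scoring_params("saphyr", d = 12, min_labels = 4)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    m <- sample(6:12, 1)
    x <- sort(sample.int(8e4, n))
    b <- sort(sample.int(1e5, m))
    seg <- label_map("s", 8e4 + 10, x)
    ctg <- label_map("c", 1e5 + 10, b)
    a <- align_segment(seg, ctg, "semiglobal", p)
    # oracle over both orientations
    o_fwd <- oracle_align(b, x, p)
    xr <- rev(seg$length_bp - x)
    o_rev <- oracle_align(b, xr, p)
    o_best <- max(o_fwd$score, o_rev$score)
    if (is.null(a)) {
      expect_lte(o_best, 0)
    } else {
      expect_equal(a$score, o_best, tolerance = 1e-9)
    }
  }
})

test_that("a deleted interior label is skipped and scored like the oracle", {
  set.seed(4)
  x <- sort(sample.int(1.5e5, 12))
  seg <- label_map("s", 1.5e5, x)
  ctg <- label_map("c", 1.5e5, x[-6])
  p <- scoring_params("saphyr", d = 12, min_labels = 4)
  a <- align_segment(seg, ctg, "semiglobal", p)
  expect_false(6 %in% a$pairs[, "segment"])
  o <- oracle_align(x[-6], x, p)
  expect_equal(a$score, o$score, tolerance = 1e-9)
})

test_that("alignment score is invariant to global shift and joint reversal", {
  set.seed(6)
  x <- sort(sample.int(1e5, 15))
  b <- sort(c(x + 20, sample.int(1e5, 3)))  # noisy containing copy
  seg <- label_map("s", 1e5 + 50, x)
  ctg <- label_map("c", 1.1e5, b)
  a0 <- align_segment(seg, ctg, "semiglobal", sp)
  shift <- 5000
  a1 <- align_segment(label_map("s", 1e5 + 50 + shift, x + shift),
                      label_map("c", 1.1e5 + shift, b + shift),
                      "semiglobal", sp)
  expect_equal(a1$score, a0$score, tolerance = 1e-9)
  rev_map <- function(m) reverse_label_map(m)
  a2 <- align_segment(rev_map(seg), rev_map(ctg), "semiglobal", sp)
  expect_equal(a2$score, a0$score, tolerance = 1e-9)
})

test_that("used-pair masking yields a different second-best alignment", {
  set.seed(8)
  x <- sort(sample.int(8e4, 14))
  seg <- label_map("s", 8e4 + 10, x)
  ctg <- label_map("c", 8e4 + 10, x)
  a1 <- align_segment(seg, ctg, "semiglobal", sp)
  a2 <- align_segment(seg, ctg, "semiglobal", sp, used = unname(a1$pairs))
  if (!is.null(a2)) {
    k1 <- paste(a1$pairs[, 1], a1$pairs[, 2])
    k2 <- paste(a2$pairs[, 1], a2$pairs[, 2])
    expect_length(intersect(k1, k2), 0)
    expect_lte(a2$score, a1$score)
  } else succeed("no positive second-best alignment exists")
})

test_that("iterative alignment finds duplications and respects the cap", {
  set.seed(12)
  # a 14-label pattern with resolvable spacing (>= collapse scale)
  x <- 1000 + cumsum(c(0, 1500 + sample.int(6000, 13)))
  L <- max(x) + 1000
  seg <- label_map("s", L, x)
  two <- label_map("c", 3 * L, c(x, x + L + 1e4))
  hits <- iterative_align(seg, two, "semiglobal", sp)
  expect_length(hits, 2)
  loci <- sort(vapply(hits, function(a) min(a$contig_pos), 0))
  expect_gt(loci[2] - loci[1], L)

  # zero copies: an unrelated contig
  other <- random_map("c2", 40, 2e5)
  expect_length(iterative_align(seg, other, "semiglobal", sp), 0)

  # 15 tandem copies but the per-pair cap is 12
  tandem <- label_map("c3", 15 * L,
                      as.numeric(outer(x, (0:14) * L, `+`)))
  hits15 <- iterative_align(seg, tandem, "semiglobal", sp)
  expect_length(hits15, 12)
})

test_that("E-value calibration recovers exact log-linear score data", {
  K <- 0.02; m <- 5e4; n_r <- 30; lambda <- 0.004
  h <- 30
  hsp <- (log(K * m * n_r) - log(seq_len(h))) / lambda
  decoys <- max(hsp) + seq_len(25) * 5
  filler <- seq(min(hsp) - 5000, min(hsp) - 10, length.out = 170)
  mod <- calibrate_evalue(c(decoys, hsp, filler), m, n_r)
  expect_false(mod$degenerate)
  expect_equal(mod$lambda, lambda, tolerance = 1e-6)
  expect_equal(mod$K, K, tolerance = 1e-6)

  expect_true(calibrate_evalue(rep(100, 200), m, n_r)$degenerate)
  expect_true(calibrate_evalue(rnorm(20), m, n_r)$degenerate)
})

test_that("score cutoffs invert the E-value model", {
  mod <- structure(list(K = 0.02, lambda = 0.004, m = 5e4, n_r = 30,
                        degenerate = FALSE), class = "evalue_model")
  s1 <- score_cutoff(mod, 1e-4)
  s2 <- score_cutoff(mod, 1e-6)
  expect_gt(s2, s1)
  # round trip: P(E(S*)) == p
  for (p in c(1e-2, 1e-4, 1e-9)) {
    s <- score_cutoff(mod, p)
    E <- mod$K * mod$m * mod$n_r * exp(-mod$lambda * s)
    expect_equal(1 - exp(-E), p, tolerance = 1e-9)
  }
  unit <- structure(list(K = 1, lambda = 1, m = 1, n_r = 1,
                         degenerate = FALSE), class = "evalue_model")
  expect_equal(score_cutoff(unit, 1 - exp(-1)), 0, tolerance = 1e-12)
  expect_error(score_cutoff(mod, 0), "p must be")
  expect_error(score_cutoff(mod, 1), "p must be")
})

test_that("step-score filtering matches a direct mean/median oracle", {
  p <- scoring_params("saphyr", mean_step_min = 1000, median_step_min = 1200)
  mk <- function(steps) {
    n <- length(steps) + 1
    segment_alignment("s", "c", "+",
                      pairs = cbind(contig = 1:n, segment = 1:n),
                      score = sum(steps), step_scores = steps)
  }
  set.seed(14)
  alns <- lapply(1:30, function(i) mk(rnorm(8, 1500, 600)))
  kept <- filter_alignments(alns, p)
  manual <- Filter(function(a) mean(a$step_scores) >= 1000 &&
                     median(a$step_scores) >= 1200, alns)
  expect_equal(vapply(kept, function(a) a$score, 0),
               vapply(manual, function(a) a$score, 0))
  # perfect alignment always survives thresholds <= 2c
  perfect <- mk(rep(2 * p$c, 9))
  expect_length(filter_alignments(list(perfect), p), 1)
  bad <- mk(c(rep(2000, 3), rep(100, 5)))  # median below threshold
  expect_length(filter_alignments(list(bad), p), 0)
})
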