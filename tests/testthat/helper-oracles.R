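# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Exhaustive, unbanded alignment DP in plain R. Modes: semiglobal (start
# anywhere / end at matrix argmax) and fitting (first and last labels of
# both maps paired). Returns list(score, pairs) with 1-based (contig,
# segment) indices, or NULL.
oracle_align <- function(b, x, params, fitting = FALSE, banned = NULL) {
  m <- length(b); n <- length(x)
  if (m < 1 || n < 1) return(NULL)
  gaps <- diff(x)
  pm <- function(g) 1 - min(1, (g / params$w)^params$t)
  obs <- numeric(n)
  for (k in seq_len(n)) {
    pl <- if (k == 1) 0 else pm(gaps[k - 1])
    pr <- if (k == n) 0 else pm(gaps[k])
    obs[k] <- (1 - pl) * (1 - pr)
  }
  Mfun <- function(p, q) {
    if (x[q] - x[p] < params$eta) return(0)
    if (q - p < 2) return(0)
    sum(obs[(p + 1):(q - 1)])
  }
  S <- matrix(-Inf, m, n)
  Pi <- matrix(0L, m, n); Pp <- matrix(0L, m, n)
  is_banned <- function(j, q) !is.null(banned) &&
    any(banned[, 1] == j & banned[, 2] == q)
  for (j in 1:m) for (q in 1:n) {
    if (is_banned(j, q)) next
    best <- if (fitting) { if (j == 1 && q == 1) 0 else -Inf } else 0
    bi <- 0L; bp <- 0L
    if (j > 1 && q > 1) {
      for (i in 1:(j - 1)) for (p in 1:(q - 1)) {
        if (!is.finite(S[i, p])) next
        sc <- S[i, p] + 2 * params$c -
          (params$c * (j - i - 1) + params$c * Mfun(p, q) +
             abs((b[j] - b[i]) - (x[q] - x[p]))^params$k)
        if (sc > best) { best <- sc; bi <- i; bp <- p }
      }
    }
    S[j, q] <- best
    Pi[j, q] <- bi; Pp[j, q] <- bp
  }
  if (fitting) {
    ej <- m; eq <- n
    if (!is.finite(S[m, n])) return(NULL)
  } else {
    idx <- which(S == max(S), arr.ind = TRUE)[1, ]
    ej <- idx[1]; eq <- idx[2]
  }
  pairs <- NULL
  j <- ej; q <- eq
  while (j > 0 && q > 0) {
    pairs <- rbind(c(j, q), pairs)
    nj <- Pi[j, q]; nq <- Pp[j, q]
    j <- nj; q <- nq
  }
  list(score = S[ej, eq], pairs = pairs)
}

# Naive longest-common-substring over token vectors: enumerate every
# substring of a (with rotations when cyclic) and test containment in b
# (with rotations / reversal).
oracle_lcs_len <- function(ta, tb, cyclic_a = FALSE, cyclic_b = FALSE,
                           allow_reverse = TRUE) {
  rots <- function(v, cyc) {
    if (!cyc || length(v) <= 1) return(list(v))
    lapply(seq_along(v), function(s) v[((seq_along(v) + s - 2) %% length(v)) + 1])
  }
  rev_tok <- function(v) {
    flip <- ifelse(grepl("\\+$", v), sub("\\+$", "-", v), sub("-$", "+", v))
    rev(flip)
  }
  bs <- rots(tb, cyclic_b)
  if (allow_reverse) bs <- c(bs, rots(rev_tok(tb), cyclic_b))
  contains <- function(small, big) {
    ns <- length(small); nb <- length(big)
    if (ns > nb) return(FALSE)
    for (s in 0:(nb - ns)) if (all(big[s + seq_len(ns)] == small)) return(TRUE)
    FALSE
  }
  best <- 0
  for (av in rots(ta, cyclic_a)) {
    na <- length(av)
    for (len in seq(min(na, max(lengths(bs))), 1)) {
      if (len <= best) break
      found <- FALSE
      for (s in 0:(na - len)) {
        sub <- av[s + seq_len(len)]
        if (any(vapply(bs, function(bv) contains(sub, bv), logical(1)))) {
          found <- TRUE; break
        }
      }
      if (found) { best <- len; break }
    }
  }
  best
}

# Brute-force copy-number ratio check straight from the definition.
oracle_cn_check <- function(mult, cns) {
  for (seg in names(mult)) {
    np <- mult[[seg]]
    for (c_lvl in seq_len(max(np - 1, 0))) {
      at <- names(mult)[unlist(mult) == c_lvl]
      if (!length(at)) next
      m_g <- max(unlist(cns[at]))
      if (np > max(c_lvl, c_lvl * cns[[seg]] / m_g) + 1) return(FALSE)
    }
  }
  TRUE
}

# Brute-force greedy subsequence-path filter over all rotations of each
# candidate and its reversal.
oracle_filter_paths <- function(token_lists) {
  rev_tok <- function(v) {
    flip <- ifelse(grepl("\\+$", v), sub("\\+$", "-", v), sub("-$", "+", v))
    rev(flip)
  }
  rots <- function(v) lapply(seq_along(v), function(s)
    v[((seq_along(v) + s - 2) %% length(v)) + 1])
  contains <- function(small, big) {
    ns <- length(small); nb <- length(big)
    if (ns > nb) return(FALSE)
    for (s in 0:(nb - ns)) if (all(big[s + seq_len(ns)] == small)) return(TRUE)
    FALSE
  }
  kept <- list()
  keep_idx <- integer(0)
  for (i in seq_along(token_lists)) {
    tok <- token_lists[[i]]
    forms <- c(rots(tok), rots(rev_tok(tok)))
    sub <- any(vapply(kept, function(kt)
      any(vapply(forms, contains, logical(1), big = kt)), logical(1)))
    if (!sub) {
      kept[[length(kept) + 1L]] <- tok
      keep_idx <- c(keep_idx, i)
    }
  }
  keep_idx
}

# Brute-force maximum-weight path over the allowed edges of a DAG given as
# an edge data.frame and node weights (enumerates all simple paths).
oracle_heaviest <- function(n_nodes, edges, w) {
  best <- -Inf; best_path <- NULL
  extend <- function(path) {
    v <- path[length(path)]
    wt <- sum(w[path])
    if (wt > best) { best <<- wt; best_path <<- path }
    nxt <- edges$to[edges$from == v]
    for (u in nxt) extend(c(path, u))
  }
  for (s in seq_len(n_nodes)) extend(s)
  list(weight = best, path = best_path)
}

# Two-strand naive motif scan for digestion.
oracle_digest <- function(seq_chr, motif) {
  comp <- chartr("ACGT", "TGCA", motif)
  rc <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  hits <- integer(0)
  L <- nchar(seq_chr); ml <- nchar(motif)
  for (s in 1:(L - ml + 1)) {
    sub <- substr(seq_chr, s, s + ml - 1)
    if (sub == motif || sub == rc) hits <- c(hits, s)
  }
  sort(unique(hits))
}

# Small random label map for property tests.
random_map <- function(id, n, len = 1e5) {
  label_map(id, len, sort(sample.int(len - 1, n)))
}
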