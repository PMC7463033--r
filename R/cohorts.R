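#' Simulate and reconstruct a cohort of amplicons
#'
#' Reproduces the package's simulation studies end to end: each case draws
#' an amplicon structure, simulates noisy spanning consensus contigs,
#' reconstructs from the (optionally corrupted) breakpoint graph, and scores
#' the result against the ground truth with the LCS precision/recall
#' metrics.
#'
#' Study types:
#' \describe{
#'   \item{cn20}{mixed cyclic/linear amplicons, 3-20 segments,
#'     0.3-2.8 Mbp, copy number 20.}
#'   \item{false_edges}{the cn20 conditions with extra false discordant
#'     edges added to the graph (+100\% of the true edge count).}
#'   \item{mixture}{three related structures per sample sharing one segment
#'     partition, simulated at copy numbers 20-15-10 and reconstructed from
#'     the pooled contigs against the merged graph; every truth is scored.}
#'   \item{denovo}{circular ecDNA-like structures, ~2 Mbp, ~9 segments.}
#'   \item{duplication}{amplicons carrying a tandem duplication of a
#'     ~280 kbp block; also reports the fraction of duplications resolved
#'     at correct multiplicity.}
#' }
#'
#' @param type study type, see details.
#' @param n_cases number of simulated amplicons (samples, for `mixture`).
#' @param seed RNG seed; every stochastic step derives from it.
#' @param metric LCS comparison metric (default `"length_bp"`).
#' @param instrument `"saphyr"` or `"irys"`.
#' @param noise apply the OM noise model (set `FALSE` for noise-free runs).
#' @param impute impute scaffold gaps (default `TRUE`).
#' @param reference optional pre-built reference genome (generated from the
#'   seed when omitted).
#' @return list with `results` (per-amplicon data.frame: `case`,
#'   `precision`, `recall`, `f1`, and for duplication studies `resolved`),
#'   `mean_f1`, and for duplication studies `resolved_fraction`.
#' @export
run_study <- function(type = c("cn20", "false_edges", "mixture", "denovo",
                               "duplication"),
                      n_cases = 20, seed = 1, metric = "length_bp",
                      instrument = "saphyr", noise = TRUE, impute = TRUE,
                      reference = NULL) {
  type <- match.arg(type)
  set.seed(seed)
  params <- scoring_params(instrument)
  if (is.null(reference)) reference <- random_reference()

  base_config <- function() {
    cfg <- switch(type,
      cn20 = ,
      false_edges = {
        n_seg <- sample(3:20, 1)
        cyc <- runif(1) < 0.45
        need <- if (cyc) 120e3 + (n_seg - 1) * 15e3
                else 2 * 120e3 + max(n_seg - 2, 0) * 15e3
        sim_config(n_segments = n_seg,
                   total_bp = runif(1, max(3e5, need + 5e4), 2.8e6),
                   cyclic = cyc, copy_number = 20)
      },
      denovo = sim_config(n_segments = max(3, rpois(1, 9)),
                          total_bp = min(3e6, max(1.2e6,
                                                  rlnorm(1, log(2e6), 0.25))),
                          cyclic = TRUE, copy_number = 20),
      duplication = sim_config(n_segments = sample(5:12, 1),
                               total_bp = runif(1, 1.2e6, 2.5e6),
                               cyclic = runif(1) < 0.45, copy_number = 20,
                               ensure_duplication = TRUE),
      mixture = sim_config(n_segments = sample(6:14, 1),
                           total_bp = runif(1, 1.2e6, 2.5e6),
                           cyclic = runif(1) < 0.45, copy_number = 20))
    if (!noise) {
      cfg$label_miss_rate <- 0
      cfg$sizing_sd <- 0
      cfg$collapse <- FALSE
    }
    cfg
  }

  rows <- list()
  resolved <- logical(0)
  for (case in seq_len(n_cases)) {
    cfg <- base_config()
    if (type == "mixture") {
      # three related structures of one sample: like the published
      # heterogeneity simulations, every member must be consistent with
      # the sample graph's (pooled) copy numbers, so truth triples are
      # rejection-sampled until each passes the ratio check
      cns <- c(20, 15, 10)
      truths <- NULL
      for (attempt in 1:100) {
        t1 <- simulate_amplicon_structure(cfg, reference)
        cand <- list(t1)
        for (k in 2:3) {
          cfgk <- base_config()
          cfgk$cyclic <- runif(1) < 0.45
          cand[[k]] <- simulate_amplicon_structure(cfgk, reference,
                                                   partition = t1$partition)
        }
        segs <- t1$graph$segments
        pooled <- Reduce(`+`, lapply(seq_along(cand), function(k)
          cns[k] * as.numeric(table(factor(cand[[k]]$elements$segment_id,
                                           levels = segs$segment_id)))))
        segs$copy_number <- pooled
        pooled_graph <- breakpoint_graph(segs)
        ok <- all(vapply(cand, function(tr)
          cn_ratio_check(tr$elements, pooled_graph), logical(1)))
        truths <- cand
        if (ok) break
      }
      mix <- make_mixture(truths, cns = cns, reference, cfg, params)
      recon <- reconstruct_amplicon(mix$graph, mix$contigs, reference,
                                    params = params, impute = impute)
      for (k in seq_along(truths)) {
        ev <- precision_recall(truths[[k]], recon$paths, metric,
                               graph = mix$graph)
        rows[[length(rows) + 1L]] <- data.frame(
          case = case, amplicon = k, precision = ev$precision,
          recall = ev$recall, f1 = ev$f1)
      }
    } else {
      truth <- simulate_amplicon_structure(cfg, reference)
      contigs <- simulate_contigs(truth, reference, cfg, params)
      graph <- truth$graph
      if (type == "false_edges") graph <- inject_false_edges(graph, 1.0)
      recon <- reconstruct_amplicon(graph, contigs, reference,
                                    params = params, impute = impute)
      ev <- precision_recall(truth, recon$paths, metric, graph = truth$graph)
      rows[[length(rows) + 1L]] <- data.frame(
        case = case, amplicon = 1L, precision = ev$precision,
        recall = ev$recall, f1 = ev$f1)
      if (type == "duplication")
        resolved <- c(resolved, duplication_resolved(truth, recon$paths))
    }
  }
  results <- do.call(rbind, rows)
  out <- list(results = results, mean_f1 = mean_f1(results))
  if (type == "duplication") {
    out$resolved <- resolved
    out$resolved_fraction <- mean(resolved)
  }
  out
}
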