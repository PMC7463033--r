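---
title: "Reconstructing focal amplifications from optical maps: models and methods"
author: "omamplicon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing focal amplifications from optical maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omamplicon)
```

## The problem

Focal copy-number amplifications (fCNAs) — extrachromosomal circular DNA
(ecDNA), breakage–fusion–bridge products, and other complex rearrangements —
amplify oncogenes to high copy number in many cancers. Short-read sequencing
can segment the amplified region and call breakpoints, yielding a
*breakpoint graph*: copy-number-annotated genomic segments joined by
concordant and discordant junction edges. But a graph admits many possible
walks; the *structure* of the amplicon (the order and orientation of its
segments) is often ambiguous from the graph alone, particularly when large
blocks are duplicated inside the amplicon.

Optical mapping (OM) provides orthogonal long-range evidence: fluorescent
labels at a sequence motif (DLE-1 `CTTAAG`, or Nt.BspQI `GCTCTTC`) imaged
along DNA fragments of hundreds of kilobases, assembled into consensus
contigs. A contig is an ordered list of label positions — no base-level
sequence, but enough long-range signal to place multi-hundred-kilobase
segments unambiguously.

`omamplicon` reconstructs amplicon structures by (1) digesting the
breakpoint-graph segments in silico, (2) aligning each digested segment to
each OM contig with a banded dynamic program, (3) building a per-contig
scaffold DAG of alignments, (4) imputing small unalignable segments across
scaffold gaps using the breakpoint graph, and (5) extracting
copy-number-consistent, non-redundant paths. A simulator and an LCS-based
scoring module close the loop so the whole pipeline is testable without
external data.

## Alignment scoring model

For contig labels $b$ and segment labels $x$, the DP score of extending an
alignment from pair $(i, p)$ to $(j, q)$ is

$$\mathrm{Score}(i,j,p,q) = 2c - \Big(c\,(j - i - 1) + c\,M(p,q) +
\big|\,(b_j - b_i) - (x_q - x_p)\,\big|^k\Big),$$

a base reward $2c$ minus penalties for skipped contig labels, for skipped
segment labels *expected to be observable*, and for the sizing discrepancy
of the matched intervals. The recursion is banded: predecessors are
restricted to the $d$ previous labels on each map ($d = 6$ by default), and
the best chain is read from the matrix argmax (semi-global) or the corner
cell (fitting). The reverse orientation is scored by reversing the
segment's gap sequence, never the contig. Emitted label pairings are
masked and the DP re-run to find additional (e.g. duplicated) placements,
up to 12 per segment–contig pair.

### Label collapse

Two labels closer than roughly the imaging resolution are read as one. We
model the probability that a label pair separated by $\Delta$ merges as
$P_\mathrm{merge}(\Delta) = 1 - \min(1, (\Delta/w)^t)$: certain at
$\Delta = 0$, impossible beyond $w$. A label's *observability* is the
probability it merges with neither neighbour, and $M(p,q)$ sums the
observabilities of labels interior to $(p, q)$ (zero when the span is
below $\eta$). Skipping a collapse-prone label is thereby almost free,
while skipping a well-separated label costs a full $c$.

The merge probability is implemented in the decreasing form above; the
increasing variant (`merge_as_printed = TRUE`) is available for
comparison, but contradicts the physics of the error mode (closer labels
merge *more* often) and is not used anywhere in the package.

### Parameter defaults

| parameter | meaning | default (Saphyr / Irys) |
|---|---|---|
| $c$ | missing-label score (score units) | 1500 |
| $k$ | sizing-difference exponent | 1.1 |
| $w$ | collapse length scale (bp) | 1500 / 2000 |
| $t$ | collapse shape exponent | 2 |
| $\eta$ | minimum span for the interior sum (bp) | $= w$ |
| $d$ | DP band width (labels) | 6 |
| min. labels | alignable-segment threshold | 12 / 10 |

$c$ sets the scale: with $k$ slightly above 1, a sizing discrepancy of
~600 bp costs about $c$, and ~1.3 kbp costs about $2c$ — so a chain step
must match interval lengths to within roughly one kilobase to be worth
more than skipping. These defaults follow from the scoring model's
structure at the label densities the motifs produce (about one site per
4 kbp), and every value is exposed through `scoring_params()`.

## Alignment significance

With many contigs available, significance follows an empirical
extreme-value model $E(S) = K m n_r e^{-\lambda S}$: per segment, the best
score against every contig is collected, the top 25 removed (possible true
alignments), the remaining scores at or above their 85th percentile form
the high-scoring pairs, each gets an empirical E-value equal to its rank,
and $\log E$ is regressed on $S$ to estimate $K$ and $\lambda$. Score
cutoffs for the default p-values ($10^{-4}$ semi-global, $10^{-6}$
overlap, $10^{-9}$ detection) invert $P = 1 - e^{-E}$.

With only a handful of contigs the regression is degenerate, and a
conservative fixed cutoff is used instead: 60% of the *expected attainable*
perfect score, $0.6 \cdot 2c\,(n_\mathrm{eff} - 1)$. Here $n_\mathrm{eff}$
is the expected retained label count under the collapse model, computed by
the recursion $p_k = P_\mathrm{merge}(g_k)(1 - p_{k-1})$ over the
segment's gaps (a merge removes exactly one label of a pair, and a gap
cannot merge if its left neighbour already did). Using the raw label count
here would hold collapse-dense segments to an unreachable ideal and reject
their true alignments; using the per-label observability product would
double-count the loss (a merge removes one label of the pair, not both)
and let spurious chains through. The retained-count expectation is the
self-consistent middle. Alignments additionally must pass mean and median
per-step score thresholds (both 0 by default: a real placement must at
least break even per step on average).

## Scaffolds and imputation

Significant alignments on one contig, ordered by contig coordinate, form
the nodes of a scaffold DAG. A directed *allowed* edge connects a node to
the next compatible node — right endpoint overlapping the next left
endpoint by at most one label, with no compatible node strictly between
(adjacent endpoints only, which keeps the edge set linear-sized);
overlapping alignments are joined by *forbidden* edges and compete for a
place in the heaviest path.

Graph segments below the alignable-label minimum never become nodes; they
are recovered by *imputation*. For every allowed edge with a positive gap
under 400 kbp, a constrained depth-first search enumerates breakpoint-graph
paths between the flanking alignments' graph vertices, subject to: segment
multiplicity within the candidate at most the graph copy number; candidate
length within $\min(25000, 10000 L_p)$ bp of the expected gap (short side
checked at completion, long side during growth); at most $2^{10}$
candidates (on overflow the search re-runs breadth-first with the cap at
$2^{16}$); no trivial cycles through segments under 100 bp. Both phases
also carry a state-expansion budget (default $2 \times 10^5$) so dense
corrupted graphs cannot stall the search; an exhausted budget leaves the
junction unimputed, like a cap overflow.

Candidates are scored by a fitting alignment of a *compound map* — the
anchor labels plus the concatenated oriented digests of the interior
segments, laid end-to-start with no inserted gap (breakpoint edges are
direct adjacencies), with the anchors' unlabeled segment tails as spacers —
against the contig interval between the anchors. The unimputed junction
score is $2c - c\,n_\mathrm{int}$ (all interior contig labels
unexplained, the gap taken at face value); the best candidate is kept only
if it beats that.

## Paths, linking, and copy-number consistency

Per scaffold, maximum-weight source-to-sink paths (weight = summed segment
bp) are extracted by DP in topological order, with imputed gap paths
spliced in. Scaffolds from different contigs are linked when a suffix of
one path equals a prefix of another (in either assembly orientation of
each contig) *and* the shared terminal segment's alignment is clipped by
the contig end on at least one side (at least 5 of its labels unaligned
beyond the terminus; under the standard noise model a terminal label is
effectively lost with probability about 0.25, so five in a row keeps
false link evidence near 0.1% while genuine truncations, spanning tens of
labels, always qualify). The clipping requirement is the evidence criterion
implied by the linking rationale — a graph segment has no interior
breakpoints, so a segment truncated by a contig end must continue
elsewhere; two *complete* terminal observations of a shared segment are
not continuation evidence, and linking on them chimerises co-occurring
amplicons that merely share segments, which destroys precision on pooled
heterogeneous samples.

Candidate paths are then checked for copy-number-ratio consistency: for a
segment with path multiplicity $n_p$ and each occupied level $c < n_p$
with $m_g$ the maximum copy number among level-$c$ segments, we require
$n_p \le \max(c,\ c\,n_g / m_g) + 1$ — the multiplicity ratio may not
exceed the copy-number ratio by more than one copy. (The unscaled variant
$n_p \le \max(c, n_g/m_g) + 1$ rejects ratio-consistent structures —
including published ones with multiplicities 4:2:1 at copy numbers
46:25:12 — at the $c = 2$ level, so the ratio form is the one
implemented.) Surviving paths are sorted by total alignment score and
greedily filtered: a path is dropped if any rotation of it, or of its
orientation-reversed form, is a contiguous substring of an already-kept
path. Finally a path whose head repeats its tail (in at least 3 total
elements) is folded and flagged cyclic; singletons and two-element repeats
(segmental tandem duplications) stay linear.

## The simulator

`simulate_amplicon_structure()` partitions a region of a synthetic
reference (i.i.d. bases, which gives about one DLE-1 site per 4 kbp) into
segments and applies random inversions, duplications (30% inverted) and
block translocations to the identity path; the implied breakpoint graph
carries exact copy numbers (path multiplicity × amplicon copy number) and
one edge per distinct junction. Cyclic truths are rotated to start at the
longest segment — any rotation represents the same circle — and their
spanning contig wraps past the origin by that segment, so circularity is
detectable as the same segment aligned at both contig ends. Linear truths
place their two longest segments at the termini: a terminal segment below
the alignable-label minimum has no flanking anchor and is unrecoverable by
construction, which would make the noise-free exactness property
unattainable for reasons unrelated to the algorithms.

Noise is applied once to the spanning digest, standing in for
molecule-level simulation plus consensus assembly: label collapse by the
merge model (adjacent pairs fuse to their midpoint), i.i.d. label miss
(default rate 0.10), and Gaussian per-interval sizing error (sd = 2% of
the interval length, order-preserving). Assembly failure can be emulated
with `contig_break_rate`; molecule pools (`simulate_molecules()`,
log-normal lengths, median 244 kbp, minimum 150 kbp) support the
integration-point clustering workflow. What the simulator does *not*
emulate: chimeric joins, scan artifacts, false labels, and real consensus
assembly errors — so passing simulations demonstrate the reconstruction
algorithms under the stated error modes, not instrument-level fidelity.

## Evaluation

Reconstructions are scored against the truth by the longest common
substring (LCS) over oriented segment tokens, with the reconstruction also
tried in reversed orientation and cyclic paths compared over all rotations
(by doubling, capped at the path length). Three path measures are
supported: summed bp length, element count, and junction count. Precision
is $M(\mathrm{LCS})/M(\mathrm{recon})$ for the reconstruction with the
largest LCS (ties by LCS bp, then the smaller reconstruction); recall is
$M(\mathrm{LCS})/M(\mathrm{truth})$; F1 of $(0,0)$ is defined as 0.
Reference-trivial path tails (reference-adjacent run absent from the
truth) are trimmed before scoring. A forced duplication counts as
*resolved* when the truth sub-path from one element before the duplicated
block through one element after its copies occurs contiguously in a
reconstruction (rotation- and reversal-aware).

## Study cohorts and problem sizes

`run_study()` packages five end-to-end studies; these are the sizes used
throughout the test suite and the acceptance script, chosen to exercise
every pipeline stage while keeping a full run in the minutes range on one
core:

- `cn20`: 20 amplicons, 3–20 segments, 0.3–2.8 Mbp, 45% cyclic, copy
  number 20, one spanning noisy consensus contig each.
- `false_edges`: the same cohort with random false discordant edges added
  at 100% of the true edge count.
- `mixture`: 10 samples × 3 amplicons sharing one segment partition,
  copy numbers 20-15-10, pooled contigs, merged graph; every truth scored.
  Truth triples are rejection-sampled until every member passes the
  copy-number ratio check against the pooled graph — the analogue of
  heterogeneity studies built from paths of a single sample's graph, which
  are copy-number-consistent with that graph by construction. A subclonal
  structure genuinely inconsistent with the pooled copy numbers would be
  rejected by the ratio check, a known limitation of pooled-CN filtering.
- `denovo`: 20 circular structures, total length log-normal around 2 Mbp,
  segment count Poisson around 9.
- `duplication`: 20 amplicons with a forced ~280 kbp tandem duplicated
  block of 1–3 segments; reports the resolved fraction.

A small worked example:

```{r example, eval = FALSE}
set.seed(7)
ref <- random_reference()
cfg <- sim_config(n_segments = 8, total_bp = 1.6e6, cyclic = TRUE)
truth <- simulate_amplicon_structure(cfg, ref)
contigs <- simulate_contigs(truth, ref, cfg)
recon <- reconstruct_amplicon(truth$graph, contigs, ref)
summary(recon)
precision_recall(truth, recon$paths, "length_bp")
```

## Known limitations

- Terminal graph segments below the alignable-label minimum cannot be
  recovered (no flanking anchor); highly segmented graphs whose alignable
  anchors are separated by more than the 400 kbp imputation limit lose the
  intervening content — both mirror the failure modes reported for this
  class of method.
- The empirical E-value slope estimate is consistent but noisy below a few
  hundred contigs; small datasets use the conservative fixed cutoff
  instead.
- The greedy rotation-subsequence filter can discard a true amplicon that
  is a substring of a co-occurring larger reconstruction; the LCS scoring
  then charges the containing path's extra content to precision.
- Detection-mode search of unaligned contig regions assigns new segments
  the median amplified copy number, as the region carries no read-depth
  information of its own.
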