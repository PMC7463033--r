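# omamplicon

Reconstruction of focal copy-number amplifications (ecDNA,
breakage–fusion–bridge products, and other complex rearrangements) by
integrating an NGS-derived **breakpoint graph** with **optical map (OM)
contigs**.

## Who this is for

Cancer-genomics analysts who have (a) a copy-number-annotated breakpoint
graph of an amplified region — genomic segments plus concordant/discordant
junction edges — and (b) Bionano-style consensus maps (CMAP) of the same
sample, and who want the large-scale *structure* of the amplicon: the
order and orientation of its segments, including duplicated blocks and
circularity, which the graph alone usually leaves ambiguous.

## What it does

1. **In silico digestion**: each graph segment becomes an ordered list of
   label positions for the instrument's motif (DLE-1 `CTTAAG` or Nt.BspQI
   `GCTCTTC`).
2. **Alignment**: a banded dynamic program scores segment-to-contig
   placements,

   `Score(i,j,p,q) = 2c − ( c·(j−i−1) + c·M(p,q) + |(b_j−b_i) − (x_q−x_p)|^k )`,

   where `M(p,q)` is the expected number of *observable* labels skipped on
   the segment under a label-collapse model (labels closer than ~2 kbp
   merge during imaging). Alignments are extracted iteratively with
   used-pair masking (duplications!), and significance comes from an
   empirical E-value model `E = K·m·n_r·e^(−λS)` calibrated per segment
   (with a conservative fixed fallback when contigs are few).
3. **Scaffolding**: per contig, significant alignments form a DAG with
   allowed edges between adjacent compatible endpoints (≤ 1 label overlap)
   and forbidden edges between overlapping ones.
4. **Imputation**: gaps under 400 kbp are explained by constrained search
   for breakpoint-graph paths between the flanking alignments, scored by a
   fitting alignment of the concatenated ("compound") label map; the best
   candidate is kept only if it beats the unimputed junction.
5. **Pathfinding**: heaviest scaffold paths, cross-contig linking on
   clipped shared end segments, a copy-number ratio check
   (`n_p ≤ max(c, c·n_g/m_g) + 1`), greedy rotation-subsequence
   filtering, and cyclic/linear classification. Output is the standard
   cycles format.

A simulator (rearranged amplicon structures, noisy consensus maps and
molecules, false graph edges, heterogeneous mixtures, unlabeled viral
inserts) and an LCS-based precision/recall module make the whole pipeline
verifiable end to end — see the methods vignette
(`vignettes/amplicon-reconstruction.Rmd`) for the models and the design
decisions.

## Worked example

Simulate a cyclic 1.6 Mbp amplicon of 8 segments, generate a noisy
spanning consensus map, reconstruct, and score:

```r
library(omamplicon)
set.seed(7)
ref    <- random_reference()                       # synthetic 2x6 Mbp genome
cfg    <- sim_config(n_segments = 8, total_bp = 1.6e6, cyclic = TRUE)
truth  <- simulate_amplicon_structure(cfg, ref)    # path: 7+,8+,5+,4-,1+,2+,3-,6+
contigs <- simulate_contigs(truth, ref, cfg)       # miss 10%, collapse, 2% sizing sd
recon  <- reconstruct_amplicon(truth$graph, contigs, ref)
summary(recon)
#> Reconstruction summary: 8 alignments, 1 scaffolds
#>  path n_elements length_bp cyclic    score  contigs
#>     1          8   1600000   TRUE 851174.6 contig_1
precision_recall(truth, recon$paths, "length_bp")
#> <eval_result> length_bp: precision 1.000, recall 1.000, F1 1.000
```

The single reconstructed path reproduces the simulated circle exactly
(same 8 oriented segments, cyclic flag set from the segment aligned at
both contig ends), so precision and recall are 1 under the bp-length LCS
metric. `write_cycles(recon$paths, recon$graph$segments, "cycles.txt")`
emits the standard cycles file; `plot(recon)` draws the scaffold layout.

A thin command-line wrapper is included at
`inst/scripts/om-amplicon.R` (`align`, `reconstruct`, `simulate`,
`evaluate` subcommands) for shell use on CMAP/XMAP/graph/cycles files.

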