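# invgsea

Two-contrast transcriptome analysis for degeneration studies: weighted
running-sum gene set enrichment with permutation nulls, cross-contrast
*inverted* enrichment testing, and core-module detection on
combined-score-thresholded interaction networks.

## The problem

Bulk RNA-seq studies of neuronal degeneration — for instance spiral
ganglion neuron (SGN) loss after ototoxic insult — often compare two
contrasts over the same gene universe: degeneration vs control in
wild-type tissue (defining a degeneration-specific gene signature), and a
protected genotype vs wild-type under the same insult. The biological
question is whether the protected genotype *reverses* the degeneration
signature: are the genes that go up during degeneration pushed back down
(and vice versa)? `invgsea` turns that question into a signed enrichment
statistic with a permutation null, and complements it with differential
expression, collection-wide GSEA, and protein–protein-interaction module
detection, so the full analysis chain runs from a counts matrix to a
module table.

## The statistics

**Enrichment score.** For a gene list *L* of length *N* ranked by a
per-gene metric *r* and a gene set *S* with *N_h* members in *L*, walk
down the list accumulating

- *P_hit(S, i)* = Σ_{g_j ∈ S, j ≤ i} |r_j|^w / Σ_{g_j ∈ S} |r_j|^w
- *P_miss(S, i)* = Σ_{g_j ∉ S, j ≤ i} 1 / (N − N_h)

The enrichment score ES is the signed value of *P_hit − P_miss* at the
position where its magnitude is maximal; with *w* = 0 the magnitude is
the classical two-sample Kolmogorov–Smirnov statistic on hit vs miss
ranks. Significance comes from phenotype permutations (labels reshuffled,
ranking recomputed) or gene-set permutations (size-matched random sets),
with the add-one estimator restricted to same-sign permutations, and
NES = ES / mean |ES\*| over same-sign permutations.

**Inverted enrichment.** The signature of contrast A (up- and
down-called genes at *P* < 0.01, |log2FC| > 0.2) is scored against
contrast B's ranked list after negating the metric of A-down genes, so
concordant regulation gives NES > 0 and inverted regulation NES < 0.
Exact set arithmetic counts the direction-reversed genes alongside.

**Core modules.** Edges with STRING-style combined score > 0.4 (both the
[0,1] and 0–1000 dialects are read) form the interaction network; a
from-scratch MCODE implementation (k-core-based vertex weighting, greedy
seeded expansion, haircut post-processing; parameters 2 / 0.2 / haircut
on / K-core 2 / depth 100) returns density-scored modules.

A synthetic-data generator plants differential expression with a chosen
inversion fraction, spiked gene sets, and dense subgraphs, so every stage
is testable offline against known ground truth.

## Worked example

```r
library(invgsea)

design <- sim_design(n_genes = 2000, n_de = 200,
                     inversion_fraction = 0.8, seed = 42)
sim <- simulate_two_contrast_counts(design)

dge_A <- differential_expression(sim$expr_A, "treated", "control")
dge_A
#> dge_result: treated vs control (exact_nb), 2000 genes
#> calls at p < 0.01, |log2FC| > 0.2: 82 up, 107 down, 1811 ns

dge_B <- differential_expression(sim$expr_B, "treated", "control")
pair <- contrast_pair(dge_A, dge_B, expr_B = sim$expr_B,
                      treated_B = "treated", reference_B = "control")
report <- inverted_enrichment(pair, n_permutations = 500, seed = 42)
report
#> inversion_report (direction-aware cross-contrast enrichment)
#>   NES = -1.881, p = 0.004016 (phenotype, 500 permutations)
#>   44 of 82 A-up genes are down in B; 62 of 107 A-down genes are up in B

net <- simulate_planted_module_graph(200, 0.01, list(c(10, 0.9)), seed = 42)
mods <- mcode_find_complexes(net$network)
mods
#> mcode_result: 2 module(s)
#>   #1 score 8.50: 9 nodes, 34 edges (seed N0015)
#>   #2 score 3.00: 3 nodes, 3 edges (seed N0043)
```

The 0.8 inversion fraction plants direction reversal for 80% of the 200
differential genes, and the direction-aware test recovers it as a strongly
negative NES (−1.88, p ≈ 0.004): contrast B undoes contrast A's
signature. With `inversion_fraction = 0` the same pipeline returns a
strongly positive NES. The module detector recovers 9 of the 10 planted
dense-subgraph nodes (score = density × node count).

End-to-end runs over files on disk go through `write_simulation()`,
`pipeline_config()` and `run_pipeline()` (TSV/GMT/RNK/edge-list in,
per-stage TSVs plus a reproducibility manifest out); a thin CLI wrapper
lives at `inst/cli/pipeline.R`.

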