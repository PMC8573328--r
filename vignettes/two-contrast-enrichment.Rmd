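---
title: "Two-contrast enrichment, inversion testing and module detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-contrast enrichment, inversion testing and module detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invgsea)
```

This vignette is the package's own account of what it computes, the
choices that were genuinely open, and what its tests do and do not show.

## The running-sum enrichment statistic

Given a ranked gene list $L$ of length $N$ with metric $r_j$ and a gene
set $S$ with $N_h$ members in $L$, the statistic accumulates a weighted
hit CDF $P_{hit}(S,i)=\sum_{g_j\in S,\,j\le i}|r_j|^w / \sum_{g_j\in
S}|r_j|^w$ and a miss CDF $P_{miss}(S,i)=\#\{g_j\notin S,\,j\le
i\}/(N-N_h)$. Both reach exactly 1 at $i=N$, so the running difference
terminates at 0 — `compute_es()` asserts this on every call as a cheap
internal consistency check. The enrichment score is the *signed* value
of $P_{hit}-P_{miss}$ at the position of maximal magnitude.

Two points here were design decisions:

* **Signed ES.** The maximum-deviation form is a magnitude; but the
  scientific use of the statistic needs to distinguish enrichment at the
  top of the list from enrichment at the bottom (a reported negative NES
  is meaningless otherwise). We therefore return the signed deviation
  whose magnitude equals the maximum-deviation statistic.
* **Weight exponent.** $w$ defaults to 1, the standard weighted form;
  $w=0$ recovers the classical two-sample Kolmogorov–Smirnov statistic
  between hit and miss ranks, which the test suite verifies against
  `stats::ks.test` to $10^{-12}$ and against `fgsea::calcGseaStat` as a
  second independent implementation.

Ties in the ranking are broken lexicographically on gene ID (C locale,
radix sort), making every ordering — and therefore every downstream
number — total and reproducible.

## Permutation significance and NES

The permutation p-value uses the sign-matched add-one estimator
$p = (1+\#\{\text{same-sign } |ES^*|\ge|ES|\}) / (1+\#\{\text{same-sign
permutations}\})$, which cannot return 0 and is the natural estimator
when the observed labelling is itself one realization of the null. In
exhaustive gene-set mode (every subset of size $N_h$ enumerated, used on
small instances) the plain tail proportion is used instead — the
observed subset is one of the enumerated ones, so positivity is
automatic. No published formula fixes the NES; we use the convention of
the method family the statistic comes from: $NES = ES / \mathrm{mean}\,
|ES^*|$ over same-sign permutations, undefined (with a warning) when
fewer than two same-sign permutations exist.

Phenotype permutations reshuffle sample-to-group labels and recompute
the entire signal-to-noise ranking per permutation; in
`enrich_collection()` the same permuted rankings are shared across all
sets, the standard scheme that keeps collection-wide FDR coherent.
A practical caveat worth knowing: at 6 + 6 samples, balanced label
shuffles overlap the true grouping substantially, so the phenotype null
of a truly enriched set is inflated relative to a size-matched random-set
null. That is a property of phenotype permutation at small $n$, not of
the implementation; the test suite's set-ordering checks therefore use
the gene-set null, and the calibration checks use a global-null design
where the effect is absent.

## Differential expression

Calls use raw $P < 0.01$ and $|\log_2 FC| > 0.2$; the fold change is
always $\log_2((\bar x_{trt}+1)/(\bar x_{ref}+1))$ on raw group means, so
it is well defined at zero counts and bit-reproducible.
Benjamini–Hochberg values are reported but do not drive calls (the
calling rule is a raw-p convention; switching to `padj` is a one-line
change for users who want it).

The p-value engine was a genuinely open choice. A per-gene Welch t-test
on $\log_2(x+1)$ is the simplest defensible test and is provided
(`method = "welch"`); but at 6 samples per group with biological
coefficient of variation $\sqrt{0.1}\approx0.32$ it has roughly 60%
power at $P<0.01$ for a 1.0 log2-fold effect — below what a recovery-
oriented pipeline should deliver, and the reason count-based methods
that share dispersion information across genes exist. The default is
therefore the negative-binomial exact test (edgeR classic: TMM
normalization, tagwise dispersion, `exactTest`), which reaches ~0.85
sensitivity at ~0.06 false-discovery proportion under the same design.
The Welch engine remains the right choice for already-normalized
(non-count) matrices and doubles as an independent check: both engines
are verified to hold the nominal null rate (fraction of $p<0.01$ within
binomial noise of 0.01 under a global null).

The signal-to-noise ranking metric divides the difference of group means
of $\log_2(x+1)$ by the sum of group standard deviations, each floored
at $\max(\sigma, 0.2|\mu|, 0.2)$ — the conventional guard that keeps
zero-variance genes from dominating the extremes of the list.

## The inverted cross-contrast test

The degeneration-specific signature is the union of contrast A's up- and
down-called genes with their directions. To test it against contrast B,
the metric of every A-down gene is negated before re-sorting and the
signed combined set is scored with `compute_es()`. This direction-aware
construction was chosen over scoring an unsigned union because an
unsigned union cannot yield a negative score under inversion — it is the
only construction of the two that can express "B reverses A". The
unsigned variant (A-up set against the plain B ranking) is available via
`include_unsigned = TRUE` for comparison. Phenotype permutations
re-derive the B ranking and re-apply the flip each time, so the null
respects the construction.

Direction-reversed genes are additionally counted by exact set
arithmetic over the shared universe (genes absent from either contrast
are dropped and the coverage is checked, with a warning below 90%);
these counts are deliberately decoupled from the enrichment statistic so
each can be sanity-checked against the other.

## Network modules

Edges are kept when the combined score is strictly greater than 0.4;
the reader auto-detects the 0–1000 integer dialect (any value above 1
rescales the column by 1000), collapses reciprocal duplicates keeping
the maximum score, and drops self-loops. Scores are used only for
thresholding — the module detector runs on topology.

The detector implements the molecular-complex-detection scheme: vertex
weight is the highest k-core order of the closed neighborhood times that
core's density; complexes grow greedily from unassigned seeds in
decreasing weight order, admitting unassigned neighbors whose weight
exceeds the seed's weight times $(1-\text{node score cutoff})$;
post-processing discards complexes without a 2-core and haircuts members
of induced degree < 2. Defaults are degree cutoff 2, node score cutoff
0.2, haircut on, fluff off, K-core 2, max depth 100. Two boundary
behaviors deserve explicit documentation:

* **Uniform-weight bridges.** When two dense regions of equal vertex
  weight are joined by a single edge, the admission rule crosses the
  bridge (every node passes the threshold) and the regions merge into
  one complex. This is the faithful behavior of the greedy rule; tests
  pin it down on a bridged pair of 4-cliques.
* **Haircut disconnection.** The haircut can in principle disconnect a
  complex; the component containing the seed is then kept (largest
  component, smallest member ID on ties, if the seed itself was
  stripped), keeping the "members connected" invariant and total
  determinism.

Module score is induced density × node count. An independent checker
(`validate_modules()`) re-derives connectivity, counts, scores, k-core
existence, haircut bounds and disjointness straight from the graph and
is run inside the pipeline after every detection.

## The synthetic-data generator

The generator emulates the structure of a two-contrast degeneration
study: negative-binomial counts (variance $\mu + \alpha\mu^2$) around
log-normal gene baselines (median 150, log-sd 1 — moderately expressed
transcripts with a realistic spread), a planted differential core shared
by both contrasts with exact $\pm$lfc shifts on treated-group means, and
a chosen fraction of that core direction-flipped in contrast B
(`round(inversion_fraction * n_de)` genes, exactly). Defaults — 2000
genes, 200 differential, 6 samples per group, lfc 1.0, dispersion 0.1 —
are the study conditions used throughout the tests and the acceptance
script; they were chosen once as a typical bulk-RNA-seq regime
(BCV ≈ 0.32, moderate effects, small groups) and give the problem sizes
that keep the full suite in the minutes range. Module-graph fixtures use
200 nodes, background edge probability 0.01 and a planted 10-node
module of density 0.9; edge scores are drawn in (0.4, 1] so topology
tests are decoupled from threshold tests.

What the generator does **not** emulate: library-size variation between
samples (beyond what TMM absorbs), mean–dispersion trends, gene–gene
correlation within pathways, batch structure, or contrast-specific
differential genes outside the shared core. Passing tests therefore
demonstrate correctness of the statistics and recovery under a clean
overdispersed model — not robustness to the full messiness of real
tissue data.

## Numerical and degenerate-input conventions

* Zero-variance genes: Welch p is 1 when group means are equal, 0
  otherwise; the signal-to-noise floor handles ranking.
* `compute_es()` refuses empty or universe-covering intersections
  (the miss denominator must be positive) and an all-zero weighted hit
  normalizer.
* ES = 0 profiles have an empty leading edge and p = 1.
* All sorts are radix sorts with documented tie-breaks; reruns of any
  seeded computation are byte-identical, which the pipeline tests assert
  on whole output bundles.

## Known limitations

* The phenotype-permutation NES is conservative for strongly enriched
  sets at very small group sizes (see above); the gene-set null is the
  sharper instrument there.
* No multi-level p-value refinement: permutation p-values are floored at
  the add-one bound, so FDR resolution is limited by the permutation
  count.
* The fluff post-processing stage of the module detector is not
  implemented (flag reserved); module membership for sparse planted
  modules can drop low-degree members by design of the haircut.
* `P < 0.01` on raw p-values follows the field convention the pipeline
  targets; users comparing across very different universe sizes should
  prefer the reported `padj`.
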