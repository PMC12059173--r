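---
title: "Statistical methods for TLS maturity analysis"
author: "TLSscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for TLS maturity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TLSscape)
```

## Scope

Tertiary lymphoid structures (TLS) are ectopic lymphoid aggregates that
form in tumors and range from absent (nTLS) through immature (imTLS) to
mature, germinal-center-containing (mTLS) states. TLSscape implements the
statistical layer used to compare these states across data modalities:
compositional enrichment of cell clusters, density contrasts on 2-D
embeddings, TCR/BCR clonotype definition with diversity and sharing
statistics, rank-based gene-set activity scoring, a spot-level cell-type
co-occurrence score for spatial transcriptomics, and nearest-neighbour
proximity statistics for multiplex imaging. Upstream machinery —
alignment, clustering, batch correction, UMAP, deconvolution, image
segmentation — is out of scope; their outputs (cell tables, embeddings,
spot abundances, coordinates) are this package's inputs.

Every method ships with a synthetic-data generator that plants the
parameter the method is supposed to estimate, so the whole pipeline is
covered by parameter-recovery tests without access to patient data.

## Compositional enrichment

For cluster $c$ and TLS statuses $A, B$, cluster membership is modeled
one-vs-rest as binomial with a logit link and status as the sole factor.
The reported effect is the estimated-marginal-mean contrast on the logit
scale, expressed in bits:

$$\log_2 \mathrm{OR} = \frac{\mathrm{logit}\, \hat p_A -
\mathrm{logit}\, \hat p_B}{\ln 2},$$

with Wald standard error and two-sided p-value. Because the one-factor
binomial model is saturated, the estimate coincides with the closed-form
2×2 contingency odds ratio; the test suite checks agreement to $10^{-6}$.
A full interaction model over all clusters yields the same cluster-wise
marginal contrasts; the per-cluster formulation is used because it is
numerically simpler and reported per cluster anyway.

Choices made where the procedure was genuinely open:

* **Pooling.** Cells are pooled within status (each cell one binary
  observation), matching the binary-choice framing; a `by = "sample"`
  mode treats per-sample binomial totals as the observations instead.
  For the one-factor model both give identical estimates — the option
  exists for auditability, not because the numbers move.
* **Zero cells.** If the cluster is empty (or exhaustive) in one status,
  0.5 is added to all four 2×2 cells (Haldane–Anscombe) and Wald
  statistics are computed from the corrected table; the result carries
  `corrected = TRUE`. This keeps the log odds ratio finite.
* **Multiplicity.** Bonferroni with family = the rendered grid (clusters
  × status pairs), i.e. per-panel adjustment. Whether the family should
  span several panels is not decidable from the procedure itself; the
  family size is recorded in every result row so any other family can be
  reconstituted.

## Embedding density contrasts

Per status, a product-Gaussian KDE is evaluated on a shared 100×100 grid
covering the pooled embedding's bounding box padded by three bandwidths:

$$\hat f(x,y) = \frac{1}{n}\sum_i \phi_{h_x}(x - x_i)\,\phi_{h_y}(y - y_i).$$

The bandwidth is the normal reference rule (`bw.nrd`) computed on the
*pooled* embedding and shared across statuses — contrasts are only
meaningful at a common smoothing scale. Each density integrates to one,
so the contrast $\hat f_A - \hat f_B$ compares distributional shape
rather than abundance; a `weighted = TRUE` mode multiplies by cell counts
when absolute density is wanted. A zero-variance axis falls back to a
small fixed bandwidth with a warning. Per-cluster versus per-compartment
granularity is left to the caller via the `group` argument, since the
appropriate faceting depends on the question being asked.

## Clonotypes, diversity, sharing

Cells with chains of both receptor classes are excluded as *ambiguous*;
cells with more than two chains of one paired arm (e.g. a third β chain)
are excluded as *multichain*. A secondary chain of one arm (two total)
is tolerated and enters the clonotype key.

* **TCR.** A clonotype is the exact pair of CDR3 nucleotide sequence
  sets over both arms; single-arm cells form keys that never merge with
  paired keys. "Expanded" means clone size ≥ 2, counted over all
  assigned cells regardless of cluster.
* **BCR.** Heavy chains are partitioned by (V gene, J gene, junction
  length) — multi-gene annotations resolve to the first listed call —
  and clustered by single linkage on normalized Hamming distance of the
  junction, cut at a threshold. Single linkage is the permissive
  convention for clonal grouping (a chain of near neighbours belongs
  together); light chains do not enter the distance. The threshold is
  estimated from the valley between the two modes of the
  distance-to-nearest distribution (clonally related vs unrelated
  sequences in the same partition) and falls back to 0.15 with a warning
  when that distribution is unimodal or too small (< 20 heavy chains).
* **Diversity.** Shannon entropy $-\sum_i p_i \ln p_i$ in nats (the
  base is a flag) and D50 = 100 × (smallest number of clonotypes, in
  descending size order, whose cumulative cell fraction reaches 0.5) /
  (number of clonotypes); the boundary tie resolves to the first index
  reaching 0.5.
* **Sharing.** Entry $(i, j)$ of the sharing matrix counts clonotypes
  with at least one cell in each of clusters $i$ and $j$; per-status
  matrices restrict to one status's cells. The shared-feature fraction
  between two cluster groups is computed per sample by default because
  the corresponding displays show per-sample points; a pooled mode
  exists.

## Gene-set activity

`aucellScore()` ranks each cell's genes by decreasing expression and
integrates the recovery curve of set members over the top
$\lceil 0.05\,G \rceil$ ranks, normalized by the maximum attainable area,
yielding scores in $[0,1]$. The statistic is rank-based, hence invariant
to any monotone per-cell normalization. Ties are broken deterministically
by gene order (a seeded random mode exists); determinism was preferred so
reruns are bit-identical. The bundled signatures — the classical
12-chemokine TLS signature, the 29-gene TLS imprint, and the naive,
cytotoxicity, proliferation, progenitor-exhausted/Tfh and terminally
exhausted T-state lists — are available via `bundledGeneSets()` exactly
as curated. `scaleModuleScore()` complements this with a z-score-based
module mean (log-normalized expression assumed) min–max scaled along a
supplied cell ordering, e.g. a pseudotime computed elsewhere.

## Spatial co-occurrence

With $C_{ij}$ the predicted abundance of type $i$ in spot $j$ over $N$
spots,

$$\mathrm{score}_{AB} = \frac{\sum_{j=1}^{N} C_{Aj} C_{Bj}}{N} \times 1000 .$$

Abundances are used exactly as provided — no per-spot renormalization —
and all-zero spots stay in $N$. Under independence the expected score is
$\bar C_A \bar C_B \times 1000$, which is what the generator reproduces
at co-localization 0. A compositional mode (row-normalized spots) is
offered for sensitivity analysis only.

## Imaging proximity

Distances are Euclidean in microns with no edge correction — medians of
raw nearest-neighbour distances are reported, so estimates near core
boundaries are biased upward equally across groups; this is a documented
limitation rather than a correction target. Self-neighbourhood is
excluded by cell id, so coincident distinct cells count at distance 0.
Summaries are per core and phenotype pair, with a pooled per-status mode;
per-core medians are the default because cores are the natural
experimental unit. Missing phenotypes yield rows with missing medians
rather than silently dropping the core.

## The synthetic generators

All generators are pure functions of their spec including its seed; one
master seed expands into per-module child seeds by fixed offsets, and
ground truth is always returned beside the data.

* **Composition.** Cluster proportions per status are derived from the
  base proportions so that each planted cluster's one-vs-rest odds ratio
  is *exactly* $2^{\beta}$, with the remaining mass spread over
  unaffected clusters in their base ratios. A consequence worth knowing:
  planting effects on some clusters shifts the one-vs-rest odds of the
  others, so a "null" cluster is only exactly null in an effect-free
  simulation.
* **Expression.** Negative-binomial counts with per-gene Gamma base
  means; signature-gene means are multiplied by $(1 + \mathrm{effect})$
  in flagged cells. Large dispersion approaches Poisson.
* **Repertoire.** Clone-size weights follow a truncated discrete
  power law (zeta; exponent 2.5 by default, the heavy-tailed expansion
  regime); clonotypes are homed in clusters and span a partner cluster
  with the pair's sharing probability; CDR3s are random nucleotide
  strings of length 30–45 in multiples of 3, so identity — not
  similarity — encodes TCR clonotype.
* **Spots.** Independent per-type Gamma abundances plus, per
  co-localized pair, a shared Gamma(1,1) factor scaled by the loading
  ρ and added to both types. This was chosen over adding the factor to
  Dirichlet-normalized abundances because row normalization induces
  negative cross-type correlation, which would break the exact
  independence reference at ρ = 0; with independent Gammas, ρ = 0 means
  independent and the co-occurrence score is provably non-decreasing
  in ρ.
* **Points.** Clustered phenotypes follow a Neyman–Scott (Thomas)
  process — Poisson parents, Poisson offspring, Gaussian scatter —
  optionally sharing parents across phenotypes to plant cross-phenotype
  proximity; other phenotypes are complete spatial randomness. Offspring
  falling outside the window are dropped.

What the generators deliberately do **not** emulate: raw reads, UMI
collisions, batch effects, somatic hypermutation phylogenies, realistic
transcriptome-wide correlation, or irregular tissue geometry. Passing
recovery tests therefore demonstrates correctness of the statistics, not
robustness to every artefact of real data.

## Numerical conventions and problem sizes

Delimited outputs serialize floats at 12 significant digits; MTX plus
index files carry counts; AIRR Rearrangement TSV carries chains. All
randomness flows from config seeds — no stage reads ambient RNG state —
so pipeline reruns produce identical output checksums (modulo manifest
timings).

The bundled demonstration uses 3 statuses × 4 samples × 2,000 cells,
1,000 genes, a 400-clonotype TCR repertoire, 300 spots × 5 types and 6
imaging cores: large enough that planted effects dominate sampling noise,
small enough to run end-to-end in about a minute on one CPU. The
composition recovery studies use 10,000 cells per status, where the
planted ±2 log2 odds ratios are recovered with bias well under 0.1 and
95% Wald intervals cover at their nominal rate.
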