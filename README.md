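# TLSscape

Statistics for comparing tertiary lymphoid structure (TLS) maturity
states — absent (nTLS), immature (imTLS) and mature,
germinal-center-containing (mTLS) — across the data modalities of a
modern tumor-immunology study: single-cell transcriptomes, paired-chain
TCR/BCR repertoires, spatial transcriptomic deconvolution output, and
multiplex-imaging cell coordinates. It is written for analysts who
already have the upstream objects (cluster labels, embeddings, receptor
contigs, spot abundances, segmented cell positions) and need the
downstream inference layer.

## What it computes

* **Compositional enrichment.** Per-cluster one-vs-rest binomial-logit
  models with estimated-marginal-mean contrasts between statuses,
  reported as log2 odds ratios with Wald errors and Bonferroni
  adjustment over the grid:
  `log2 OR = (logit p_A − logit p_B) / ln 2`.
  Saturated on one factor, the estimate equals the closed-form 2×2
  contingency odds ratio; zero cells get a flagged Haldane–Anscombe
  correction.
* **Embedding density contrasts.** Product-Gaussian KDE per status on a
  shared grid with a common normal-reference bandwidth, and node-wise
  differences `f_A − f_B` between unit-mass densities.
* **Repertoire analysis.** Ambiguous/multichain exclusion; TCR
  clonotypes by exact paired CDR3-nucleotide identity; BCR clonotypes by
  single-linkage clustering of heavy-chain junctions within V/J/length
  partitions at a data-driven distance threshold; Shannon entropy and
  D50 diversity; cross-cluster clonotype sharing matrices and
  shared-feature fractions of expanded clones.
* **Gene-set activity.** Rank-based AUC scores (area under the
  recovery curve over the top 5% of each cell's ranking, normalized to
  [0,1]), with the 12-chemokine, 29-gene TLS-imprint and T-cell-state
  signatures bundled.
* **Spatial co-occurrence.** For cell types A, B over N spots with
  predicted abundances C:
  `score_AB = (Σ_j C_Aj · C_Bj / N) × 1000`.
* **Imaging proximity.** Euclidean pairwise and nearest-neighbour
  distances between phenotypes, with per-core medians grouped by TLS
  status.
* **Synthetic data.** Generators that plant every parameter the methods
  estimate (log2 ORs, signature elevation, clone-size law and sharing
  probability, co-localization loading, spatial clustering), so the
  whole pipeline carries parameter-recovery tests.

## Worked example

Plant a log2 odds ratio of 2 for a "stem" cluster in mTLS, recover it,
and run repertoire statistics on a simulated TCR repertoire with 25%
clonotype sharing between two clusters:

```r
library(TLSscape)

spec <- compositionSpec(
  statuses = c("nTLS", "imTLS", "mTLS"),
  samplesPerStatus = 4, cellsPerSample = 2000,
  clusters = c("stem", "effector", "tex", "other"),
  baseProportions = c(0.20, 0.25, 0.15, 0.40),
  plantedLog2OR = data.frame(cluster = "stem", status = "mTLS", log2_or = 2),
  seed = 1)
cells <- simulateComposition(spec)
res <- enrichmentGrid(cells)
subset(res, cluster == "stem", c(cluster, contrast, log2_or, se, p_adj))
#>   cluster      contrast log2_or     se p_adj
#> 7    stem imTLS_vs_nTLS  0.0714 0.0572     1
#> 8    stem  mTLS_vs_nTLS  2.0752 0.0520     0
#> 9    stem mTLS_vs_imTLS  2.0039 0.0515     0
```

The planted effect (2) is recovered in the two mTLS contrasts; the
untouched imTLS contrast sits at 0.

```r
tcells <- data.frame(cell_id = cells$cell_id,
                     subcluster = cells$subcluster, lineage = "T")
rep <- simulateRepertoire(tcells, repertoireSpec(
  nClonotypes = 300,
  sharingProb = data.frame(cluster_a = "stem", cluster_b = "effector",
                           prob = 0.25),
  seed = 2))
asg <- defineTcrClonotypes(rep$chains)
asg
#> ClonotypeAssignment (TCR): 24000 cells, 300 clonotypes
#>   classes: TCR=24000
#>   expanded clonotypes (size >= 2): 300
clonalDiversity(asg)
#>   group shannon d50 n_cells n_clonotypes
#> 1   all   5.089  13   24000          300
sharingCounts(sharingMatrix(asg, cells))[c("stem", "effector"),
                                         c("stem", "effector")]
#>            stem effector
#> stem        105       32
#> effector     32       77
```

Shannon entropy is in nats; D50 = 13 means 13% of clonotypes account for
half the cells (an oligoclonal, power-law repertoire). 32 of the 105
clonotypes seen in the stem cluster also appear in the effector cluster,
reflecting the planted 25% sharing probability.

A complete synthetic study (cells, counts, chains, spots, imaging cores)
plus an end-to-end run:

```r
cfg <- writeSyntheticDemo("demo", seed = 42)
manifest <- runPipeline(cfg)   # writes demo/out/*.csv and manifest.json
```

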