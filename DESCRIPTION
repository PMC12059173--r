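Package: TLSscape
Title: Composition, Repertoire and Spatial Statistics for Tertiary
    Lymphoid Structure Maturity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for dissecting tertiary lymphoid structure
    (TLS) maturity states (nTLS, imTLS, mTLS) from single-cell, antigen
    receptor repertoire, spatial transcriptomic and multiplex imaging data.
    Implements per-cluster compositional enrichment via binomial-logit
    models with estimated-marginal-mean contrasts, kernel density contrasts
    on 2-D embeddings, paired-chain TCR clonotype calling and
    distance-based BCR clonal clustering with Shannon/D50 diversity and
    cross-cluster sharing statistics, rank-based AUC gene-set activity
    scoring with bundled TLS signatures, a spot-level cell-type
    co-occurrence score, and nearest-neighbour proximity summaries for
    phenotype-labelled point patterns. A synthetic-data module with planted
    effects supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    emmeans,
    jsonlite,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
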