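#' Construct a gene set
#'
#' @param name set label.
#' @param genes character vector of gene symbols (deduplicated, must be
#'   nonempty).
#' @return a `GeneSet` list with elements `name` and `genes`.
#' @export
geneSet <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene set '", name, "' is empty")
  structure(list(name = name, genes = genes), class = "GeneSet")
}

#' Bundled TLS and T-cell-state signatures
#'
#' The curated signatures used throughout the package: the classical
#' 12-chemokine TLS signature, the 29-gene TLS imprint signature, and the
#' naive, cytotoxicity, proliferation, progenitor-exhausted/Tfh and
#' terminally exhausted T-cell state signatures.
#'
#' @return named list of [geneSet()] objects.
#' @export
bundledGeneSets <- function() {
  list(
    chemokine12 = geneSet("chemokine12", c(
      "CCL2", "CCL3", "CCL4", "CCL5", "CCL8", "CCL18", "CCL19", "CCL21",
      "CXCL9", "CXCL10", "CXCL11", "CXCL13")),
    tls_imprint = geneSet("tls_imprint", c(
      "IGHA1", "IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHGP", "IGHM",
      "IGKC", "IGLC1", "IGLC2", "IGLC3", "JCHAIN", "CD79A", "FCRL5",
      "MZB1", "SSR4", "XBP1", "TRBC2", "IL7R", "CXCL12", "LUM", "C1QA",
      "C7", "CD52", "APOE", "PTLP", "PTGDS", "PIM2", "DERL3")),
    naive = geneSet("naive", c("CCR7", "IL7R", "TCF7")),
    cytotoxicity = geneSet("cytotoxicity", c(
      "GZMA", "GZMB", "GZMH", "PRF1", "NKG7", "GNLY")),
    proliferation = geneSet("proliferation", c("STMN1", "TUBB", "MKI67")),
    tex_prog_tfh = geneSet("tex_prog_tfh", c("CXCL13", "TCF7", "PDCD1")),
    tex_term = geneSet("tex_term", c(
      "TOX", "HAVCR2", "CD101", "PDCD1", "LAG3", "CXCL13", "ENTPD1",
      "TIGIT")))
}

#' Rank-based AUC gene-set activity score per cell
#'
#' For every cell, genes are ranked by decreasing expression (ties broken
#' deterministically by gene column order, or randomly when
#' `randomTies = TRUE`). The score is the area under the recovery curve —
#' the running count of gene-set members encountered while walking down
#' the ranking — over the top \code{ceiling(topFraction * nGenes)} ranks,
#' normalized by the maximal area attainable for this set size and
#' threshold, so scores lie in [0, 1]: 1 when the whole set occupies the
#' top ranks, 0 when no member enters the window. Being rank-based, the
#' score is invariant to any monotone transform of a cell's expression
#' values.
#'
#' @param counts cells x genes expression matrix (raw or normalized).
#' @param gene_set a [geneSet()]; members absent from the matrix are
#'   dropped with a warning, an empty intersection is an error.
#' @param topFraction fraction of the ranking integrated over; default
#'   0.05.
#' @param randomTies break expression ties at random (seeded by `seed`)
#'   instead of by gene order.
#' @param seed seed used when `randomTies`.
#' @return numeric vector of per-cell scores in [0, 1], named by cell id,
#'   with attributes `gene_set`, `top_fraction`, `n_set_genes_present`.
#' @export
aucellScore <- function(counts, gene_set, topFraction = 0.05,
                        randomTies = FALSE, seed = 1L) {
  stopifnot(topFraction > 0, topFraction < 1)
  genes <- colnames(counts)
  present <- intersect(gene_set$genes, genes)
  miss <- setdiff(gene_set$genes, genes)
  if (!length(present))
    stop("no genes of set '", gene_set$name, "' present in the matrix")
  if (length(miss))
    warning("gene set '", gene_set$name, "' members absent: ",
            paste(miss, collapse = ", "))
  G <- length(genes)
  k <- as.integer(ceiling(topFraction * G))
  nset <- length(present)
  maxAUC <- if (nset >= k) k * (k + 1) / 2 else
    nset * (nset + 1) / 2 + (k - nset) * nset
  isSet <- genes %in% present
  dense <- as.matrix(counts)
  if (randomTies) set.seed(childSeed(seed, 97L))
  scores <- vapply(seq_len(nrow(dense)), function(i) {
    x <- dense[i, ]
    tie <- if (randomTies) sample.int(G) else seq_len(G)
    ord <- order(-x, tie)
    r <- which(isSet[ord])          # ranks of the set genes
    r <- r[r <= k]
    sum(k - r + 1) / maxAUC
  }, numeric(1))
  names(scores) <- rownames(counts)
  attr(scores, "gene_set") <- gene_set$name
  attr(scores, "top_fraction") <- topFraction
  attr(scores, "n_set_genes_present") <- nset
  scores
}

#' Scaled module score along a given cell ordering
#'
#' Log-normalizes counts (library-size scaling to 10,000 followed by
#' log1p), z-scores each gene-set member across cells, averages the
#' z-scores per cell and min-max scales the result to [0, 1], returned in
#' the supplied cell order (e.g. a pseudotime ordering computed
#' elsewhere). Zero-variance genes are dropped from the mean with a
#' warning; if all cells tie, the min-max guard returns 0.5 everywhere.
#'
#' @param counts cells x genes count matrix.
#' @param gene_set a [geneSet()].
#' @param cellOrder permutation of the matrix's cell ids.
#' @return numeric vector of scores in [0, 1], named by cell id, in
#'   `cellOrder`.
#' @export
scaleModuleScore <- function(counts, gene_set, cellOrder = rownames(counts)) {
  if (!setequal(cellOrder, rownames(counts)) ||
      length(cellOrder) != nrow(counts))
    stop("cellOrder must be a permutation of the matrix's cells")
  present <- intersect(gene_set$genes, colnames(counts))
  if (!length(present))
    stop("no genes of set '", gene_set$name, "' present in the matrix")
  m <- as.matrix(counts[, present, drop = FALSE])
  lib <- Matrix::rowSums(counts)
  lib[lib == 0] <- 1
  norm <- log1p(m / lib * 1e4)
  sds <- apply(norm, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance gene(s) dropped: ",
            paste(present[sds == 0], collapse = ", "))
    norm <- norm[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  score <- if (ncol(norm)) rowMeans(scale(norm)) else
    rep(0, nrow(counts))
  rng <- range(score)
  scaled <- if (diff(rng) == 0) rep(0.5, length(score)) else
    (score - rng[1]) / diff(rng)
  names(scaled) <- rownames(counts)
  scaled[cellOrder]
}
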