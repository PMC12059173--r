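#' Per-cell quality-control metrics from a count matrix
#'
#' Computes, for every cell, the number of detected genes (count > 0), the
#' total UMI count and the percentage of counts falling on mitochondrial
#' genes.
#'
#' @param counts cells x genes matrix (dense or [Matrix::sparseMatrix()])
#'   of nonnegative integers with cell ids as rownames.
#' @param mitoGenes gene symbols treated as mitochondrial; defaults to the
#'   human convention of symbols prefixed "MT-". Symbols absent from the
#'   matrix trigger a warning.
#' @param doubletScores optional named numeric in `[0, 1]` (names = cell
#'   ids), e.g. Scrublet output computed upstream.
#' @return data.frame with columns `cell_id`, `n_genes`, `total_umi`,
#'   `pct_mito`, and `doublet_score` (NA when not supplied). `pct_mito` is 0
#'   for all-zero cells.
#' @export
computeCellQC <- function(counts, mitoGenes = NULL, doubletScores = NULL) {
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("empty count matrix")
  genes <- colnames(counts)
  if (is.null(mitoGenes)) mitoGenes <- grep("^MT-", genes, value = TRUE)
  miss <- setdiff(mitoGenes, genes)
  if (length(miss))
    warning("mitochondrial genes absent from matrix: ",
            paste(miss, collapse = ", "))
  mitoGenes <- intersect(mitoGenes, genes)
  total <- Matrix::rowSums(counts)
  nGenes <- Matrix::rowSums(counts > 0)
  mito <- if (length(mitoGenes))
    Matrix::rowSums(counts[, mitoGenes, drop = FALSE]) else rep(0, nrow(counts))
  pct <- ifelse(total > 0, 100 * mito / total, 0)
  ds <- rep(NA_real_, nrow(counts))
  if (!is.null(doubletScores)) {
    idx <- match(rownames(counts), names(doubletScores))
    ds <- as.numeric(doubletScores[idx])
  }
  data.frame(cell_id = rownames(counts), n_genes = as.integer(nGenes),
             total_umi = as.integer(total), pct_mito = as.numeric(pct),
             doublet_score = ds, stringsAsFactors = FALSE)
}

#' Apply per-cell quality filters
#'
#' Exclusion bounds are strict: cells with fewer than `minGenes` or more
#' than `maxGenes` detected genes, more than `maxPctMito` percent
#' mitochondrial counts, a total UMI count of more than `maxUmi`, or a
#' doublet score greater than `maxDoublet` are removed, so cells sitting
#' exactly on a threshold are kept. When all doublet scores are missing the
#' doublet rule is skipped with a warning.
#'
#' @param qc data.frame from [computeCellQC()].
#' @param minGenes,maxGenes,maxPctMito,maxUmi,maxDoublet thresholds;
#'   defaults 200, 4000, 20, 25000, 0.2.
#' @return list with `keep` (named logical mask), `report` (removals
#'   attributed to the first failing rule in the fixed order genes-low,
#'   genes-high, mito, umi, doublet) and `n_kept`.
#' @export
applyCellFilters <- function(qc, minGenes = 200, maxGenes = 4000,
                             maxPctMito = 20, maxUmi = 25000,
                             maxDoublet = 0.2) {
  assertColumns(qc, c("cell_id", "n_genes", "total_umi", "pct_mito"), "qc")
  stopifnot(minGenes > 0, maxGenes > 0, maxPctMito > 0, maxUmi > 0,
            maxDoublet > 0)
  useDoublet <- "doublet_score" %in% names(qc) &&
    any(!is.na(qc$doublet_score))
  if (!useDoublet)
    warning("no doublet scores available; doublet rule skipped")
  fails <- cbind(
    `genes-low` = qc$n_genes < minGenes,
    `genes-high` = qc$n_genes > maxGenes,
    mito = qc$pct_mito > maxPctMito,
    umi = qc$total_umi > maxUmi,
    doublet = if (useDoublet)
      !is.na(qc$doublet_score) & qc$doublet_score > maxDoublet
    else rep(FALSE, nrow(qc)))
  keep <- !apply(fails, 1L, any)
  names(keep) <- qc$cell_id
  firstFail <- apply(fails, 1L, function(z)
    if (any(z)) colnames(fails)[which(z)[1L]] else NA_character_)
  report <- table(factor(firstFail[!keep], levels = colnames(fails)))
  list(keep = keep, report = as.integer(report) |>
         stats::setNames(colnames(fails)), n_kept = sum(keep))
}

#' Remove genes detected in too few cells
#'
#' A gene is retained iff it has a nonzero count in at least `minCells`
#' cells ("fewer than three cells" are excluded by default, so a gene seen
#' in exactly three cells stays). Cells are untouched.
#'
#' @param counts cells x genes count matrix.
#' @param minCells minimum number of expressing cells; default 3.
#' @return the column-filtered matrix.
#' @export
applyGeneFilter <- function(counts, minCells = 3) {
  expressed <- Matrix::colSums(counts > 0)
  counts[, expressed >= minCells, drop = FALSE]
}

#' Run the full QC stage in the canonical order
#'
#' Gene filter first, then per-cell QC recomputed on the gene-filtered
#' matrix, then cell filters.
#'
#' @inheritParams computeCellQC
#' @inheritParams applyCellFilters
#' @param minCells gene filter threshold.
#' @param recomputeQC recompute `n_genes` after gene filtering (default
#'   TRUE); set FALSE to threshold on pre-filter gene counts.
#' @return list with `counts` (filtered matrix), `qc` (post-gene-filter QC
#'   table) and `filter` (the [applyCellFilters()] result).
#' @export
runQC <- function(counts, mitoGenes = NULL, doubletScores = NULL,
                  minCells = 3, minGenes = 200, maxGenes = 4000,
                  maxPctMito = 20, maxUmi = 25000, maxDoublet = 0.2,
                  recomputeQC = TRUE) {
  pre <- if (recomputeQC) NULL else
    computeCellQC(counts, mitoGenes, doubletScores)
  counts <- applyGeneFilter(counts, minCells)
  if (ncol(counts) == 0L)
    stop("gene filter removed every gene; nothing left to QC")
  qc <- if (recomputeQC)
    computeCellQC(counts, mitoGenes, doubletScores) else pre
  flt <- applyCellFilters(qc, minGenes, maxGenes, maxPctMito, maxUmi,
                          maxDoublet)
  list(counts = counts[flt$keep, , drop = FALSE], qc = qc, filter = flt)
}
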