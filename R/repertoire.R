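TR_LOCI <- c("TRA", "TRB")
IG_LOCI <- c("IGH", "IGK", "IGL")

#' Classify cells by receptor chain content
#'
#' Cells carrying chains of both receptor classes (any TR locus together
#' with any IG locus) are "ambiguous"; cells with more than two chains of
#' one paired arm (a third alpha or beta chain for T cells; a third heavy
#' or third light chain for B cells) are "multichain". Both categories are
#' excluded from clonotype calling. A secondary chain of one arm (two
#' total) is permitted. Duplicate (cell, locus, CDR3) records are
#' deduplicated with a warning.
#'
#' @param chains receptor table with columns `cell_id`, `locus`,
#'   `cdr3_nt`.
#' @return data.frame (`cell_id`, `receptor_class`) with class one of
#'   "TCR", "BCR", "ambiguous", "multichain".
#' @export
classifyCells <- function(chains) {
  assertColumns(chains, c("cell_id", "locus", "cdr3_nt"), "chains")
  bad <- !chains$locus %in% c(TR_LOCI, IG_LOCI)
  if (any(bad))
    stop("invalid locus value(s): ",
         paste(unique(chains$locus[bad]), collapse = ", "))
  dup <- duplicated(chains[, c("cell_id", "locus", "cdr3_nt")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (cell, locus, cdr3) records removed")
    chains <- chains[!dup, , drop = FALSE]
  }
  counts <- table(chains$cell_id, factor(chains$locus,
                                         levels = c(TR_LOCI, IG_LOCI)))
  nTR <- rowSums(counts[, TR_LOCI, drop = FALSE])
  nIG <- rowSums(counts[, IG_LOCI, drop = FALSE])
  armMax <- pmax(counts[, "TRA"], counts[, "TRB"], counts[, "IGH"],
                 counts[, "IGK"] + counts[, "IGL"])
  cls <- ifelse(nTR > 0 & nIG > 0, "ambiguous",
         ifelse(armMax > 2, "multichain",
         ifelse(nTR > 0, "TCR", "BCR")))
  data.frame(cell_id = rownames(counts), receptor_class = unname(cls),
             stringsAsFactors = FALSE)
}

dedupeChains <- function(chains) {
  chains[!duplicated(chains[, c("cell_id", "locus", "cdr3_nt")]), ,
         drop = FALSE]
}

#' Define TCR clonotypes by exact paired CDR3 nucleotide identity
#'
#' The clonotype key of a cell is the sorted set of its TRA CDR3
#' nucleotide sequences together with the sorted set of its TRB CDR3s;
#' cells share a clonotype iff both arms match exactly. Cells carrying only
#' one arm form single-arm keys that never merge with paired keys. Only
#' cells classified "TCR" receive a clonotype.
#'
#' @param chains receptor table (see [classifyCells()]).
#' @return a [ClonotypeAssignment-class].
#' @export
defineTcrClonotypes <- function(chains) {
  cls <- classifyCells(chains)
  chains <- dedupeChains(chains)
  tcrCells <- cls$cell_id[cls$receptor_class == "TCR"]
  sub <- chains[chains$cell_id %in% tcrCells, , drop = FALSE]
  keys <- vapply(split(sub, sub$cell_id), function(d) {
    paste0("TRA:", paste(sort(d$cdr3_nt[d$locus == "TRA"]), collapse = "+"),
           "|TRB:", paste(sort(d$cdr3_nt[d$locus == "TRB"]), collapse = "+"))
  }, character(1))
  uk <- unique(keys)
  ids <- stats::setNames(sprintf("tcr_ct%05d", seq_along(uk)), uk)
  cellDf <- data.frame(cell_id = cls$cell_id,
                       receptor_class = cls$receptor_class,
                       clonotype_id = NA_character_,
                       stringsAsFactors = FALSE)
  cellDf$clonotype_id[match(names(keys), cellDf$cell_id)] <-
    unname(ids[keys])
  sizes <- table(cellDf$clonotype_id)
  methods::new("ClonotypeAssignment", cells = cellDf,
               cloneSizes = stats::setNames(as.integer(sizes), names(sizes)),
               receptor = "TCR")
}

firstGeneCall <- function(x) sub("[,;].*$", "", x)

heavyChainTable <- function(chains) {
  cls <- classifyCells(chains)
  chains <- dedupeChains(chains)
  bcr <- cls$cell_id[cls$receptor_class == "BCR"]
  h <- chains[chains$locus == "IGH" & chains$cell_id %in% bcr, ,
              drop = FALSE]
  h <- h[!duplicated(h$cell_id), , drop = FALSE]   # one heavy chain per cell
  assertColumns(h, c("v_gene", "j_gene"), "heavy chains")
  h$partition <- paste(firstGeneCall(h$v_gene), firstGeneCall(h$j_gene),
                       nchar(h$cdr3_nt), sep = "|")
  h
}

#' Data-driven clonal distance threshold for BCR clustering
#'
#' Computes every heavy chain's normalized Hamming distance to its nearest
#' non-identical neighbour within (V gene, J gene, junction length)
#' partitions, then locates the density valley between the two main modes
#' of that distribution: small distances come from clonally related
#' sequences, large ones from unrelated sequences in the same partition.
#' Falls back to `fallback` with a warning when too few heavy chains are
#' available or the distribution shows no second mode.
#'
#' @param chains receptor table.
#' @param fallback threshold used when no valley can be found; default
#'   0.15.
#' @param minChains minimum number of heavy chains required; default 20.
#' @return a scalar threshold in (0, 1), with attribute `"fallback"` TRUE
#'   when the default was returned.
#' @export
estimateBcrThreshold <- function(chains, fallback = 0.15, minChains = 20L) {
  h <- heavyChainTable(chains)
  fb <- function(msg) {
    warning(msg, "; falling back to threshold ", fallback)
    structure(fallback, fallback = TRUE)
  }
  if (nrow(h) < minChains)
    return(fb(sprintf("only %d heavy chains (< %d)", nrow(h), minChains)))
  dists <- unlist(lapply(split(h$cdr3_nt, h$partition), function(seqs) {
    u <- unique(seqs)            # multiplicity must not move the threshold
    if (length(u) < 2L) return(numeric(0))
    d <- as.matrix(hammingDistMatrix(u))
    diag(d) <- Inf
    apply(d, 1L, min)
  }), use.names = FALSE)
  if (length(dists) < 5L)
    return(fb("not enough nearest-neighbor distances"))
  den <- stats::density(dists, from = 0, to = 1, n = 512)
  y <- den$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) < 2L)
    return(fb("nearest-neighbor distance distribution is unimodal"))
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valleyIdx <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  structure(den$x[valleyIdx], fallback = FALSE)
}

#' Define BCR clonotypes by heavy-junction clustering within V/J/length partitions
#'
#' Within each partition sharing the same heavy-chain V gene, J gene and
#' junction length (ambiguous multi-gene calls resolved to the first
#' listed gene), performs single-linkage hierarchical clustering on the
#' normalized Hamming distances between heavy-chain junction sequences and
#' cuts the dendrogram at `threshold`; each resulting cluster is one
#' clonotype. Light chains do not enter the distance. Only cells
#' classified "BCR" with a heavy chain receive a clonotype.
#'
#' @param chains receptor table.
#' @param threshold normalized distance cut in (0, 1]; typically from
#'   [estimateBcrThreshold()]. At 0, clonotypes are exact-junction
#'   identity classes; at 1, each partition collapses to one clonotype.
#' @return a [ClonotypeAssignment-class].
#' @export
defineBcrClonotypes <- function(chains, threshold = 0.15) {
  stopifnot(threshold >= 0, threshold <= 1)
  cls <- classifyCells(chains)
  h <- heavyChainTable(chains)
  cellDf <- data.frame(cell_id = cls$cell_id,
                       receptor_class = cls$receptor_class,
                       clonotype_id = NA_character_,
                       stringsAsFactors = FALSE)
  ctr <- 0L
  for (part in split(h, h$partition)) {
    u <- unique(part$cdr3_nt)
    if (length(u) == 1L) {
      grp <- stats::setNames(1L, u)
    } else {
      hc <- stats::hclust(hammingDistMatrix(u), method = "single")
      grp <- stats::setNames(stats::cutree(hc, h = threshold), u)
    }
    ids <- sprintf("bcr_ct%05d", ctr + grp[part$cdr3_nt])
    ctr <- ctr + max(grp)
    cellDf$clonotype_id[match(part$cell_id, cellDf$cell_id)] <- ids
  }
  sizes <- table(cellDf$clonotype_id)
  methods::new("ClonotypeAssignment", cells = cellDf,
               cloneSizes = stats::setNames(as.integer(sizes), names(sizes)),
               receptor = "BCR")
}

#' Clonal diversity of a cell group: Shannon entropy and D50
#'
#' With \eqn{p_i} the fraction of the group's assigned cells carried by
#' clonotype i, Shannon entropy is \eqn{-\sum_i p_i \log p_i} (natural log
#' by default) and D50 is 100 times the smallest number of clonotypes,
#' taken in descending size order, whose cumulative cell fraction reaches
#' 0.5, divided by the number of clonotypes. A monoclonal group scores
#' entropy 0 and D50 100 x 1/1 = 100.
#'
#' @param assignment a [ClonotypeAssignment-class].
#' @param cellIds optional subset of cell ids defining the group; default
#'   all assigned cells.
#' @param group label for the output row.
#' @param base logarithm base for the entropy; default `exp(1)` (nats).
#' @return data.frame (`group`, `shannon`, `d50`, `n_cells`,
#'   `n_clonotypes`).
#' @export
clonalDiversity <- function(assignment, cellIds = NULL, group = "all",
                            base = exp(1)) {
  stopifnot(is(assignment, "ClonotypeAssignment"))
  tab <- assignment@cells
  tab <- tab[!is.na(tab$clonotype_id), , drop = FALSE]
  if (!is.null(cellIds)) tab <- tab[tab$cell_id %in% cellIds, , drop = FALSE]
  if (!nrow(tab)) stop("no assigned cells in group '", group, "'")
  sizes <- sort(as.integer(table(tab$clonotype_id)), decreasing = TRUE)
  p <- sizes / sum(sizes)
  shannon <- -sum(p * log(p, base = base))
  k <- which(cumsum(p) >= 0.5)[1L]    # first index reaching half the cells
  data.frame(group = group, shannon = shannon,
             d50 = 100 * k / length(sizes),
             n_cells = sum(sizes), n_clonotypes = length(sizes),
             stringsAsFactors = FALSE)
}

#' Clonotype sharing between cell clusters
#'
#' Entry (i, j) counts clonotypes having at least one cell in cluster i
#' and at least one in cluster j; the diagonal counts clonotypes present
#' in each cluster. When the cell table carries a `tls_status` column, a
#' per-status decomposition (same count restricted to cells of one
#' status) is included.
#'
#' @param assignment a [ClonotypeAssignment-class].
#' @param cells cell table with `cell_id` and the cluster column.
#' @param clusterCol name of the cluster column; default "subcluster".
#' @return a [SharingMatrix-class].
#' @export
sharingMatrix <- function(assignment, cells, clusterCol = "subcluster") {
  stopifnot(is(assignment, "ClonotypeAssignment"))
  assertColumns(cells, c("cell_id", clusterCol), "cells")
  tab <- assignment@cells
  tab <- tab[!is.na(tab$clonotype_id), , drop = FALSE]
  idx <- match(tab$cell_id, cells$cell_id)
  tab$cluster <- cells[[clusterCol]][idx]
  if ("tls_status" %in% names(cells))
    tab$tls_status <- cells$tls_status[idx]
  tab <- tab[!is.na(tab$cluster), , drop = FALSE]
  clusters <- sort(unique(cells[[clusterCol]]))
  countFrom <- function(d) {
    inc <- table(d$clonotype_id, factor(d$cluster, levels = clusters)) > 0
    m <- t(inc) %*% inc
    storage.mode(m) <- "integer"
    m
  }
  counts <- countFrom(tab)
  byStatus <- list()
  if ("tls_status" %in% names(cells)) {
    for (s in unique(stats::na.omit(tab$tls_status)))
      byStatus[[s]] <- countFrom(tab[tab$tls_status == s, , drop = FALSE])
  }
  methods::new("SharingMatrix", counts = counts, byStatus = byStatus)
}

#' Fraction of clonotypes shared between two cluster groups
#'
#' Numerator: clonotypes (restricted to expanded ones, clone size >= 2,
#' when `expandedOnly`) with at least one cell in a `groupA` cluster and
#' at least one in a `groupB` cluster. Denominator: clonotypes (same
#' expansion filter) with at least one cell in either group. Computed per
#' grouping unit (per sample by default); an empty denominator yields NA.
#' Clone size is counted over all assigned cells, regardless of cluster.
#'
#' @param assignment a [ClonotypeAssignment-class].
#' @param cells cell table with `cell_id`, the cluster column and the
#'   `by` column.
#' @param groupA,groupB disjoint sets of cluster labels.
#' @param expandedOnly restrict to clone size >= 2; default TRUE.
#' @param clusterCol cluster column; default "subcluster".
#' @param by unit column ("sample_id" default) or NULL to pool everything.
#' @return data.frame (`unit`, `n_shared`, `n_total`, `fraction`).
#' @export
sharedFeatureFraction <- function(assignment, cells, groupA, groupB,
                                  expandedOnly = TRUE,
                                  clusterCol = "subcluster",
                                  by = "sample_id") {
  stopifnot(is(assignment, "ClonotypeAssignment"))
  if (length(intersect(groupA, groupB)))
    stop("groupA and groupB must be disjoint")
  assertColumns(cells, c("cell_id", clusterCol), "cells")
  tab <- assignment@cells
  tab <- tab[!is.na(tab$clonotype_id), , drop = FALSE]
  idx <- match(tab$cell_id, cells$cell_id)
  tab$cluster <- cells[[clusterCol]][idx]
  if (!is.null(by)) {
    assertColumns(cells, by, "cells")
    tab$unit <- cells[[by]][idx]
  } else tab$unit <- "pooled"
  if (expandedOnly) {
    keep <- names(assignment@cloneSizes)[assignment@cloneSizes >= 2L]
    tab <- tab[tab$clonotype_id %in% keep, , drop = FALSE]
  }
  tab <- tab[tab$cluster %in% c(groupA, groupB), , drop = FALSE]
  out <- lapply(split(tab, tab$unit), function(d) {
    inA <- unique(d$clonotype_id[d$cluster %in% groupA])
    inB <- unique(d$clonotype_id[d$cluster %in% groupB])
    tot <- union(inA, inB)
    data.frame(unit = d$unit[1L], n_shared = length(intersect(inA, inB)),
               n_total = length(tot),
               fraction = if (length(tot)) length(intersect(inA, inB)) /
                 length(tot) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
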