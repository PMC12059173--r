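#' Spot-level co-occurrence score of two cell types
#'
#' With \eqn{C_{ij}} the predicted abundance of type i in spot j over N
#' spots, the co-occurrence score of types A and B is
#' \deqn{\mathrm{score}_{AB} = \frac{\sum_{j=1}^{N} C_{Aj} C_{Bj}}{N}
#' \times 1000.}
#' Abundances are used exactly as provided; spots with all-zero abundance
#' still count in N. Set `compositional = TRUE` to row-normalize each spot
#' to proportions first (sensitivity mode).
#'
#' @param abund spots x cell-types matrix of nonnegative abundances with
#'   type labels as colnames.
#' @param a,b cell-type labels.
#' @param compositional row-normalize spots before scoring.
#' @return the scalar score.
#' @export
cooccurrenceScore <- function(abund, a, b, compositional = FALSE) {
  abund <- as.matrix(abund)
  for (ty in c(a, b))
    if (!ty %in% colnames(abund))
      stop("unknown cell type: ", ty)
  if (nrow(abund) < 1L) stop("need at least one spot")
  if (compositional) abund <- normalizeSpots(abund)
  sum(abund[, a] * abund[, b]) / nrow(abund) * 1000
}

normalizeSpots <- function(abund) {
  tot <- rowSums(abund)
  tot[tot == 0] <- 1
  abund / tot
}

#' All pairwise co-occurrence scores
#'
#' Computes the full symmetric type x type score matrix in one quadratic
#' form, \eqn{C^\top C / N \times 1000}; the diagonal holds each type's
#' self score.
#'
#' @inheritParams cooccurrenceScore
#' @return symmetric numeric matrix over the cell types.
#' @export
cooccurrenceMatrix <- function(abund, compositional = FALSE) {
  abund <- as.matrix(abund)
  if (ncol(abund) < 2L) stop("need at least two cell types")
  if (compositional) abund <- normalizeSpots(abund)
  crossprod(abund) / nrow(abund) * 1000
}

#' Long-format export of a co-occurrence matrix
#'
#' @param m matrix from [cooccurrenceMatrix()].
#' @return data.frame (`type_a`, `type_b`, `score`) including the
#'   diagonal, heatmap-ready.
#' @export
cooccurrenceToLong <- function(m) {
  data.frame(type_a = rep(rownames(m), times = ncol(m)),
             type_b = rep(colnames(m), each = nrow(m)),
             score = as.vector(m), stringsAsFactors = FALSE)
}
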