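#' @import methods
NULL

#' DensityGrid: a 2-D kernel density estimate on a regular grid
#'
#' Holds a product-Gaussian kernel density estimate of a set of embedding
#' coordinates, evaluated on a regular rectangular grid. The density is a
#' proper density over the plane (integrates to 1); the grid window captures
#' most but not necessarily all of its mass.
#'
#' @slot gridX,gridY strictly increasing grid node coordinates.
#' @slot density matrix of nonnegative density values,
#'   \code{length(gridX) x length(gridY)}.
#' @slot bandwidth named numeric of length 2, Gaussian kernel standard
#'   deviations per axis.
#' @slot nPoints number of points the estimate was computed from.
#'
#' @seealso [estimateDensity2d()], [densityContrast()]
#' @exportClass DensityGrid
setClass("DensityGrid",
  representation(
    gridX = "numeric",
    gridY = "numeric",
    density = "matrix",
    bandwidth = "numeric",
    nPoints = "integer"
  )
)

setValidity("DensityGrid", function(object) {
  msg <- character()
  if (any(diff(object@gridX) <= 0) || any(diff(object@gridY) <= 0))
    msg <- c(msg, "grid coordinates must be strictly increasing")
  if (!identical(dim(object@density),
                 c(length(object@gridX), length(object@gridY))))
    msg <- c(msg, "density dimensions must match grid lengths")
  if (any(object@density < 0))
    msg <- c(msg, "density must be nonnegative")
  if (length(object@bandwidth) != 2L || any(object@bandwidth <= 0))
    msg <- c(msg, "bandwidth must be two positive values")
  if (length(msg)) msg else TRUE
})

#' ContrastGrid: node-wise difference of two DensityGrid objects
#'
#' @slot gridX,gridY grid node coordinates shared by both input grids.
#' @slot contrast matrix of density differences (first minus second status).
#' @slot statusPair the ordered pair of group labels contrasted.
#' @slot bandwidth the common kernel bandwidth of the two inputs.
#'
#' @seealso [densityContrast()]
#' @exportClass ContrastGrid
setClass("ContrastGrid",
  representation(
    gridX = "numeric",
    gridY = "numeric",
    contrast = "matrix",
    statusPair = "character",
    bandwidth = "numeric"
  )
)

setValidity("ContrastGrid", function(object) {
  msg <- character()
  if (!identical(dim(object@contrast),
                 c(length(object@gridX), length(object@gridY))))
    msg <- c(msg, "contrast dimensions must match grid lengths")
  if (length(object@statusPair) != 2L)
    msg <- c(msg, "statusPair must name exactly two groups")
  if (length(msg)) msg else TRUE
})

#' ClonotypeAssignment: the clonotype partition of a receptor repertoire
#'
#' Per-cell receptor classification together with the clonotype each
#' QC-passing cell was assigned to. Cells classified as ambiguous (both TCR
#' and BCR chains) or multichain (more than two chains of one paired arm)
#' carry no clonotype.
#'
#' @slot cells data.frame with columns \code{cell_id},
#'   \code{receptor_class} (one of TCR, BCR, ambiguous, multichain, none)
#'   and \code{clonotype_id} (NA for unassigned cells).
#' @slot cloneSizes named integer vector, cells per clonotype.
#' @slot receptor which receptor class the partition covers ("TCR" or "BCR").
#'
#' @seealso [defineTcrClonotypes()], [defineBcrClonotypes()],
#'   [clonalDiversity()], [sharingMatrix()]
#' @exportClass ClonotypeAssignment
setClass("ClonotypeAssignment",
  representation(
    cells = "data.frame",
    cloneSizes = "integer",
    receptor = "character"
  )
)

setValidity("ClonotypeAssignment", function(object) {
  msg <- character()
  need <- c("cell_id", "receptor_class", "clonotype_id")
  if (!all(need %in% names(object@cells)))
    msg <- c(msg, paste("cells must have columns:", paste(need, collapse = ", ")))
  else {
    assigned <- !is.na(object@cells$clonotype_id)
    if (sum(object@cloneSizes) != sum(assigned))
      msg <- c(msg, "clone sizes must sum to the number of assigned cells")
    bad <- object@cells$receptor_class %in% c("ambiguous", "multichain") & assigned
    if (any(bad))
      msg <- c(msg, "ambiguous/multichain cells must not carry a clonotype")
  }
  if (length(msg)) msg else TRUE
})

#' SharingMatrix: clonotype sharing between cell clusters
#'
#' Symmetric count matrix whose (i, j) entry is the number of clonotypes with
#' at least one cell in cluster i and at least one cell in cluster j; the
#' diagonal counts clonotypes present in each cluster. A per-TLS-status
#' decomposition restricts the count to cells of each status.
#'
#' @slot counts symmetric integer matrix over cluster labels.
#' @slot byStatus named list of per-status sharing matrices.
#'
#' @seealso [sharingMatrix()]
#' @exportClass SharingMatrix
setClass("SharingMatrix",
  representation(
    counts = "matrix",
    byStatus = "list"
  )
)

setValidity("SharingMatrix", function(object) {
  msg <- character()
  if (!isSymmetric(unname(object@counts)))
    msg <- c(msg, "counts must be symmetric")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

# ---- accessors ----

#' @describeIn DensityGrid grid x coordinates
#' @param object a DensityGrid/ContrastGrid
#' @export
setGeneric("gridX", function(object) standardGeneric("gridX"))
#' @describeIn DensityGrid grid y coordinates
#' @export
setGeneric("gridY", function(object) standardGeneric("gridY"))
#' @describeIn DensityGrid density value matrix
#' @export
setGeneric("densityValues", function(object) standardGeneric("densityValues"))
#' @describeIn DensityGrid per-axis kernel standard deviations
#' @export
setGeneric("bandwidth", function(object) standardGeneric("bandwidth"))
#' @describeIn ContrastGrid contrast value matrix
#' @param object a ContrastGrid
#' @export
setGeneric("contrastValues", function(object) standardGeneric("contrastValues"))
#' @describeIn ClonotypeAssignment named clone-size vector
#' @param object a ClonotypeAssignment
#' @export
setGeneric("cloneSizes", function(object) standardGeneric("cloneSizes"))
#' @describeIn ClonotypeAssignment per-cell classification and assignment table
#' @export
setGeneric("assignedCells", function(object) standardGeneric("assignedCells"))
#' @describeIn SharingMatrix shared-clonotype count matrix
#' @param object a SharingMatrix
#' @export
setGeneric("sharingCounts", function(object) standardGeneric("sharingCounts"))
#' @describeIn SharingMatrix per-status sharing matrices
#' @export
setGeneric("sharingByStatus", function(object) standardGeneric("sharingByStatus"))

setMethod("gridX", "DensityGrid", function(object) object@gridX)
setMethod("gridY", "DensityGrid", function(object) object@gridY)
setMethod("densityValues", "DensityGrid", function(object) object@density)
setMethod("bandwidth", "DensityGrid", function(object) object@bandwidth)
setMethod("gridX", "ContrastGrid", function(object) object@gridX)
setMethod("gridY", "ContrastGrid", function(object) object@gridY)
setMethod("contrastValues", "ContrastGrid", function(object) object@contrast)
setMethod("bandwidth", "ContrastGrid", function(object) object@bandwidth)
setMethod("cloneSizes", "ClonotypeAssignment", function(object) object@cloneSizes)
setMethod("assignedCells", "ClonotypeAssignment", function(object) object@cells)
setMethod("sharingCounts", "SharingMatrix", function(object) object@counts)
setMethod("sharingByStatus", "SharingMatrix", function(object) object@byStatus)

# ---- show ----

setMethod("show", "DensityGrid", function(object) {
  cat("DensityGrid:", length(object@gridX), "x", length(object@gridY),
      "nodes over", object@nPoints, "points\n")
  cat("  bandwidth:", format(object@bandwidth, digits = 4), "\n")
  cat("  x range: [", format(min(object@gridX), digits = 4), ",",
      format(max(object@gridX), digits = 4), "]  y range: [",
      format(min(object@gridY), digits = 4), ",",
      format(max(object@gridY), digits = 4), "]\n")
})

setMethod("show", "ContrastGrid", function(object) {
  cat("ContrastGrid:", object@statusPair[1], "vs", object@statusPair[2],
      "on", length(object@gridX), "x", length(object@gridY), "nodes\n")
  cat("  contrast range: [", format(min(object@contrast), digits = 4), ",",
      format(max(object@contrast), digits = 4), "]\n")
})

setMethod("show", "ClonotypeAssignment", function(object) {
  tab <- table(object@cells$receptor_class)
  cat("ClonotypeAssignment (", object@receptor, "): ",
      nrow(object@cells), " cells, ", length(object@cloneSizes),
      " clonotypes\n", sep = "")
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (length(object@cloneSizes))
    cat("  expanded clonotypes (size >= 2):",
        sum(object@cloneSizes >= 2L), "\n")
})

setMethod("show", "SharingMatrix", function(object) {
  cat("SharingMatrix over", nrow(object@counts), "clusters;",
      "statuses:", paste(names(object@byStatus), collapse = ", "), "\n")
  print(object@counts)
})
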