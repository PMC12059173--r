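#' Product-Gaussian 2-D kernel density estimate on a regular grid
#'
#' Evaluates the density \eqn{\hat f(x, y) = n^{-1} \sum_i \phi_{h_x}(x -
#' x_i)\, \phi_{h_y}(y - y_i)} at every node of a regular grid, where
#' \eqn{\phi_h} is the Gaussian density with standard deviation h. The
#' estimate integrates to 1 over the plane; the grid window only truncates
#' where it is evaluated.
#'
#' @param points matrix or data.frame of embedding coordinates (columns x,
#'   y or the first two columns).
#' @param gridBounds optional `c(xmin, xmax, ymin, ymax)`; default the
#'   bounding box of the points padded by 3 bandwidths per axis.
#' @param nGrid nodes per axis (scalar or length 2); default 100.
#' @param bandwidth optional `c(hx, hy)` kernel standard deviations;
#'   default the normal reference rule ([stats::bw.nrd()]) per axis. A
#'   zero-variance axis falls back to a small fixed bandwidth with a
#'   warning.
#' @return a [DensityGrid-class].
#' @export
estimateDensity2d <- function(points, gridBounds = NULL, nGrid = 100L,
                              bandwidth = NULL) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 1L) stop("need at least one point")
  if (anyNA(pts)) stop("points contain missing coordinates")
  if (length(nGrid) == 1L) nGrid <- rep(as.integer(nGrid), 2L)
  if (is.null(bandwidth)) {
    bandwidth <- vapply(1:2, function(j) {
      v <- pts[, j]
      if (length(v) < 2L || stats::sd(v) == 0) {
        warning("degenerate axis ", j, "; using fixed minimal bandwidth")
        return(diff(range(v)) / 10 + 1e-3)
      }
      stats::bw.nrd(v)
    }, numeric(1))
  }
  stopifnot(length(bandwidth) == 2L, all(bandwidth > 0))
  if (is.null(gridBounds)) {
    gridBounds <- c(min(pts[, 1]) - 3 * bandwidth[1],
                    max(pts[, 1]) + 3 * bandwidth[1],
                    min(pts[, 2]) - 3 * bandwidth[2],
                    max(pts[, 2]) + 3 * bandwidth[2])
  }
  gx <- seq(gridBounds[1], gridBounds[2], length.out = nGrid[1])
  gy <- seq(gridBounds[3], gridBounds[4], length.out = nGrid[2])
  # nx x n and ny x n kernel matrices; density = their cross product / n
  Ax <- matrix(stats::dnorm(outer(gx, pts[, 1], "-"), sd = bandwidth[1]),
               nrow = length(gx))
  Ay <- matrix(stats::dnorm(outer(gy, pts[, 2], "-"), sd = bandwidth[2]),
               nrow = length(gy))
  dens <- (Ax %*% t(Ay)) / nrow(pts)
  dens[dens < 0] <- 0
  methods::new("DensityGrid", gridX = gx, gridY = gy, density = dens,
               bandwidth = stats::setNames(as.numeric(bandwidth),
                                           c("hx", "hy")),
               nPoints = nrow(pts))
}

#' Node-wise contrast of two density grids
#'
#' Subtracts the second group's density from the first on their common
#' grid. With both densities normalized to unit mass (the default output of
#' [estimateDensity2d()]) the contrast compares distribution shape rather
#' than cell abundance; set `weighted = TRUE` to weight each density by its
#' point count instead.
#'
#' @param a,b [DensityGrid-class] objects on identical grids with identical
#'   bandwidths.
#' @param statusPair labels for the pair, default `c("A", "B")`.
#' @param weighted multiply each density by its number of points.
#' @return a [ContrastGrid-class] with `contrast = a - b`.
#' @export
densityContrast <- function(a, b, statusPair = c("A", "B"),
                            weighted = FALSE) {
  stopifnot(is(a, "DensityGrid"), is(b, "DensityGrid"))
  if (!isTRUE(all.equal(a@gridX, b@gridX, tolerance = 0)) ||
      !isTRUE(all.equal(a@gridY, b@gridY, tolerance = 0)))
    stop("density grids do not match")
  if (!isTRUE(all.equal(unname(a@bandwidth), unname(b@bandwidth),
                        tolerance = 0)))
    stop("bandwidths do not match")
  da <- a@density; db <- b@density
  if (weighted) {
    da <- da * a@nPoints
    db <- db * b@nPoints
  }
  methods::new("ContrastGrid", gridX = a@gridX, gridY = a@gridY,
               contrast = da - db, statusPair = as.character(statusPair),
               bandwidth = a@bandwidth)
}

#' Per-status density grids and all pairwise contrasts on a shared grid
#'
#' Computes one density per status on a common grid (bounding box of the
#' pooled embedding padded by 3 bandwidths; bandwidth from the normal
#' reference rule on the pooled embedding so all statuses share one
#' smoothing scale) and the contrast for every ordered status pair.
#'
#' @param cells cell table with embedding columns and `tls_status`.
#' @param dims names of the two embedding columns; default
#'   `c("dim1", "dim2")`.
#' @param group optional column to facet by (e.g. subcluster); when given,
#'   a list of results per group level is returned.
#' @param nGrid grid nodes per axis.
#' @return list with `densities` (named list of [DensityGrid-class]) and
#'   `contrasts` (named list of [ContrastGrid-class], names "A_vs_B"), or a
#'   list of such lists when `group` is given.
#' @export
statusDensityMaps <- function(cells, dims = c("dim1", "dim2"),
                              group = NULL, nGrid = 100L) {
  assertColumns(cells, c(dims, "tls_status"), "cells")
  if (!is.null(group)) {
    assertColumns(cells, group, "cells")
    return(lapply(split(cells, cells[[group]]), statusDensityMaps,
                  dims = dims, group = NULL, nGrid = nGrid))
  }
  pts <- as.matrix(cells[, dims])
  bw <- c(stats::bw.nrd(pts[, 1]), stats::bw.nrd(pts[, 2]))
  bounds <- c(min(pts[, 1]) - 3 * bw[1], max(pts[, 1]) + 3 * bw[1],
              min(pts[, 2]) - 3 * bw[2], max(pts[, 2]) + 3 * bw[2])
  statuses <- intersect(c(tlsStatuses(), unique(cells$tls_status)),
                        unique(cells$tls_status))
  dens <- lapply(statuses, function(s)
    estimateDensity2d(pts[cells$tls_status == s, , drop = FALSE],
                      gridBounds = bounds, nGrid = nGrid, bandwidth = bw))
  names(dens) <- statuses
  contrasts <- list()
  for (i in seq_along(statuses)) for (j in seq_along(statuses)) {
    if (i == j) next
    nm <- paste0(statuses[i], "_vs_", statuses[j])
    contrasts[[nm]] <- densityContrast(dens[[i]], dens[[j]],
                                       c(statuses[i], statuses[j]))
  }
  list(densities = dens, contrasts = contrasts)
}

#' Long-format export of a density or contrast grid
#'
#' @param grid a [DensityGrid-class] or [ContrastGrid-class].
#' @return data.frame with columns `x`, `y`, `value`.
#' @export
gridToLong <- function(grid) {
  vals <- if (is(grid, "DensityGrid")) grid@density else grid@contrast
  data.frame(x = rep(grid@gridX, times = length(grid@gridY)),
             y = rep(grid@gridY, each = length(grid@gridX)),
             value = as.vector(vals))
}
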