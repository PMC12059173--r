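#' Pairwise Euclidean distance matrix of a point pattern
#'
#' @param points data.frame with `x` and `y` coordinates (microns) and
#'   optionally `cell_id` used as dimnames.
#' @return symmetric distance matrix with zero diagonal.
#' @export
pairwiseDistances <- function(points) {
  assertColumns(points, c("x", "y"), "points")
  if (nrow(points) < 2L) stop("need at least two cells")
  d <- as.matrix(stats::dist(cbind(points$x, points$y)))
  if ("cell_id" %in% names(points))
    dimnames(d) <- list(points$cell_id, points$cell_id)
  d
}

#' Nearest-neighbour distances from one phenotype to another
#'
#' For each cell of phenotype `from`, the minimum Euclidean distance to
#' any cell of phenotype `to`. When `from == to` a cell is excluded as its
#' own neighbour by cell id, so coincident distinct cells still count at
#' distance 0. Note the statistic is directional: nn(A to B) need not
#' equal nn(B to A).
#'
#' @param points data.frame with `x`, `y`, `phenotype` and (for
#'   self-exclusion) `cell_id`.
#' @param from,to phenotype labels.
#' @return numeric vector of distances in input order of the `from`
#'   cells, named by cell id when available; length 0 (flagged via
#'   attribute `"missing_phenotype"`) when either phenotype is absent, and
#'   NA for a `from` cell with no eligible neighbour.
#' @export
nnDistance <- function(points, from, to) {
  assertColumns(points, c("x", "y", "phenotype"), "points")
  fromIdx <- which(points$phenotype == from)
  toIdx <- which(points$phenotype == to)
  if (!length(fromIdx) || !length(toIdx)) {
    out <- numeric(0)
    attr(out, "missing_phenotype") <- setdiff(c(from, to),
                                              unique(points$phenotype))
    return(out)
  }
  ids <- if ("cell_id" %in% names(points)) points$cell_id else
    as.character(seq_len(nrow(points)))
  fx <- points$x[fromIdx]; fy <- points$y[fromIdx]
  tx <- points$x[toIdx]; ty <- points$y[toIdx]
  res <- vapply(seq_along(fromIdx), function(i) {
    dd <- sqrt((tx - fx[i])^2 + (ty - fy[i])^2)
    dd[ids[toIdx] == ids[fromIdx[i]]] <- Inf   # self-exclusion by id
    m <- min(dd)
    if (is.infinite(m)) NA_real_ else m
  }, numeric(1))
  names(res) <- ids[fromIdx]
  res
}

#' Nearest-neighbour proximity summaries per core and phenotype pair
#'
#' For every tissue core and every (from, to) phenotype pair, computes the
#' distribution of nearest-neighbour distances and its median. A core
#' missing either phenotype still yields a row, with missing median, so
#' dropout is visible. Medians can then be compared across TLS statuses.
#'
#' @param points point table (`core_id`, `tls_status`, `cell_id`, `x`,
#'   `y`, `phenotype`), one row per cell, possibly many cores.
#' @param pairs data.frame with columns `from`, `to`.
#' @param pool also return status-level medians pooled over all
#'   per-cell distances of a status (default FALSE: per-core medians
#'   only).
#' @return data.frame (`core_id`, `tls_status`, `from`, `to`, `n_from`,
#'   `n_to`, `median_nn`); with `pool = TRUE`, the pooled per-status rows
#'   are appended with `core_id = "pooled"`.
#' @export
proximitySummary <- function(points, pairs, pool = FALSE) {
  assertColumns(points, c("core_id", "tls_status", "x", "y", "phenotype"),
                "points")
  assertColumns(pairs, c("from", "to"), "pairs")
  rows <- list()
  pooled <- list()
  for (core in unique(points$core_id)) {
    sub <- points[points$core_id == core, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      dd <- nnDistance(sub, pairs$from[r], pairs$to[r])
      key <- paste(sub$tls_status[1L], pairs$from[r], pairs$to[r],
                   sep = "\r")
      pooled[[key]] <- c(pooled[[key]], dd)
      rows[[length(rows) + 1L]] <- data.frame(
        core_id = core, tls_status = sub$tls_status[1L],
        from = pairs$from[r], to = pairs$to[r],
        n_from = sum(sub$phenotype == pairs$from[r]),
        n_to = sum(sub$phenotype == pairs$to[r]),
        median_nn = if (length(dd)) stats::median(dd, na.rm = TRUE) else
          NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (pool && length(pooled)) {
    extra <- do.call(rbind, lapply(names(pooled), function(key) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      data.frame(core_id = "pooled", tls_status = parts[1],
                 from = parts[2], to = parts[3],
                 n_from = NA_integer_, n_to = NA_integer_,
                 median_nn = if (length(pooled[[key]]))
                   stats::median(pooled[[key]], na.rm = TRUE) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    out <- rbind(out, extra)
  }
  rownames(out) <- NULL
  out
}
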