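#' Per-cluster compositional enrichment between two TLS statuses
#'
#' Fits a one-vs-rest binomial-logit model of cluster membership with TLS
#' status as the sole factor, over the cells of the two statuses in
#' `contrast`, and reports the estimated-marginal-mean contrast on the
#' logit scale as a log2 odds ratio with Wald standard error and two-sided
#' p-value. With one factor this model is saturated, so the estimate equals
#' the closed-form 2x2 contingency odds ratio.
#'
#' When the cluster is empty (or exhaustive) in one status the 2x2 table
#' has a zero cell; 0.5 is then added to all four counts
#' (Haldane-Anscombe) and the Wald statistics are computed from the
#' corrected table, flagged via `corrected = TRUE`.
#'
#' @param cells cell table with `tls_status` and a cluster column.
#' @param cluster the cluster label tested (one vs rest).
#' @param contrast ordered pair `c(statusA, statusB)`; positive `log2_or`
#'   means the cluster is enriched in `statusA` relative to `statusB`.
#' @param clusterCol column holding cluster labels; default "subcluster".
#' @param by `"pooled"` (default) pools cells within status; `"sample"`
#'   fits on per-sample binomial totals (same one-factor model, sample
#'   rows as independent binomial observations).
#' @return one-row data.frame: `cluster`, `contrast`, `log2_or`, `se`,
#'   `p`, `p_adj` (NA here; filled by [enrichmentGrid()]), `n_family`,
#'   `corrected`.
#' @export
fitClusterEnrichment <- function(cells, cluster, contrast,
                                 clusterCol = "subcluster",
                                 by = c("pooled", "sample")) {
  by <- match.arg(by)
  assertColumns(cells, c("tls_status", clusterCol), "cells")
  stopifnot(length(contrast) == 2L)
  if (!cluster %in% cells[[clusterCol]])
    stop("cluster '", cluster, "' absent from table")
  sub <- cells[cells$tls_status %in% contrast, , drop = FALSE]
  for (s in contrast)
    if (!any(sub$tls_status == s))
      stop("status '", s, "' has no cells")
  member <- sub[[clusterCol]] == cluster
  inA <- sum(member & sub$tls_status == contrast[1])
  outA <- sum(!member & sub$tls_status == contrast[1])
  inB <- sum(member & sub$tls_status == contrast[2])
  outB <- sum(!member & sub$tls_status == contrast[2])

  if (min(inA, outA, inB, outB) == 0L) {
    # Haldane-Anscombe correction keeps the log odds ratio finite
    a <- inA + 0.5; b <- outA + 0.5; c0 <- inB + 0.5; d <- outB + 0.5
    est <- log((a * d) / (b * c0))
    se <- sqrt(1 / a + 1 / b + 1 / c0 + 1 / d)
    p <- 2 * stats::pnorm(-abs(est / se))
    corrected <- TRUE
  } else {
    if (by == "pooled") {
      dat <- data.frame(
        status = factor(contrast, levels = c(contrast[2], contrast[1])),
        inCl = c(inA, inB), outCl = c(outA, outB))
    } else {
      assertColumns(sub, "sample_id", "cells (by = 'sample')")
      agg <- stats::aggregate(member ~ sample_id + tls_status,
                              data = cbind(sub, member = member), FUN = sum)
      tot <- stats::aggregate(member ~ sample_id + tls_status,
                              data = cbind(sub, member = member),
                              FUN = length)
      dat <- data.frame(
        status = factor(agg$tls_status,
                        levels = c(contrast[2], contrast[1])),
        inCl = agg$member, outCl = tot$member - agg$member)
    }
    fit <- stats::glm(cbind(inCl, outCl) ~ status, family = stats::binomial(),
                      data = dat)
    emm <- emmeans::emmeans(fit, ~status)
    ctr <- summary(emmeans::contrast(
      emm, method = list(delta = c(-1, 1)), adjust = "none"))
    est <- ctr$estimate
    se <- ctr$SE
    p <- ctr$p.value
    corrected <- FALSE
  }
  data.frame(cluster = cluster,
             contrast = paste(contrast, collapse = "_vs_"),
             log2_or = est / log(2), se = se / log(2), p = p,
             p_adj = NA_real_, n_family = 1L, corrected = corrected,
             stringsAsFactors = FALSE)
}

#' Enrichment grid over all clusters and status contrasts
#'
#' Runs [fitClusterEnrichment()] for every cluster x ordered status pair in
#' a compartment, Bonferroni-adjusts p-values with family size equal to the
#' whole grid, and adds dot-plot-ready columns (`dot_color` = log2 odds
#' ratio, `dot_size` = -log10 adjusted p, capped).
#'
#' @inheritParams fitClusterEnrichment
#' @param compartment optional lineage label; restricts cells to
#'   `lineage == compartment`.
#' @param statuses status order; default the levels present, in
#'   nTLS/imTLS/mTLS order when applicable. Contrasts are all pairs
#'   (later status vs earlier).
#' @param capNeglog10 cap for `dot_size`; default 10.
#' @return data.frame of per-(cluster, contrast) results with `p_adj =
#'   min(1, p * n_family)`.
#' @export
enrichmentGrid <- function(cells, compartment = NULL,
                           clusterCol = "subcluster", statuses = NULL,
                           by = c("pooled", "sample"), capNeglog10 = 10) {
  by <- match.arg(by)
  assertColumns(cells, c("tls_status", clusterCol), "cells")
  if (!is.null(compartment)) {
    assertColumns(cells, "lineage", "cells")
    cells <- cells[cells$lineage == compartment, , drop = FALSE]
  }
  if (is.null(statuses)) {
    present <- unique(cells$tls_status)
    statuses <- c(intersect(tlsStatuses(), present),
                  setdiff(present, tlsStatuses()))
  }
  if (length(statuses) < 2L) stop("need at least two statuses")
  clusters <- sort(unique(cells[[clusterCol]]))
  if (!length(clusters)) stop("no clusters in compartment")
  pairs <- utils::combn(seq_along(statuses), 2L)
  res <- list()
  for (cl in clusters) {
    for (j in seq_len(ncol(pairs))) {
      ctr <- c(statuses[pairs[2L, j]], statuses[pairs[1L, j]])
      res[[length(res) + 1L]] <-
        fitClusterEnrichment(cells, cl, ctr, clusterCol, by)
    }
  }
  out <- do.call(rbind, res)
  out$n_family <- nrow(out)
  out$p_adj <- pmin(1, out$p * out$n_family)
  out$dot_color <- out$log2_or
  out$dot_size <- pmin(-log10(pmax(out$p_adj, .Machine$double.xmin)),
                       capNeglog10)
  out
}
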