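# shared fixture builders and independent oracles

# chains table row helper
chainRow <- function(cell, locus, cdr3, v = paste0(locus, "V1"),
                     j = paste0(locus, "J1")) {
  data.frame(cell_id = cell, locus = locus, cdr3_nt = cdr3,
             cdr3_aa = NA_character_, v_gene = v, j_gene = j,
             junction_length = nchar(cdr3), stringsAsFactors = FALSE)
}

# random TCR fixture with a small sequence pool so clonotypes collide
randomTcrFixture <- function(nCells, seed) {
  set.seed(seed)
  pool <- replicate(max(3L, nCells %/% 3L),
                    paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                          collapse = ""))
  rows <- lapply(seq_len(nCells), function(i) {
    cell <- sprintf("cell%03d", i)
    out <- rbind(chainRow(cell, "TRA", sample(pool, 1)),
                 chainRow(cell, "TRB", sample(pool, 1)))
    if (runif(1) < 0.15)  # secondary alpha chain, still a valid TCR cell
      out <- rbind(out, chainRow(cell, "TRA", sample(pool, 1)))
    out
  })
  unique(do.call(rbind, rows))
}

# two partitions (named cluster labels) induce the same equivalence classes
samePartition <- function(a, b) {
  stopifnot(identical(names(a), names(b)))
  ta <- outer(a, a, "=="); tb <- outer(b, b, "==")
  identical(ta, tb)
}

# brute-force TCR grouping: sorted TRA set + sorted TRB set per cell
bruteForceTcrPartition <- function(chains, cells) {
  keys <- vapply(cells, function(cc) {
    d <- chains[chains$cell_id == cc, ]
    paste(paste(sort(d$cdr3_nt[d$locus == "TRA"]), collapse = ","),
          paste(sort(d$cdr3_nt[d$locus == "TRB"]), collapse = ","),
          sep = "/")
  }, character(1))
  stats::setNames(keys, cells)
}

# brute-force KDE: double loop over points and nodes
bruteForceKde <- function(pts, gx, gy, bw) {
  out <- matrix(0, length(gx), length(gy))
  for (i in seq_along(gx)) for (j in seq_along(gy)) {
    s <- 0
    for (p in seq_len(nrow(pts)))
      s <- s + stats::dnorm(gx[i] - pts[p, 1], sd = bw[1]) *
        stats::dnorm(gy[j] - pts[p, 2], sd = bw[2])
    out[i, j] <- s / nrow(pts)
  }
  out
}

# brute-force recovery-curve AUC for one cell
bruteForceAuc <- function(x, isSet, topFraction) {
  G <- length(x)
  k <- ceiling(topFraction * G)
  ord <- order(-x, seq_len(G))
  hits <- cumsum(isSet[ord])[seq_len(k)]
  nset <- sum(isSet)
  maxA <- sum(pmin(seq_len(k), nset))
  sum(hits) / maxA
}

# direct Shannon/D50 formulas from a clone-size vector
oracleDiversity <- function(sizes) {
  sizes <- sort(sizes, decreasing = TRUE)
  p <- sizes / sum(sizes)
  k <- 0; acc <- 0
  for (i in seq_along(p)) { acc <- acc + p[i]; k <- i; if (acc >= 0.5) break }
  list(shannon = -sum(p * log(p)), d50 = 100 * k / length(p))
}

# chains fixture realizing a given clone-size vector as a TCR repertoire
tcrFixtureFromSizes <- function(sizes) {
  rows <- list(); cell <- 0L
  for (k in seq_along(sizes)) {
    a <- paste(rep(c("A", "C", "G", "T")[(k %% 4) + 1], 9), collapse = "")
    b <- paste0(substr(a, 1, 6), sprintf("%03d", k))
    for (i in seq_len(sizes[k])) {
      cell <- cell + 1L
      id <- sprintf("cell%02d", cell)
      rows[[length(rows) + 1L]] <- rbind(
        chainRow(id, "TRA", paste0("AAA", sprintf("%03d", k))),
        chainRow(id, "TRB", paste0("CCC", sprintf("%03d", k))))
    }
  }
  do.call(rbind, rows)
}
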