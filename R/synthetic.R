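#' Specify a synthetic cell-composition experiment
#'
#' Describes a multinomial cluster composition that differs between TLS
#' maturity statuses through planted log2 odds ratios. The first status is
#' the reference; for a cluster with planted effect \eqn{\beta} in status s,
#' the one-vs-rest odds of belonging to that cluster in s are
#' \eqn{2^\beta} times the reference odds, with the remaining probability
#' mass spread over the unaffected clusters in their base ratios (which
#' leaves each planted cluster's odds ratio exact).
#'
#' @param statuses ordered status labels; default `c("nTLS","imTLS","mTLS")`.
#' @param samplesPerStatus,cellsPerSample positive integers.
#' @param clusters cluster labels.
#' @param baseProportions probability vector over `clusters` (sums to 1).
#' @param plantedLog2OR data.frame with columns `cluster`, `status`,
#'   `log2_or`: the planted per-cluster log2 odds ratio of that status
#'   versus the reference status. Omitted combinations are 0.
#' @param clusterLineage optional named vector mapping cluster -> lineage
#'   label (default all "T").
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return a `CompositionSpec` list.
#' @export
compositionSpec <- function(statuses = tlsStatuses(),
                            samplesPerStatus = 4L,
                            cellsPerSample = 2000L,
                            clusters,
                            baseProportions,
                            plantedLog2OR = NULL,
                            clusterLineage = NULL,
                            seed = 1L) {
  stopifnot(length(statuses) >= 2L, samplesPerStatus >= 1L,
            cellsPerSample >= 1L,
            length(clusters) == length(baseProportions))
  if (any(baseProportions < 0) || abs(sum(baseProportions) - 1) > 1e-12)
    stop("baseProportions must be nonnegative and sum to 1")
  if (!is.null(plantedLog2OR)) {
    assertColumns(plantedLog2OR, c("cluster", "status", "log2_or"),
                  "plantedLog2OR")
    if (!all(plantedLog2OR$cluster %in% clusters))
      stop("plantedLog2OR references unknown cluster")
    if (!all(plantedLog2OR$status %in% statuses[-1L]))
      stop("plantedLog2OR status must be a non-reference status")
  }
  if (is.null(clusterLineage)) {
    clusterLineage <- stats::setNames(rep("T", length(clusters)), clusters)
  }
  structure(
    list(statuses = statuses, samplesPerStatus = as.integer(samplesPerStatus),
         cellsPerSample = as.integer(cellsPerSample), clusters = clusters,
         baseProportions = stats::setNames(baseProportions, clusters),
         plantedLog2OR = plantedLog2OR, clusterLineage = clusterLineage,
         seed = as.integer(seed)),
    class = "CompositionSpec")
}

# Per-status cluster proportions implied by the planted log2 odds ratios.
adjustedProportions <- function(spec, status) {
  p <- spec$baseProportions
  lor <- stats::setNames(rep(0, length(p)), names(p))
  if (!is.null(spec$plantedLog2OR)) {
    rows <- spec$plantedLog2OR[spec$plantedLog2OR$status == status, ]
    lor[rows$cluster] <- rows$log2_or
  }
  affected <- names(p)[lor != 0]
  if (!length(affected)) return(p)
  odds <- (p[affected] / (1 - p[affected])) * 2^lor[affected]
  pAff <- odds / (1 + odds)
  rem <- 1 - sum(pAff)
  others <- setdiff(names(p), affected)
  if (rem <= 0 || (length(others) == 0L && abs(rem) > 1e-12))
    stop("adjusted proportion vector fails to normalize for status ", status)
  out <- p
  out[affected] <- pAff
  out[others] <- p[others] * rem / sum(p[others])
  out
}

#' Simulate per-cell metadata with planted compositional effects
#'
#' Draws cells for each (status, sample) from the multinomial over clusters
#' implied by the spec's base proportions and planted log2 odds ratios.
#'
#' @param spec a [compositionSpec()].
#' @return data.frame (`cell_id`, `sample_id`, `tls_status`, `lineage`,
#'   `subcluster`) with the spec attached as attribute `"truth"`.
#' @export
simulateComposition <- function(spec) {
  stopifnot(inherits(spec, "CompositionSpec"))
  set.seed(childSeed(spec$seed, 11L))
  props <- lapply(spec$statuses, function(s) adjustedProportions(spec, s))
  names(props) <- spec$statuses
  rows <- list()
  for (s in spec$statuses) {
    for (i in seq_len(spec$samplesPerStatus)) {
      cl <- sample(spec$clusters, spec$cellsPerSample, replace = TRUE,
                   prob = props[[s]])
      sid <- sprintf("%s_s%02d", s, i)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = sprintf("%s_c%05d", sid, seq_len(spec$cellsPerSample)),
        sample_id = sid, tls_status = s,
        lineage = unname(spec$clusterLineage[cl]), subcluster = cl,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- spec
  out
}

#' Simulate negative-binomial counts with a planted signature elevation
#'
#' Generates a sparse cells x genes count matrix. Signature genes have their
#' mean multiplied by `1 + effect` in cells flagged TRUE in the
#' `positiveCol` column; all counts are negative binomial with common
#' dispersion. Gene symbols are the signature genes, then filler genes, then
#' optional mitochondrial genes (prefix "MT-") for QC exercises.
#'
#' @param cells cell table; needs `cell_id` and, when `effect > 0`, a
#'   logical column named by `positiveCol`.
#' @param signature a gene set as returned by [geneSet()].
#' @param effect nonnegative fold elevation of signature-gene means in
#'   positive cells (0 = null).
#' @param nbDispersion NB size parameter; larger is closer to Poisson.
#' @param seed integer seed.
#' @param nGenes total genes including signature and mito genes.
#' @param nMitoGenes how many "MT-" genes to append.
#' @param positiveCol name of the logical flag column in `cells`.
#' @return a [Matrix::dgCMatrix-class] of counts, rows = cells, columns =
#'   genes, with the per-gene base means attached as attribute `"truth"`.
#' @export
simulateExpression <- function(cells, signature, effect = 0,
                               nbDispersion = 2, seed = 1L,
                               nGenes = 300L, nMitoGenes = 0L,
                               positiveCol = "signature_positive") {
  assertColumns(cells, "cell_id", "cells")
  if (!length(signature$genes)) stop("empty gene set")
  stopifnot(effect >= 0, nbDispersion > 0)
  if (effect > 0 && !positiveCol %in% names(cells))
    stop("cells must carry the '", positiveCol,
         "' flag when effect > 0")
  pos <- if (positiveCol %in% names(cells)) cells[[positiveCol]] else
    rep(FALSE, nrow(cells))
  sig <- signature$genes
  nFill <- nGenes - length(sig) - nMitoGenes
  if (nFill < 0) stop("nGenes too small for signature plus mito genes")
  genes <- c(sig, sprintf("GENE%04d", seq_len(nFill)),
             if (nMitoGenes > 0) sprintf("MT-G%d", seq_len(nMitoGenes)))
  set.seed(childSeed(seed, 23L))
  baseMean <- stats::setNames(stats::rgamma(length(genes), shape = 0.5,
                                            rate = 0.25), genes)
  n <- nrow(cells)
  mu <- matrix(baseMean, nrow = n, ncol = length(genes), byrow = TRUE)
  mu[pos, genes %in% sig] <- mu[pos, genes %in% sig] * (1 + effect)
  counts <- matrix(stats::rnbinom(n * length(genes), size = nbDispersion,
                                  mu = mu),
                   nrow = n, dimnames = list(cells$cell_id, genes))
  out <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  attr(out, "truth") <- list(baseMean = baseMean, effect = effect,
                             signature = sig, positive = cells$cell_id[pos])
  out
}

#' Specify a synthetic paired-chain receptor repertoire
#'
#' @param cloneSizeExponent exponent (> 1) of the truncated discrete
#'   power-law on clone-size weights; larger means less expansion.
#' @param nClonotypes clonotypes per receptor class present in the cells.
#' @param sharingProb NULL or data.frame (`cluster_a`, `cluster_b`, `prob`):
#'   probability that a clonotype homed in one cluster of the pair also
#'   seeds cells in the other.
#' @param ambiguousFrac,multichainFrac per-cell probabilities of emitting an
#'   ambiguous (both receptor classes) or multichain (>2 chains of one
#'   paired arm) cell.
#' @param seed integer seed.
#' @return a `RepertoireSpec` list.
#' @export
repertoireSpec <- function(cloneSizeExponent = 2.5, nClonotypes = 200L,
                           sharingProb = NULL, ambiguousFrac = 0,
                           multichainFrac = 0, seed = 1L) {
  stopifnot(cloneSizeExponent > 1, nClonotypes >= 1L)
  for (p in c(ambiguousFrac, multichainFrac))
    if (p < 0 || p > 1) stop("fractions must be probabilities in [0, 1]")
  if (!is.null(sharingProb)) {
    assertColumns(sharingProb, c("cluster_a", "cluster_b", "prob"),
                  "sharingProb")
    if (any(sharingProb$prob < 0 | sharingProb$prob > 1))
      stop("sharing probabilities must lie in [0, 1]")
  }
  structure(
    list(cloneSizeExponent = cloneSizeExponent,
         nClonotypes = as.integer(nClonotypes), sharingProb = sharingProb,
         ambiguousFrac = ambiguousFrac, multichainFrac = multichainFrac,
         seed = as.integer(seed)),
    class = "RepertoireSpec")
}

randomCdr3 <- function(n) {
  lens <- sample(seq(30L, 45L, by = 3L), n, replace = TRUE)
  vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

# clone-size weights: truncated zeta, P(w) proportional to w^-alpha
zetaWeights <- function(n, alpha, maxSize) {
  s <- seq_len(max(1L, maxSize))
  sample(s, n, replace = TRUE, prob = s^(-alpha))
}

#' Simulate paired receptor chains with ground-truth clonotypes
#'
#' Emits one or more receptor chain records per cell. T-lineage cells get a
#' TRA+TRB pair, B-lineage cells an IGH plus a light chain; clonotype
#' identity is encoded by identical CDR3 nucleotide strings. Clonotypes are
#' homed in clusters and span a second cluster with the pair's sharing
#' probability; cells then sample a clonotype available in their cluster
#' with probability proportional to its power-law size weight. Designated
#' fractions of cells are emitted as ambiguous (an extra chain of the other
#' receptor class) or multichain (a third chain of one paired arm).
#'
#' @param cells cell table with `cell_id`, `subcluster`, `lineage`
#'   (lineages starting with "B" get BCR chains, all others TCR).
#' @param spec a [repertoireSpec()].
#' @return list with `chains` (receptor table: `cell_id`, `locus`,
#'   `cdr3_nt`, `cdr3_aa`, `v_gene`, `j_gene`, `junction_length`), `truth`
#'   (per-cell true clonotype and class) and `clonotypes` (per-clonotype
#'   receptor class and cluster set).
#' @export
simulateRepertoire <- function(cells, spec) {
  stopifnot(inherits(spec, "RepertoireSpec"))
  assertColumns(cells, c("cell_id", "subcluster", "lineage"), "cells")
  clusters <- unique(cells$subcluster)
  if (!is.null(spec$sharingProb)) {
    ref <- unique(c(spec$sharingProb$cluster_a, spec$sharingProb$cluster_b))
    if (!all(ref %in% clusters))
      stop("sharingProb references unknown cluster: ",
           paste(setdiff(ref, clusters), collapse = ", "))
  }
  set.seed(childSeed(spec$seed, 37L))
  isB <- grepl("^B", cells$lineage) | cells$lineage %in% c("plasma", "Plasma")
  classes <- ifelse(isB, "BCR", "TCR")

  chainRows <- list()
  truthRows <- list()
  clonoRows <- list()

  for (rc in intersect(c("TCR", "BCR"), unique(classes))) {
    sub <- cells[classes == rc, , drop = FALSE]
    cl <- unique(sub$subcluster)
    K <- spec$nClonotypes
    # every cluster gets at least one homed clonotype, rest proportional
    home <- c(cl, sample(cl, max(0L, K - length(cl)), replace = TRUE,
                         prob = as.numeric(table(sub$subcluster)[cl])))
    K <- length(home)
    w <- zetaWeights(K, spec$cloneSizeExponent,
                     maxSize = max(table(sub$subcluster)))
    sets <- as.list(home)
    if (!is.null(spec$sharingProb)) {
      for (r in seq_len(nrow(spec$sharingProb))) {
        a <- spec$sharingProb$cluster_a[r]
        b <- spec$sharingProb$cluster_b[r]
        p <- spec$sharingProb$prob[r]
        for (k in seq_len(K)) {
          if (home[k] == a && stats::runif(1) < p)
            sets[[k]] <- union(sets[[k]], b)
          else if (home[k] == b && stats::runif(1) < p)
            sets[[k]] <- union(sets[[k]], a)
        }
      }
    }
    ids <- sprintf("%s_clone%04d", tolower(rc), seq_len(K))
    # receptor sequences per clonotype
    if (rc == "TCR") {
      seq1 <- randomCdr3(K); seq2 <- randomCdr3(K)
      vPool <- list(TRA = sprintf("TRAV%d", 1:8),
                    TRB = sprintf("TRBV%d", 1:8))
      jPool <- list(TRA = sprintf("TRAJ%d", 1:6),
                    TRB = sprintf("TRBJ%d", 1:6))
    } else {
      seq1 <- randomCdr3(K); seq2 <- randomCdr3(K)
      lightLocus <- sample(c("IGK", "IGL"), K, replace = TRUE)
      vPool <- list(IGH = sprintf("IGHV%d-1", 1:5),
                    IGK = sprintf("IGKV%d", 1:4),
                    IGL = sprintf("IGLV%d", 1:4))
      jPool <- list(IGH = sprintf("IGHJ%d", 1:4),
                    IGK = sprintf("IGKJ%d", 1:3),
                    IGL = sprintf("IGLJ%d", 1:3))
    }
    if (rc == "TCR") {
      vGene1 <- sample(vPool$TRA, K, TRUE); jGene1 <- sample(jPool$TRA, K, TRUE)
      vGene2 <- sample(vPool$TRB, K, TRUE); jGene2 <- sample(jPool$TRB, K, TRUE)
    } else {
      vGene1 <- sample(vPool$IGH, K, TRUE); jGene1 <- sample(jPool$IGH, K, TRUE)
      vGene2 <- vapply(lightLocus, function(x) sample(vPool[[x]], 1L),
                       character(1))
      jGene2 <- vapply(lightLocus, function(x) sample(jPool[[x]], 1L),
                       character(1))
    }

    membership <- vapply(sets, function(s, cc) cc %in% s, logical(length(cl)),
                         cc = cl)
    if (length(cl) == 1L) membership <- matrix(membership, nrow = 1L)
    rownames(membership) <- cl

    clsTruth <- list()
    for (ci in cl) {
      inCl <- sub$cell_id[sub$subcluster == ci]
      avail <- which(membership[ci, ])
      pick <- avail[sample.int(length(avail), length(inCl), replace = TRUE,
                               prob = w[avail])]
      clsTruth[[length(clsTruth) + 1L]] <- data.frame(
        cell_id = inCl, true_clonotype = ids[pick], true_class = rc,
        stringsAsFactors = FALSE)
    }
    tr <- do.call(rbind, clsTruth)
    truthRows[[length(truthRows) + 1L]] <- tr
    k <- match(tr$true_clonotype, ids)
    secondLocus <- if (rc == "TCR") rep("TRB", nrow(tr)) else lightLocus[k]
    chainRows[[length(chainRows) + 1L]] <- data.frame(
      cell_id = rep(tr$cell_id, 2L),
      locus = c(rep(if (rc == "TCR") "TRA" else "IGH", nrow(tr)),
                secondLocus),
      cdr3_nt = c(seq1[k], seq2[k]), cdr3_aa = NA_character_,
      v_gene = c(vGene1[k], vGene2[k]),
      j_gene = c(jGene1[k], jGene2[k]),
      stringsAsFactors = FALSE)
    clonoRows[[length(clonoRows) + 1L]] <- data.frame(
      clonotype_id = ids, receptor = rc,
      clusters = vapply(sets, paste, character(1), collapse = ";"),
      weight = w, stringsAsFactors = FALSE)
  }

  chains <- do.call(rbind, chainRows)
  truth <- do.call(rbind, truthRows)
  truth <- truth[!duplicated(truth$cell_id), ]

  # ambiguous: extra chain of the other receptor class
  amb <- truth$cell_id[stats::runif(nrow(truth)) < spec$ambiguousFrac]
  if (length(amb)) {
    other <- ifelse(truth$true_class[match(amb, truth$cell_id)] == "TCR",
                    "IGH", "TRA")
    chains <- rbind(chains, data.frame(
      cell_id = amb, locus = other, cdr3_nt = randomCdr3(length(amb)),
      cdr3_aa = NA_character_, v_gene = paste0(other, "V1"),
      j_gene = paste0(other, "J1"), stringsAsFactors = FALSE))
    truth$true_class[truth$cell_id %in% amb] <- "ambiguous"
    truth$true_clonotype[truth$cell_id %in% amb] <- NA_character_
  }
  # multichain: two extra chains of one paired arm (three of that arm total)
  rest <- setdiff(truth$cell_id, amb)
  mc <- rest[stats::runif(length(rest)) < spec$multichainFrac]
  if (length(mc)) {
    arm <- ifelse(truth$true_class[match(mc, truth$cell_id)] == "TCR",
                  "TRB", "IGH")
    extra <- data.frame(
      cell_id = rep(mc, 2L), locus = rep(arm, 2L),
      cdr3_nt = randomCdr3(2L * length(mc)), cdr3_aa = NA_character_,
      v_gene = paste0(rep(arm, 2L), "V9"), j_gene = paste0(rep(arm, 2L), "J9"),
      stringsAsFactors = FALSE)
    chains <- rbind(chains, extra)
    truth$true_class[truth$cell_id %in% mc] <- "multichain"
    truth$true_clonotype[truth$cell_id %in% mc] <- NA_character_
  }
  chains$junction_length <- nchar(chains$cdr3_nt)
  chains <- chains[order(chains$cell_id, chains$locus, chains$cdr3_nt), ]
  rownames(chains) <- NULL
  rownames(truth) <- NULL
  list(chains = chains, truth = truth,
       clonotypes = do.call(rbind, clonoRows))
}

#' Specify synthetic spot-level cell-type abundances
#'
#' Abundances are independent per-type Gamma draws (shape = the type's
#' concentration) plus, for each co-localized pair, a shared Gamma(1,1)
#' latent factor scaled by the pair's loading rho and added to both types.
#' At rho = 0 types are exactly independent, so the co-occurrence score of
#' a pair equals the product of its mean abundances (x 1000) in
#' expectation; increasing rho increases the pair's covariance and hence
#' its score.
#'
#' @param nSpots number of spots.
#' @param cellTypes type labels.
#' @param baseConcentration nonnegative Gamma shape per type (0 = absent).
#' @param colocalizedPairs NULL or data.frame (`type_a`, `type_b`, `rho`)
#'   with rho >= 0.
#' @param seed integer seed.
#' @return a `SpotSpec` list.
#' @export
spotSpec <- function(nSpots = 300L, cellTypes,
                     baseConcentration = NULL, colocalizedPairs = NULL,
                     seed = 1L) {
  stopifnot(nSpots >= 1L, length(cellTypes) >= 1L)
  if (is.null(baseConcentration))
    baseConcentration <- stats::setNames(rep(1, length(cellTypes)), cellTypes)
  stopifnot(length(baseConcentration) == length(cellTypes))
  if (any(baseConcentration < 0))
    stop("concentrations must be nonnegative")
  if (!is.null(colocalizedPairs)) {
    assertColumns(colocalizedPairs, c("type_a", "type_b", "rho"),
                  "colocalizedPairs")
    if (!all(c(colocalizedPairs$type_a, colocalizedPairs$type_b) %in%
             cellTypes))
      stop("colocalizedPairs references unknown cell type")
    if (any(colocalizedPairs$rho < 0)) stop("rho must be >= 0")
  }
  structure(
    list(nSpots = as.integer(nSpots), cellTypes = cellTypes,
         baseConcentration = stats::setNames(baseConcentration, cellTypes),
         colocalizedPairs = colocalizedPairs, seed = as.integer(seed)),
    class = "SpotSpec")
}

#' Simulate a spots x cell-types abundance matrix with planted co-localization
#'
#' @param spec a [spotSpec()].
#' @return numeric matrix (rows = spots, columns = cell types) of
#'   nonnegative abundances; the spec is attached as attribute `"truth"`.
#' @export
simulateSpots <- function(spec) {
  stopifnot(inherits(spec, "SpotSpec"))
  set.seed(childSeed(spec$seed, 53L))
  n <- spec$nSpots
  A <- vapply(spec$cellTypes, function(ct) {
    sh <- spec$baseConcentration[[ct]]
    if (sh == 0) rep(0, n) else stats::rgamma(n, shape = sh, rate = 1)
  }, numeric(n))
  if (n == 1L) A <- matrix(A, nrow = 1L,
                           dimnames = list(NULL, spec$cellTypes))
  if (!is.null(spec$colocalizedPairs)) {
    for (r in seq_len(nrow(spec$colocalizedPairs))) {
      L <- stats::rgamma(n, shape = 1, rate = 1)
      rho <- spec$colocalizedPairs$rho[r]
      A[, spec$colocalizedPairs$type_a[r]] <-
        A[, spec$colocalizedPairs$type_a[r]] + rho * L
      A[, spec$colocalizedPairs$type_b[r]] <-
        A[, spec$colocalizedPairs$type_b[r]] + rho * L
    }
  }
  rownames(A) <- sprintf("spot%04d", seq_len(n))
  attr(A, "truth") <- spec
  A
}

#' Specify synthetic multiplex-imaging point patterns
#'
#' Each tissue core carries one point pattern per phenotype: clustered
#' phenotypes follow a Neyman-Scott (Thomas) process — Poisson parents with
#' Gaussian-scattered offspring — while the rest are complete spatial
#' randomness at the stated intensity. Clustered phenotypes sharing a
#' `parentGroup` share parent locations within a core, planting spatial
#' proximity between them.
#'
#' @param nCores number of tissue cores.
#' @param coreStatus TLS status label per core (length `nCores`).
#' @param phenotypes data.frame with columns `phenotype`, `clustered`
#'   (logical), `intensity` (points or parents per square micron),
#'   `offspringPerParent`, `clusterRadius` (microns; used when clustered),
#'   and optional `parentGroup`.
#' @param window rectangle `c(xmin, xmax, ymin, ymax)` in microns.
#' @param seed integer seed.
#' @return a `PointSpec` list.
#' @export
pointSpec <- function(nCores = 6L, coreStatus = NULL, phenotypes,
                      window = c(0, 600, 0, 600), seed = 1L) {
  stopifnot(nCores >= 1L, length(window) == 4L)
  if (window[2] <= window[1] || window[4] <= window[3])
    stop("window must have positive area")
  assertColumns(phenotypes,
                c("phenotype", "clustered", "intensity"), "phenotypes")
  if (is.null(coreStatus))
    coreStatus <- rep(tlsStatuses(), length.out = nCores)
  stopifnot(length(coreStatus) == nCores)
  if (!"parentGroup" %in% names(phenotypes))
    phenotypes$parentGroup <- ifelse(phenotypes$clustered,
                                     phenotypes$phenotype, NA)
  structure(
    list(nCores = as.integer(nCores), coreStatus = coreStatus,
         phenotypes = phenotypes, window = window, seed = as.integer(seed)),
    class = "PointSpec")
}

#' Simulate phenotype-labelled point patterns per tissue core
#'
#' @param spec a [pointSpec()].
#' @return data.frame (`core_id`, `tls_status`, `cell_id`, `x`, `y`,
#'   `phenotype`) with the spec as attribute `"truth"`.
#' @export
simulatePoints <- function(spec) {
  stopifnot(inherits(spec, "PointSpec"))
  set.seed(childSeed(spec$seed, 71L))
  w <- spec$window
  area <- (w[2] - w[1]) * (w[4] - w[3])
  ph <- spec$phenotypes
  out <- list()
  for (core in seq_len(spec$nCores)) {
    coreId <- sprintf("core%02d", core)
    parents <- list()
    groups <- unique(stats::na.omit(ph$parentGroup[ph$clustered]))
    for (g in groups) {
      lam <- ph$intensity[ph$clustered & !is.na(ph$parentGroup) &
                            ph$parentGroup == g][1]
      nPar <- stats::rpois(1L, lam * area)
      parents[[g]] <- cbind(stats::runif(nPar, w[1], w[2]),
                            stats::runif(nPar, w[3], w[4]))
    }
    for (r in seq_len(nrow(ph))) {
      if (ph$clustered[r]) {
        par <- parents[[ph$parentGroup[r]]]
        if (!nrow(par)) next
        nOff <- stats::rpois(nrow(par), ph$offspringPerParent[r])
        px <- rep(par[, 1], nOff); py <- rep(par[, 2], nOff)
        x <- px + stats::rnorm(length(px), sd = ph$clusterRadius[r])
        y <- py + stats::rnorm(length(py), sd = ph$clusterRadius[r])
        keep <- x >= w[1] & x <= w[2] & y >= w[3] & y <= w[4]
        x <- x[keep]; y <- y[keep]
      } else {
        nPts <- stats::rpois(1L, ph$intensity[r] * area)
        x <- stats::runif(nPts, w[1], w[2])
        y <- stats::runif(nPts, w[3], w[4])
      }
      if (!length(x)) next
      out[[length(out) + 1L]] <- data.frame(
        core_id = coreId, tls_status = spec$coreStatus[core],
        cell_id = sprintf("%s_%s_%04d", coreId, ph$phenotype[r],
                          seq_along(x)),
        x = x, y = y, phenotype = ph$phenotype[r],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- spec
  res
}
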