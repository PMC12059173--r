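pipelineDefaults <- function() list(
  seed = 1L,
  out_dir = "tlsscape_out",
  stages = c("qc", "enrichment", "density", "scoring", "repertoire",
             "cooccurrence", "proximity"),
  inputs = list(cell_table = NULL, counts_dir = NULL, doublet_scores = NULL,
                airr = NULL, spots = NULL, points = NULL,
                gene_sets = NULL),
  qc = list(min_cells = 3, min_genes = 200, max_genes = 4000,
            max_pct_mito = 20, max_umi = 25000, max_doublet = 0.2),
  enrichment = list(compartment = NULL, by = "pooled", cap_neglog10 = 10),
  density = list(n_grid = 100L, group = NULL),
  scoring = list(top_fraction = 0.05, random_ties = FALSE),
  repertoire = list(receptor = "tcr", threshold = "auto"),
  proximity = list(pairs = NULL, pool = FALSE)
)

#' Validate and complete a pipeline configuration
#'
#' Merges user settings over the package defaults (which equal the QC and
#' model defaults stated throughout the module functions) and rejects
#' unknown keys at the top level and within every section, so typos fail
#' fast before any stage runs.
#'
#' @param config named list, or path to a YAML/JSON file holding one.
#' @return validated config list.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defs <- pipelineDefaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in c("inputs", "qc", "enrichment", "density", "scoring",
                "repertoire", "proximity")) {
    bad <- setdiff(names(config[[sec]]), names(defs[[sec]]))
    if (length(bad))
      stop("unknown key(s) in config$", sec, ": ",
           paste(bad, collapse = ", "))
    defs[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  for (k in setdiff(names(config), c("inputs", "qc", "enrichment",
                                     "density", "scoring", "repertoire",
                                     "proximity")))
    defs[[k]] <- config[[k]]
  badStages <- setdiff(defs$stages, pipelineDefaults()$stages)
  if (length(badStages))
    stop("unknown stage(s): ", paste(badStages, collapse = ", "))
  defs
}

md5OfObject <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tf)
  unname(tools::md5sum(tf))
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order — QC first, then
#' enrichment / embedding density / signature scoring on the QC-passing
#' cells; repertoire, spatial co-occurrence and imaging proximity run
#' independently — writing one delimited output per stage plus a JSON run
#' manifest with config hash, input/output checksums, per-stage row
#' counts and timings. Reruns with identical inputs and config reproduce
#' identical output checksums.
#'
#' @param config a [pipelineConfig()] list or a path to one.
#' @return the manifest list, invisibly; outputs land in
#'   `config$out_dir`.
#' @export
runPipeline <- function(config) {
  cfg <- pipelineConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("TLSscape")),
                   config_hash = md5OfObject(cfg),
                   inputs = list(), stages = list())
  inputFiles <- unlist(cfg$inputs[!vapply(cfg$inputs, is.null, logical(1))])
  inputFiles <- unlist(lapply(inputFiles, function(f)
    if (dir.exists(f)) list.files(f, full.names = TRUE) else f))
  if (length(inputFiles))
    manifest$inputs <- as.list(tools::md5sum(inputFiles))

  cells <- NULL
  counts <- NULL
  if (!is.null(cfg$inputs$cell_table))
    cells <- readCellTable(cfg$inputs$cell_table)
  if (!is.null(cfg$inputs$counts_dir))
    counts <- readCounts(cfg$inputs$counts_dir)
  doublet <- NULL
  if (!is.null(cfg$inputs$doublet_scores)) {
    ds <- readDelim(cfg$inputs$doublet_scores)
    assertColumns(ds, c("cell_id", "doublet_score"), "doublet scores")
    doublet <- stats::setNames(ds$doublet_score, ds$cell_id)
  }

  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- c(res,
      list(seconds = round(proc.time()[["elapsed"]] - t0, 3)))
  }

  if ("qc" %in% cfg$stages && !is.null(counts)) {
    stage("qc", function() {
      q <- cfg$qc
      res <- runQC(counts, doubletScores = doublet,
                   minCells = q$min_cells, minGenes = q$min_genes,
                   maxGenes = q$max_genes, maxPctMito = q$max_pct_mito,
                   maxUmi = q$max_umi, maxDoublet = q$max_doublet)
      counts <<- res$counts
      if (!is.null(cells))
        cells <<- cells[cells$cell_id %in% rownames(counts), ,
                        drop = FALSE]
      writeDelim(res$qc, file.path(cfg$out_dir, "qc_metrics.csv"))
      writeDelim(data.frame(rule = names(res$filter$report),
                            removed = res$filter$report),
                 file.path(cfg$out_dir, "qc_removals.csv"))
      list(n_cells_in = length(res$filter$keep),
           n_cells_kept = res$filter$n_kept, n_genes = ncol(counts))
    })
  }
  if ("enrichment" %in% cfg$stages && !is.null(cells)) {
    stage("enrichment", function() {
      res <- enrichmentGrid(cells, compartment = cfg$enrichment$compartment,
                            by = cfg$enrichment$by,
                            capNeglog10 = cfg$enrichment$cap_neglog10)
      writeDelim(res, file.path(cfg$out_dir, "enrichment.csv"))
      list(n_tests = nrow(res))
    })
  }
  if ("density" %in% cfg$stages && !is.null(cells) &&
      all(c("dim1", "dim2") %in% names(cells))) {
    stage("density", function() {
      maps <- statusDensityMaps(cells, nGrid = cfg$density$n_grid,
                                group = cfg$density$group)
      dens <- do.call(rbind, lapply(names(maps$densities), function(s)
        cbind(status = s, gridToLong(maps$densities[[s]]))))
      ctr <- do.call(rbind, lapply(names(maps$contrasts), function(p)
        cbind(pair = p, gridToLong(maps$contrasts[[p]]))))
      writeDelim(dens, file.path(cfg$out_dir, "density.csv"))
      writeDelim(ctr, file.path(cfg$out_dir, "density_contrast.csv"))
      list(n_statuses = length(maps$densities),
           n_nodes = nrow(gridToLong(maps$densities[[1]])))
    })
  }
  if ("scoring" %in% cfg$stages && !is.null(counts)) {
    stage("scoring", function() {
      sets <- if (!is.null(cfg$inputs$gene_sets))
        readGeneSetsJson(cfg$inputs$gene_sets) else bundledGeneSets()
      sets <- Filter(function(s)
        length(intersect(s$genes, colnames(counts))) > 0, sets)
      scores <- suppressWarnings(lapply(sets, function(s)
        aucellScore(counts, s, topFraction = cfg$scoring$top_fraction,
                    randomTies = cfg$scoring$random_ties,
                    seed = cfg$seed)))
      out <- data.frame(cell_id = rownames(counts),
                        do.call(cbind, lapply(scores, as.numeric)),
                        check.names = FALSE)
      writeDelim(out, file.path(cfg$out_dir, "signature_scores.csv"))
      list(n_sets = length(scores), n_cells = nrow(out))
    })
  }
  if ("repertoire" %in% cfg$stages && !is.null(cfg$inputs$airr)) {
    stage("repertoire", function() {
      chains <- readAirr(cfg$inputs$airr)
      asg <- if (cfg$repertoire$receptor == "tcr")
        defineTcrClonotypes(chains)
      else {
        thr <- cfg$repertoire$threshold
        if (identical(thr, "auto")) thr <- estimateBcrThreshold(chains)
        defineBcrClonotypes(chains, as.numeric(thr))
      }
      writeDelim(assignedCells(asg),
                 file.path(cfg$out_dir, "clonotypes.csv"))
      if (!is.null(cells)) {
        groups <- split(cells$cell_id, cells$tls_status)
        div <- do.call(rbind, lapply(names(groups), function(g)
          tryCatch(clonalDiversity(asg, groups[[g]], g),
                   error = function(e) NULL)))
        if (!is.null(div))
          writeDelim(div, file.path(cfg$out_dir, "diversity.csv"))
        sm <- sharingMatrix(asg, cells)
        writeDelim(data.frame(cluster = rownames(sharingCounts(sm)),
                              as.data.frame(sharingCounts(sm)),
                              check.names = FALSE),
                   file.path(cfg$out_dir, "sharing.csv"))
      }
      list(n_chains = nrow(chains),
           n_clonotypes = length(cloneSizes(asg)),
           n_expanded = sum(cloneSizes(asg) >= 2L))
    })
  }
  if ("cooccurrence" %in% cfg$stages && !is.null(cfg$inputs$spots)) {
    stage("cooccurrence", function() {
      abund <- readSpots(cfg$inputs$spots)
      m <- cooccurrenceMatrix(abund)
      writeDelim(cooccurrenceToLong(m),
                 file.path(cfg$out_dir, "cooccurrence.csv"))
      list(n_spots = nrow(abund), n_types = ncol(abund))
    })
  }
  if ("proximity" %in% cfg$stages && !is.null(cfg$inputs$points)) {
    stage("proximity", function() {
      pts <- readPoints(cfg$inputs$points)
      pairs <- cfg$proximity$pairs
      if (is.null(pairs)) {
        ph <- unique(pts$phenotype)
        pairs <- expand.grid(from = ph, to = ph,
                             stringsAsFactors = FALSE)
        pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
      }
      res <- proximitySummary(pts, as.data.frame(pairs),
                              pool = cfg$proximity$pool)
      writeDelim(res, file.path(cfg$out_dir, "proximity.csv"))
      list(n_cores = length(unique(pts$core_id)), n_rows = nrow(res))
    })
  }

  outFiles <- list.files(cfg$out_dir, full.names = TRUE,
                         pattern = "\\.csv$")
  manifest$outputs <- as.list(tools::md5sum(outFiles))
  names(manifest$outputs) <- basename(outFiles)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Write a complete synthetic demonstration data set
#'
#' Generates every pipeline input with the synthetic module at the demo
#' scale — 3 TLS statuses x 4 samples x 2,000 cells with planted
#' compositional effects and a planted chemokine-signature elevation in
#' mature-TLS cells, a TCR repertoire with cross-cluster sharing, 300
#' spatial spots with one co-localized type pair, and 6 imaging cores
#' where the mature-status cores carry co-clustered phenotypes — writes
#' them to `dir` together with a JSON ground-truth sidecar, and returns a
#' ready-to-run pipeline config pointing at them.
#'
#' @param dir output directory.
#' @param seed integer master seed.
#' @return a [pipelineConfig()] list.
#' @export
writeSyntheticDemo <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clusters <- c("c1_naive", "c2_stem", "c3_effector", "c4_tex",
                "c5_treg", "c6_b")
  cspec <- compositionSpec(
    clusters = clusters,
    baseProportions = c(0.25, 0.2, 0.2, 0.15, 0.1, 0.1),
    plantedLog2OR = data.frame(
      cluster = c("c2_stem", "c4_tex", "c6_b"),
      status = c("mTLS", "imTLS", "mTLS"),
      log2_or = c(2, -2, 1)),
    clusterLineage = stats::setNames(c(rep("T", 5), "B"), clusters),
    seed = childSeed(seed, 1L))
  cells <- simulateComposition(cspec)
  # planted embedding: cluster-specific modes, mTLS stem cells shifted
  set.seed(childSeed(seed, 2L))
  modes <- cbind(x = stats::rnorm(length(clusters), sd = 4),
                 y = stats::rnorm(length(clusters), sd = 4))
  rownames(modes) <- clusters
  cells$dim1 <- modes[cells$subcluster, "x"] + stats::rnorm(nrow(cells))
  cells$dim2 <- modes[cells$subcluster, "y"] + stats::rnorm(nrow(cells))
  shift <- cells$subcluster == "c2_stem" & cells$tls_status == "mTLS"
  cells$dim1[shift] <- cells$dim1[shift] + 1.5
  cells$signature_positive <- cells$tls_status == "mTLS"
  writeCellTable(cells, file.path(dir, "cells.csv"))

  counts <- simulateExpression(cells, bundledGeneSets()$chemokine12,
                               effect = 2, nbDispersion = 2,
                               seed = childSeed(seed, 3L),
                               nGenes = 1000L, nMitoGenes = 10L)
  writeCounts(counts, file.path(dir, "counts"))
  set.seed(childSeed(seed, 4L))
  ds <- data.frame(cell_id = cells$cell_id,
                   doublet_score = stats::rbeta(nrow(cells), 1, 30))
  writeDelim(ds, file.path(dir, "doublet_scores.csv"))

  tcells <- cells[cells$lineage == "T", ]
  rep <- simulateRepertoire(tcells, repertoireSpec(
    cloneSizeExponent = 2.5, nClonotypes = 400L,
    sharingProb = data.frame(cluster_a = "c2_stem",
                             cluster_b = "c3_effector", prob = 0.3),
    ambiguousFrac = 0.02, multichainFrac = 0.02,
    seed = childSeed(seed, 5L)))
  writeAirr(rep$chains, file.path(dir, "chains.tsv"))

  spots <- simulateSpots(spotSpec(
    nSpots = 300L,
    cellTypes = c("B", "CD4T", "CD8T", "DC", "tumor"),
    baseConcentration = c(B = 1, CD4T = 1.5, CD8T = 1.5, DC = 0.8,
                          tumor = 4),
    colocalizedPairs = data.frame(type_a = "B", type_b = "CD4T",
                                  rho = 1.5),
    seed = childSeed(seed, 6L)))
  writeSpots(spots, file.path(dir, "spots.csv"))

  pts <- simulatePoints(pointSpec(
    nCores = 6L, coreStatus = rep(tlsStatuses(), each = 2L),
    phenotypes = data.frame(
      phenotype = c("CD4_TexProgTfh", "B", "tumor"),
      clustered = c(TRUE, TRUE, FALSE),
      intensity = c(3e-5, 3e-5, 3e-4),
      offspringPerParent = c(15, 15, NA),
      clusterRadius = c(20, 20, NA),
      parentGroup = c("tls", "tls", NA)),
    seed = childSeed(seed, 7L)))
  writePoints(pts, file.path(dir, "points.csv"))

  writeGroundTruth(list(composition = cspec,
                        sharing_prob = 0.3,
                        colocalized = list(pair = c("B", "CD4T"),
                                           rho = 1.5),
                        signature_effect = 2),
                   file.path(dir, "ground_truth.json"))

  pipelineConfig(list(
    seed = seed, out_dir = file.path(dir, "out"),
    inputs = list(cell_table = file.path(dir, "cells.csv"),
                  counts_dir = file.path(dir, "counts"),
                  doublet_scores = file.path(dir, "doublet_scores.csv"),
                  airr = file.path(dir, "chains.tsv"),
                  spots = file.path(dir, "spots.csv"),
                  points = file.path(dir, "points.csv"))))
}
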