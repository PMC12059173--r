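test_that("composition generator is deterministic and respects null effects", {
  spec <- compositionSpec(clusters = c("a", "b"), baseProportions = c(.6, .4),
                          samplesPerStatus = 2, cellsPerSample = 1500,
                          seed = 5)
  c1 <- simulateComposition(spec)
  c2 <- simulateComposition(spec)
  expect_identical(c1, c2)
  # null effects: per-status frequencies agree within multinomial error
  freq <- prop.table(table(c1$tls_status, c1$subcluster), 1)
  expect_true(all(abs(freq[, "a"] - 0.6) < 4 * sqrt(.6 * .4 / 3000)))
})

test_that("planted log2 odds ratios are recovered by the enrichment model", {
  spec <- compositionSpec(
    statuses = c("nTLS", "mTLS"), samplesPerStatus = 1,
    cellsPerSample = 8000, clusters = c("hit", "bg1", "bg2"),
    baseProportions = c(0.2, 0.4, 0.4),
    plantedLog2OR = data.frame(cluster = "hit", status = "mTLS",
                               log2_or = 2),
    seed = 11)
  ests <- vapply(1:20, function(r) {
    spec$seed <- 100 + r
    cells <- simulateComposition(spec)
    fitClusterEnrichment(cells, "hit", c("mTLS", "nTLS"))$log2_or
  }, numeric(1))
  expect_lt(abs(mean(ests) - 2), 0.1)
})

test_that("impossible planted effects fail to normalize", {
  spec <- compositionSpec(
    clusters = c("a", "b", "c"), baseProportions = c(.6, .3, .1),
    plantedLog2OR = data.frame(cluster = c("a", "b"),
                               status = "mTLS", log2_or = c(8, 8)),
    seed = 1)
  expect_error(simulateComposition(spec), "normalize")
})

test_that("expression generator plants a detectable signature elevation", {
  cells <- data.frame(cell_id = sprintf("c%03d", 1:400),
                      signature_positive = rep(c(TRUE, FALSE), each = 200))
  sig <- geneSet("sig", sprintf("SG%02d", 1:10))
  null <- simulateExpression(cells, sig, effect = 0, seed = 3,
                             nGenes = 150)
  sNull <- aucellScore(null, sig)
  expect_lt(abs(mean(sNull[1:200]) - mean(sNull[201:400])), 0.05)
  # one-sided recovery across seeds
  wins <- vapply(1:10, function(s) {
    m <- simulateExpression(cells, sig, effect = 5, seed = s,
                            nGenes = 150)
    sc <- aucellScore(m, sig)
    mean(sc[1:200]) > mean(sc[201:400])
  }, logical(1))
  expect_true(all(wins))
})

test_that("large dispersion approaches Poisson variance", {
  cells <- data.frame(cell_id = sprintf("c%04d", 1:3000))
  sig <- geneSet("sig", "SG1")
  m <- simulateExpression(cells, sig, effect = 0, nbDispersion = 1e6,
                          seed = 7, nGenes = 5)
  x <- as.matrix(m)
  ratio <- apply(x, 2, stats::var) / colMeans(x)
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("repertoire generator controls sharing, ambiguity and determinism", {
  cells <- data.frame(cell_id = sprintf("c%04d", 1:1000),
                      subcluster = rep(c("s1", "s2"), each = 500),
                      lineage = "T", stringsAsFactors = FALSE)
  specNull <- repertoireSpec(nClonotypes = 50, seed = 9)
  r1 <- simulateRepertoire(cells, specNull)
  expect_identical(r1, simulateRepertoire(cells, specNull))
  asg <- defineTcrClonotypes(r1$chains)
  sm <- sharingCounts(sharingMatrix(asg, cells))
  expect_identical(sm["s1", "s2"], 0L)  # disjoint repertoires

  specAmb <- repertoireSpec(nClonotypes = 50, ambiguousFrac = 0.1, seed = 13)
  r2 <- simulateRepertoire(cells, specAmb)
  cls <- classifyCells(r2$chains)
  nAmb <- sum(cls$receptor_class == "ambiguous")
  expect_lt(abs(nAmb - 100), 4 * sqrt(1000 * 0.1 * 0.9))
  expect_identical(sum(cls$receptor_class == "ambiguous"),
                   sum(r2$truth$true_class == "ambiguous"))

  expect_error(
    simulateRepertoire(cells, repertoireSpec(
      sharingProb = data.frame(cluster_a = "s1", cluster_b = "nope",
                               prob = .5))),
    "unknown cluster")
})

test_that("a steep clone-size exponent gives near-uniform repertoires", {
  cells <- data.frame(cell_id = sprintf("c%04d", 1:500),
                      subcluster = "s1", lineage = "T")
  r <- simulateRepertoire(cells, repertoireSpec(
    cloneSizeExponent = 12, nClonotypes = 400, seed = 21))
  asg <- defineTcrClonotypes(r$chains)
  div <- clonalDiversity(asg)
  expect_gt(div$shannon, 0.95 * log(div$n_clonotypes))
})

test_that("spot generator: independence at rho = 0 and absent types", {
  sp0 <- simulateSpots(spotSpec(nSpots = 4000,
                                cellTypes = c("A", "B", "C"),
                                baseConcentration = c(A = 2, B = 1, C = 0),
                                seed = 31))
  indep <- mean(sp0[, "A"]) * mean(sp0[, "B"]) * 1000
  score <- cooccurrenceScore(sp0, "A", "B")
  # Monte-Carlo agreement with the product of means
  expect_lt(abs(score - indep) / indep, 0.1)
  expect_identical(cooccurrenceScore(sp0, "A", "C"), 0)
  expect_identical(simulateSpots(spotSpec(nSpots = 50,
                                          cellTypes = "A", seed = 3)),
                   simulateSpots(spotSpec(nSpots = 50,
                                          cellTypes = "A", seed = 3)))
})

test_that("point generator: Poisson counts, determinism, planted clustering", {
  spec <- pointSpec(nCores = 1, coreStatus = "nTLS",
                    phenotypes = data.frame(
                      phenotype = "X", clustered = FALSE,
                      intensity = 5e-4),
                    window = c(0, 1000, 0, 1000), seed = 17)
  counts <- vapply(1:30, function(i) {
    spec$seed <- i
    nrow(simulatePoints(spec))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 500), 4 * sqrt(500 / 30))
  spec$seed <- 99L
  expect_identical(simulatePoints(spec), simulatePoints(spec))

  # clustered phenotypes sharing parents sit closer than CSR at equal counts
  closer <- vapply(1:20, function(s) {
    ps <- pointSpec(nCores = 1, coreStatus = "mTLS", phenotypes = data.frame(
      phenotype = c("cA", "cB", "rA", "rB"),
      clustered = c(TRUE, TRUE, FALSE, FALSE),
      intensity = c(2e-5, 2e-5, 3e-4, 3e-4),
      offspringPerParent = c(15, 15, NA, NA),
      clusterRadius = c(15, 15, NA, NA),
      parentGroup = c("g", "g", NA, NA)), seed = 1000 + s)
    pts <- simulatePoints(ps)
    md <- function(a, b) median(nnDistance(pts, a, b), na.rm = TRUE)
    md("cA", "cB") < md("rA", "rB")
  }, logical(1))
  expect_gte(sum(closer), 18)
})
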