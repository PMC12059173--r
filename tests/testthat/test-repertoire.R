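test_that("receptor-class rules match their definitions", {
  chains <- rbind(
    chainRow("amb", "TRA", "AAA"), chainRow("amb", "TRB", "CCC"),
    chainRow("amb", "IGH", "GGG"),
    chainRow("mc", "TRA", "AAA"), chainRow("mc", "TRA", "AAC"),
    chainRow("mc", "TRB", "CCA"), chainRow("mc", "TRB", "CCC"),
    chainRow("mc", "TRB", "CCG"),
    chainRow("tcr", "TRA", "AAA"), chainRow("tcr", "TRB", "CCC"),
    chainRow("sec", "TRA", "AAA"), chainRow("sec", "TRA", "AAC"),
    chainRow("sec", "TRB", "CCC"),
    chainRow("bcr", "IGH", "GGG"), chainRow("bcr", "IGK", "TTT"))
  cls <- classifyCells(chains)
  got <- stats::setNames(cls$receptor_class, cls$cell_id)
  expect_identical(got[["amb"]], "ambiguous")   # both receptor classes
  expect_identical(got[["mc"]], "multichain")   # three beta chains
  expect_identical(got[["tcr"]], "TCR")
  expect_identical(got[["sec"]], "TCR")         # secondary alpha allowed
  expect_identical(got[["bcr"]], "BCR")
  expect_warning(classifyCells(rbind(chains, chainRow("tcr", "TRA", "AAA"))),
                 "duplicate")
  expect_error(classifyCells(chainRow("x", "TRG", "AAA")), "locus")
})

test_that("TCR clonotypes require exact identity on both arms", {
  chains <- rbind(
    chainRow("c1", "TRA", "AAAGGG"), chainRow("c1", "TRB", "CCCGGG"),
    chainRow("c2", "TRA", "AAAGGG"), chainRow("c2", "TRB", "CCCGGG"),
    chainRow("c3", "TRA", "AAATTT"), chainRow("c3", "TRB", "CCCGGG"),
    chainRow("c4", "TRA", "AAAGGG"))
  asg <- defineTcrClonotypes(chains)
  ac <- assignedCells(asg)
  ids <- stats::setNames(ac$clonotype_id, ac$cell_id)
  expect_identical(ids[["c1"]], ids[["c2"]])    # clonal pair
  expect_false(ids[["c3"]] == ids[["c1"]])      # same beta, other alpha
  expect_false(ids[["c4"]] == ids[["c1"]])      # single-arm key kept apart
  expect_equal(unname(cloneSizes(asg)[ids[["c1"]]]), 2L)
})

test_that("TCR partition equals brute-force grouping and ignores row order", {
  for (seed in 1:5) {
    chains <- randomTcrFixture(40, seed)
    asg <- defineTcrClonotypes(chains)
    ac <- assignedCells(asg)
    ac <- ac[!is.na(ac$clonotype_id), ]
    got <- stats::setNames(ac$clonotype_id, ac$cell_id)
    brute <- bruteForceTcrPartition(chains, names(got))
    expect_true(samePartition(got, brute))
    shuf <- chains[sample(nrow(chains)), ]
    ac2 <- assignedCells(defineTcrClonotypes(shuf))
    ac2 <- ac2[!is.na(ac2$clonotype_id), ]
    got2 <- stats::setNames(ac2$clonotype_id, ac2$cell_id)
    expect_true(samePartition(got, got2[names(got)]))
  }
})

bcrChain <- function(cell, junction, v = "IGHV1-1", j = "IGHJ1") {
  rbind(chainRow(cell, "IGH", junction, v, j),
        chainRow(cell, "IGK", "TTTTTTTTT"))
}

test_that("BCR clustering follows single-linkage merges at the threshold", {
  # junctions of length 10: A-B distance .1, B-C .1, A-C .2
  jA <- "AAAAAAAAAA"; jB <- "AAAAAAAAAC"; jC <- "AAAAAAAACC"
  chains <- rbind(bcrChain("a", jA), bcrChain("b", jB), bcrChain("c", jC))
  asg <- defineBcrClonotypes(chains, threshold = 0.15)
  ids <- stats::setNames(assignedCells(asg)$clonotype_id,
                         assignedCells(asg)$cell_id)
  expect_true(ids[["a"]] == ids[["b"]] && ids[["b"]] == ids[["c"]])
  # without the intermediate, a and c split at the same threshold
  asg2 <- defineBcrClonotypes(rbind(bcrChain("a", jA), bcrChain("c", jC)),
                              threshold = 0.15)
  ids2 <- stats::setNames(assignedCells(asg2)$clonotype_id,
                          assignedCells(asg2)$cell_id)
  expect_false(ids2[["a"]] == ids2[["c"]])
  # identical junction, same V/J/length: one clonotype
  asg3 <- defineBcrClonotypes(rbind(bcrChain("a", jA), bcrChain("b", jA)),
                              threshold = 0.15)
  expect_equal(length(cloneSizes(asg3)), 1L)
})

test_that("threshold limits: 0 is identity, 1 merges each partition", {
  set.seed(10)
  juncs <- replicate(12, paste(sample(c("A", "C", "G", "T"), 9, TRUE),
                               collapse = ""))
  chains <- do.call(rbind, lapply(seq_along(juncs), function(i)
    bcrChain(sprintf("c%02d", i), juncs[i])))
  at0 <- defineBcrClonotypes(chains, 0)
  expect_equal(length(cloneSizes(at0)), length(unique(juncs)))
  at1 <- defineBcrClonotypes(chains, 1)
  expect_equal(length(cloneSizes(at1)), 1L)   # one V/J/length partition
  # different junction length: never merged
  mixed <- rbind(bcrChain("x", "AAAAAAAAA"), bcrChain("y", "AAAAAAAAAAAA"))
  expect_equal(length(cloneSizes(defineBcrClonotypes(mixed, 1))), 2L)
})

test_that("clonal threshold finds the valley of planted bimodality", {
  set.seed(11)
  base <- function() paste(sample(c("A", "C", "G", "T"), 45, TRUE),
                           collapse = "")
  mutate <- function(s, k) {
    pos <- sample(nchar(s), k)
    v <- strsplit(s, "")[[1]]
    v[pos] <- vapply(v[pos], function(ch)
      sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
    paste(v, collapse = "")
  }
  rows <- list()
  for (fam in 1:12) {
    anc <- base()
    for (m in 1:5)  # within-family nearest distance about 0.02-0.04
      rows[[length(rows) + 1L]] <-
        bcrChain(sprintf("f%02d_%d", fam, m), mutate(anc, 1))
    # an unrelated singleton at distance about 0.4 from the family
    rows[[length(rows) + 1L]] <-
      bcrChain(sprintf("f%02d_solo", fam), mutate(anc, 18))
  }
  chains <- do.call(rbind, rows)
  thr <- estimateBcrThreshold(chains)
  expect_false(attr(thr, "fallback"))
  expect_gt(as.numeric(thr), 0.05)
  expect_lt(as.numeric(thr), 0.4)
  # duplicating every sequence leaves the threshold unchanged
  dup <- chains
  dup$cell_id <- paste0(dup$cell_id, "_copy")
  thr2 <- estimateBcrThreshold(rbind(chains, dup))
  expect_equal(as.numeric(thr), as.numeric(thr2))
  # degenerate input falls back with a warning
  mono <- do.call(rbind, lapply(1:25, function(i)
    bcrChain(sprintf("m%02d", i), "AAAAAAAAA")))
  expect_warning(thrMono <- estimateBcrThreshold(mono), "falling back")
  expect_equal(as.numeric(thrMono), 0.15)
})

test_that("Shannon and D50 match hand-computed and enumerated values", {
  mono <- clonalDiversity(defineTcrClonotypes(tcrFixtureFromSizes(3)))
  expect_equal(mono$shannon, 0)
  expect_equal(mono$d50, 100)
  four <- clonalDiversity(defineTcrClonotypes(tcrFixtureFromSizes(
    c(1, 1, 1, 1))))
  expect_equal(four$shannon, log(4), tolerance = 1e-12)
  expect_equal(four$d50, 50)
  mixed <- clonalDiversity(defineTcrClonotypes(tcrFixtureFromSizes(
    c(5, 3, 1, 1))))
  p <- c(.5, .3, .1, .1)
  expect_equal(mixed$shannon, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(mixed$d50, 25)   # the top clone alone reaches 50%
})

test_that("diversity agrees with exhaustive enumeration (<= 6 cells, <= 3 clones)", {
  skip_if_not_installed("vegan")
  for (n in 1:6) {
    for (k in 1:min(n, 3)) {
      parts <- utils::combn(n - 1, k - 1, simplify = FALSE)
      sizeSets <- unique(lapply(parts, function(cuts)
        sort(diff(c(0, cuts, n)), decreasing = TRUE)))
      for (sizes in sizeSets) {
        got <- clonalDiversity(defineTcrClonotypes(
          tcrFixtureFromSizes(sizes)))
        oracle <- oracleDiversity(sizes)
        expect_equal(got$shannon, oracle$shannon, tolerance = 1e-12)
        expect_equal(got$d50, oracle$d50, tolerance = 1e-12)
        expect_equal(got$shannon,
                     as.numeric(vegan::diversity(sizes, "shannon")),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("sharing matrix equals brute-force set intersection", {
  cells <- data.frame(cell_id = sprintf("c%03d", 1:120),
                      subcluster = rep(c("k1", "k2", "k3"), 40),
                      tls_status = rep(c("nTLS", "mTLS"), each = 60),
                      stringsAsFactors = FALSE)
  r <- simulateRepertoire(cbind(cells, lineage = "T"),
                          repertoireSpec(nClonotypes = 15,
                                         sharingProb = data.frame(
                                           cluster_a = "k1",
                                           cluster_b = "k2", prob = .5),
                                         seed = 12))
  asg <- defineTcrClonotypes(r$chains)
  sm <- sharingMatrix(asg, cells)
  counts <- sharingCounts(sm)
  expect_true(isSymmetric(unname(counts)))
  ac <- assignedCells(asg)
  ac <- ac[!is.na(ac$clonotype_id), ]
  ac$cluster <- cells$subcluster[match(ac$cell_id, cells$cell_id)]
  members <- split(ac$cluster, ac$clonotype_id)
  for (i in rownames(counts)) for (j in colnames(counts)) {
    brute <- sum(vapply(members, function(m) i %in% m && j %in% m,
                        logical(1)))
    expect_identical(counts[i, j], as.integer(brute))
  }
  # removing a cluster never increases remaining entries
  cells2 <- cells[cells$subcluster != "k3", ]
  sm2 <- sharingCounts(sharingMatrix(asg, cells2))
  expect_true(all(sm2 <= counts[rownames(sm2), colnames(sm2)]))
  # per-status matrices sum no higher than the pooled matrix entry-wise
  for (s in names(sharingByStatus(sm)))
    expect_true(all(sharingByStatus(sm)[[s]] <= counts))
})

test_that("shared feature fraction counts spanning expanded clonotypes", {
  # 8 expanded clonotypes; 3 span both groups
  sizes <- rep(2, 8)
  chains <- tcrFixtureFromSizes(sizes)
  asg <- defineTcrClonotypes(chains)
  ac <- assignedCells(asg)
  ord <- unique(ac$clonotype_id)
  first <- !duplicated(ac$clonotype_id)
  grp <- ifelse(match(ac$clonotype_id, ord) <= 3,
                ifelse(first, "A", "B"),    # clones 1-3 span A and B
                "A")                        # clones 4-8 stay in A
  cells <- data.frame(cell_id = ac$cell_id, subcluster = grp,
                      sample_id = "s1", stringsAsFactors = FALSE)
  res <- sharedFeatureFraction(asg, cells, groupA = "A", groupB = "B")
  expect_equal(res$fraction, 3 / 8)
  expect_error(sharedFeatureFraction(asg, cells, "A", "A"), "disjoint")
  none <- sharedFeatureFraction(asg,
                                transform(cells, subcluster = "A"),
                                "A", "B")
  expect_equal(none$fraction, 0)
})
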