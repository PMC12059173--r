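test_that("distances match closed forms and the O(n^2) oracle", {
  pts <- data.frame(cell_id = c("p", "q"), x = c(0, 3), y = c(0, 4),
                    phenotype = "A")
  d <- pairwiseDistances(pts)
  expect_equal(d["p", "q"], 5)
  expect_equal(diag(d), c(p = 0, q = 0))
  # coincident distinct cells: off-diagonal zero allowed
  pts2 <- rbind(pts, data.frame(cell_id = "r", x = 0, y = 0,
                                phenotype = "A"))
  expect_equal(pairwiseDistances(pts2)["p", "r"], 0)
  set.seed(50)
  big <- data.frame(cell_id = sprintf("c%03d", 1:100),
                    x = runif(100, 0, 500), y = runif(100, 0, 500),
                    phenotype = "A")
  got <- pairwiseDistances(big)
  brute <- matrix(0, 100, 100)
  for (i in 1:100) for (j in 1:100)
    brute[i, j] <- sqrt((big$x[i] - big$x[j])^2 + (big$y[i] - big$y[j])^2)
  expect_equal(max(abs(unname(got) - brute)), 0, tolerance = 1e-12)
  expect_error(pairwiseDistances(big[1, ]), "at least two")
})

test_that("nearest-neighbour distances honour self-exclusion and ties", {
  pts <- data.frame(cell_id = c("a1", "a2", "b1", "b2"),
                    x = c(0, 10, 1, -1), y = c(0, 0, 0, 0),
                    phenotype = c("A", "A", "B", "B"))
  nn <- nnDistance(pts, "A", "B")
  expect_equal(unname(nn), c(1, 9))     # a1 ties at 1 on both sides
  # from == to with a single cell: no neighbour
  solo <- data.frame(cell_id = "s", x = 0, y = 0, phenotype = "S")
  expect_true(is.na(nnDistance(solo, "S", "S")))
  # coincident distinct cells count at distance zero
  co <- data.frame(cell_id = c("u", "v"), x = c(2, 2), y = c(3, 3),
                   phenotype = "S")
  expect_equal(unname(nnDistance(co, "S", "S")), c(0, 0))
  miss <- nnDistance(pts, "A", "Z")
  expect_length(miss, 0)
  expect_identical(attr(miss, "missing_phenotype"), "Z")
})

test_that("nn distances agree with the pairwise-matrix route exactly", {
  set.seed(51)
  pts <- data.frame(cell_id = sprintf("c%03d", 1:120),
                    x = runif(120, 0, 300), y = runif(120, 0, 300),
                    phenotype = sample(c("A", "B"), 120, TRUE))
  nn <- nnDistance(pts, "A", "B")
  dmat <- pairwiseDistances(pts)
  viaMatrix <- apply(dmat[pts$phenotype == "A", pts$phenotype == "B",
                          drop = FALSE], 1L, min)
  expect_identical(unname(nn), unname(viaMatrix))
  # asymmetry is permitted
  nnBA <- nnDistance(pts, "B", "A")
  expect_false(length(nn) == length(nnBA) &&
                 isTRUE(all.equal(sort(unname(nn)), sort(unname(nnBA)))))
})

test_that("distances are invariant to translation and rotation", {
  set.seed(52)
  pts <- data.frame(cell_id = sprintf("c%02d", 1:40),
                    x = runif(40, 0, 100), y = runif(40, 0, 100),
                    phenotype = rep(c("A", "B"), 20))
  base <- nnDistance(pts, "A", "B")
  theta <- 0.7
  rot <- transform(pts,
                   x = cos(theta) * x - sin(theta) * y + 55,
                   y = sin(theta) * x + cos(theta) * y - 12)
  expect_equal(unname(nnDistance(rot, "A", "B")), unname(base),
               tolerance = 1e-9)
})

test_that("proximity summaries report every core and flag missingness", {
  pts <- rbind(
    data.frame(core_id = "core01", tls_status = "mTLS",
               cell_id = c("a", "b"), x = c(0, 6), y = c(0, 8),
               phenotype = c("P", "Q")),
    data.frame(core_id = "core02", tls_status = "nTLS",
               cell_id = "c", x = 1, y = 1, phenotype = "P"))
  res <- proximitySummary(pts, data.frame(from = "P", to = "Q"))
  expect_equal(nrow(res), 2L)
  expect_equal(res$median_nn[res$core_id == "core01"], 10)  # 6-8-10
  expect_true(is.na(res$median_nn[res$core_id == "core02"]))
  pooled <- proximitySummary(pts, data.frame(from = "P", to = "Q"),
                             pool = TRUE)
  expect_true("pooled" %in% pooled$core_id)
})

test_that("co-clustered mature cores show smaller medians than CSR cores", {
  wins <- vapply(1:20, function(s) {
    spec <- pointSpec(
      nCores = 2, coreStatus = c("mTLS", "nTLS"),
      phenotypes = data.frame(
        phenotype = c("T", "B"), clustered = c(TRUE, TRUE),
        intensity = c(3e-5, 3e-5), offspringPerParent = c(10, 10),
        clusterRadius = c(15, 15), parentGroup = c("g", "g")),
      seed = 400 + s)
    pts <- simulatePoints(spec)
    # mature core keeps the planted clustering; control is resampled CSR
    ctrl <- pts[pts$core_id == "core02", ]
    set.seed(9000 + s)
    ctrl$x <- runif(nrow(ctrl), 0, 600)
    ctrl$y <- runif(nrow(ctrl), 0, 600)
    both <- rbind(pts[pts$core_id == "core01", ], ctrl)
    res <- proximitySummary(both, data.frame(from = "T", to = "B"))
    res$median_nn[res$tls_status == "mTLS"] <
      res$median_nn[res$tls_status == "nTLS"]
  }, logical(1))
  expect_gte(sum(wins), 18)
})
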