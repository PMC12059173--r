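test_that("a single point yields the closed-form Gaussian peak", {
  d <- estimateDensity2d(cbind(0, 0), gridBounds = c(-2, 2, -2, 2),
                         nGrid = 5, bandwidth = c(1, 1))
  # node (0,0) is the middle of a 5x5 grid on [-2,2]
  expect_equal(densityValues(d)[3, 3], 1 / (2 * pi), tolerance = 1e-12)
})

test_that("KDE is the mean of single-point densities", {
  set.seed(1)
  pts <- cbind(rnorm(8), rnorm(8))
  bw <- c(0.7, 0.9)
  joint <- estimateDensity2d(pts, gridBounds = c(-3, 3, -3, 3), nGrid = 9,
                             bandwidth = bw)
  singles <- lapply(seq_len(nrow(pts)), function(i)
    estimateDensity2d(pts[i, , drop = FALSE], gridBounds = c(-3, 3, -3, 3),
                      nGrid = 9, bandwidth = bw))
  avg <- Reduce(`+`, lapply(singles, densityValues)) / nrow(pts)
  expect_equal(densityValues(joint), avg, tolerance = 1e-12)
})

test_that("node values match the brute-force double loop", {
  set.seed(2)
  pts <- cbind(rnorm(50), rnorm(50, sd = 2))
  d <- estimateDensity2d(pts, gridBounds = c(-4, 4, -6, 6), nGrid = 20,
                         bandwidth = c(0.5, 0.8))
  brute <- bruteForceKde(pts, gridX(d), gridY(d), c(0.5, 0.8))
  expect_equal(max(abs(densityValues(d) - brute)), 0, tolerance = 1e-12)
})

test_that("automatic bandwidth follows the normal reference rule", {
  set.seed(3)
  pts <- cbind(rnorm(200), rnorm(200))
  d <- estimateDensity2d(pts)
  expect_equal(unname(bandwidth(d)),
               c(stats::bw.nrd(pts[, 1]), stats::bw.nrd(pts[, 2])))
  expect_warning(estimateDensity2d(cbind(rep(1, 5), rnorm(5))),
                 "degenerate")
  expect_error(estimateDensity2d(cbind(numeric(0), numeric(0))),
               "at least one point")
})

test_that("density mass on a padded grid is close to one", {
  set.seed(4)
  pts <- cbind(rnorm(100), rnorm(100))
  d <- estimateDensity2d(pts, nGrid = 120)  # default: +- 3 bandwidths
  cellArea <- diff(gridX(d))[1] * diff(gridY(d))[1]
  expect_gt(sum(densityValues(d)) * cellArea, 0.99)
})

test_that("independent KDE implementation reproduces the same surface", {
  skip_if_not_installed("MASS")
  set.seed(5)
  pts <- cbind(rnorm(60), rnorm(60))
  bw <- c(0.6, 0.6)
  d <- estimateDensity2d(pts, gridBounds = c(-3, 3, -3, 3), nGrid = 25,
                         bandwidth = bw)
  # MASS::kde2d divides its h by 4 to get the Gaussian sd
  ref <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * bw, n = 25,
                     lims = c(-3, 3, -3, 3))
  expect_equal(densityValues(d), ref$z, tolerance = 1e-10)
})

test_that("contrasts are antisymmetric, zero on self, and cycle to zero", {
  set.seed(6)
  cells <- data.frame(
    cell_id = sprintf("c%03d", 1:300), sample_id = "s",
    tls_status = rep(c("nTLS", "imTLS", "mTLS"), each = 100),
    subcluster = "x",
    dim1 = rnorm(300) + rep(c(0, 0.5, 1), each = 100),
    dim2 = rnorm(300))
  maps <- statusDensityMaps(cells, nGrid = 30)
  ab <- contrastValues(maps$contrasts[["imTLS_vs_nTLS"]])
  ba <- contrastValues(maps$contrasts[["nTLS_vs_imTLS"]])
  expect_identical(ab, -ba)
  bc <- contrastValues(maps$contrasts[["mTLS_vs_imTLS"]])
  ca <- contrastValues(maps$contrasts[["nTLS_vs_mTLS"]])
  expect_equal(max(abs(ab + bc + ca)), 0, tolerance = 1e-15)
  d1 <- maps$densities[["nTLS"]]
  self <- densityContrast(d1, d1, c("nTLS", "nTLS"))
  expect_true(all(contrastValues(self) == 0))
})

test_that("mismatched grids or bandwidths are rejected", {
  a <- estimateDensity2d(cbind(0, 0), gridBounds = c(-1, 1, -1, 1),
                         nGrid = 5, bandwidth = c(1, 1))
  b <- estimateDensity2d(cbind(0, 0), gridBounds = c(-2, 2, -2, 2),
                         nGrid = 5, bandwidth = c(1, 1))
  expect_error(densityContrast(a, b), "grids")
  c2 <- estimateDensity2d(cbind(0, 0), gridBounds = c(-1, 1, -1, 1),
                          nGrid = 5, bandwidth = c(2, 2))
  expect_error(densityContrast(a, c2), "andwidth")
})

test_that("a planted mode shift shows up in the status contrast", {
  set.seed(7)
  n <- 400
  cells <- data.frame(
    cell_id = sprintf("c%04d", 1:(2 * n)), sample_id = "s",
    tls_status = rep(c("nTLS", "mTLS"), each = n), subcluster = "x",
    dim1 = c(rnorm(n), rnorm(n) + 2), dim2 = rnorm(2 * n))
  maps <- statusDensityMaps(cells, nGrid = 40)
  ctr <- maps$contrasts[["mTLS_vs_nTLS"]]
  atMode <- which.min(abs(gridX(ctr) - 2))
  expect_gt(contrastValues(ctr)[atMode, which.min(abs(gridY(ctr)))], 0)
})
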