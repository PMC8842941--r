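test_that("affinity propagation handles degenerate sizes", {
  e <- affinityPropagation(matrix(numeric(), 0L, 2L))
  expect_equal(nClusters(e), 0L)
  one <- affinityPropagation(matrix(c(5, 5), 1L, 2L))
  expect_equal(nClusters(one), 1L)
  expect_equal(one@exemplars, 1L)
  expect_equal(clusterLabels(one), 1L)
})

test_that("duplicated far-apart pairs form two clusters", {
  pts <- rbind(c(0, 0), c(0, 0), c(50, 0), c(50, 0))
  cl <- affinityPropagation(pts)
  expect_equal(nClusters(cl), 2L)
  expect_equal(clusterLabels(cl)[1], clusterLabels(cl)[2])
  expect_equal(clusterLabels(cl)[3], clusterLabels(cl)[4])
})

test_that("AP matches the reference implementation on the 3-pair fixture", {
  ## scikit-learn AffinityPropagation (damping 0.5, same similarities)
  ## yields labels {0,0,1,1,2,2} on this fixture; frozen expected partition
  pts <- rbind(c(0, 0), c(1, 0), c(40, 0), c(41, 0), c(0, 40), c(1, 40))
  cl <- affinityPropagation(pts, damping = 0.5, retryDamping = numeric())
  expect_true(cl@converged)
  expect_equal(nClusters(cl), 3L)
  expect_equal(clusterLabels(cl), c(1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("AP recovers planted blobs and collapses at low preference", {
  b <- plantedBlobs(42)
  cl <- affinityPropagation(b$points, seed = 7)
  expect_gte(adjustedRandIndex(clusterLabels(cl), b$truth), 0.9)
  ## preference -> -inf limit yields a single cluster
  cl1 <- affinityPropagation(b$points, preference = -1e12, seed = 7)
  expect_equal(nClusters(cl1), 1L)
})

test_that("cluster descriptors match hand algebra", {
  one <- affinityPropagation(matrix(c(5, 5), 1, 2))
  d <- clusterDescriptors(one, matrix(c(5, 5), 1, 2))
  expect_equal(unname(d[c("dispersionMean", "extentMean", "bgss")]),
               c(0, 0, 0))
  ## two singleton clusters at distance d: BGSS = d^2 / 2
  pts <- rbind(c(0, 0), c(6, 8))     # distance 10
  cl <- new("APClustering", labels = c(1L, 2L), exemplars = c(1L, 2L),
            K = 2L, converged = TRUE, iterations = 0L)
  expect_equal(unname(clusterDescriptors(cl, pts)["bgss"]), 50)
  ## empty clustering flags everything missing
  d0 <- clusterDescriptors(affinityPropagation(matrix(numeric(), 0, 2)),
                           matrix(numeric(), 0, 2))
  expect_true(all(is.na(d0[-1])))
})

test_that("descriptors equal a per-cluster loop oracle on random labelings", {
  for (seed in 1:20) {
    inst <- randomClusteringInstance(seed)
    got <- clusterDescriptors(inst$clustering, inst$points)
    want <- oracleClusterDescriptors(inst$points, inst$labels)
    expect_equal(got, want[names(got)], tolerance = 1e-12)
  }
})

test_that("validity indices match hand-computable configurations", {
  ## two tight clusters with zero within-cluster variance
  pts <- rbind(c(0, 0), c(0, 0), c(10, 0), c(10, 0))
  cl <- new("APClustering", labels = c(1L, 1L, 2L, 2L),
            exemplars = c(1L, 3L), K = 2L, converged = TRUE,
            iterations = 0L)
  vi <- validityIndices(cl, pts)
  expect_equal(unname(vi["cIndex"]), 0)
  expect_equal(unname(vi["ballHall"]), 0)
  expect_true(is.infinite(vi["calinskiHarabasz"]))
  ## K = 1: separation indices flagged missing
  cl1 <- new("APClustering", labels = rep(1L, 4), exemplars = 1L, K = 1L,
             converged = TRUE, iterations = 0L)
  vi1 <- validityIndices(cl1, pts)
  expect_true(all(is.na(vi1[c("logSSRatio", "daviesBouldin",
                              "calinskiHarabasz", "cIndex")])))
  expect_false(is.na(vi1["ballHall"]))
})

test_that("all six indices equal the brute-force oracle", {
  for (seed in 1:20) {
    inst <- randomClusteringInstance(seed)
    got <- validityIndices(inst$clustering, inst$points)
    want <- oracleValidityIndices(inst$points, inst$labels)
    expect_equal(got, want[names(got)], tolerance = 1e-9)
  }
})

test_that("indices respect their geometric invariances", {
  inst <- randomClusteringInstance(99)
  vi <- validityIndices(inst$clustering, inst$points)
  ## translation + rotation invariance
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- inst$points %*% R + matrix(c(13, -8), nrow(inst$points), 2,
                                      byrow = TRUE)
  vi2 <- validityIndices(inst$clustering, moved)
  expect_equal(vi, vi2, tolerance = 1e-8)
  ## squared-distance scaling of BallHall; scale invariance of CIndex
  sc <- validityIndices(inst$clustering, 3 * inst$points)
  expect_equal(unname(sc["ballHall"]), unname(9 * vi["ballHall"]),
               tolerance = 1e-9)
  expect_equal(unname(sc["cIndex"]), unname(vi["cIndex"]),
               tolerance = 1e-9)
  expect_equal(unname(sc["daviesBouldin"]), unname(vi["daviesBouldin"]),
               tolerance = 1e-9)
  ## CIndex stays in [0, 1] whenever defined
  for (seed in 1:10) {
    i2 <- randomClusteringInstance(seed + 200)
    ci <- validityIndices(i2$clustering, i2$points)["cIndex"]
    expect_gte(ci, 0); expect_lte(ci, 1)
  }
})
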