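test_that("radius rule thresholds pair distances", {
  pts <- rbind(c(0, 0), c(0, 5))
  expect_equal(nrow(graphEdges(buildObjectGraph(pts, "radius", 10))), 1L)
  expect_equal(nrow(graphEdges(buildObjectGraph(pts, "radius", 4))), 0L)
  ## empty and singleton point sets are legal
  expect_equal(nNodes(buildObjectGraph(matrix(numeric(), 0, 2), "radius", 5)),
               0L)
})

test_that("radius edges equal brute-force all-pairs thresholding", {
  set.seed(15)
  pts <- matrix(runif(200, 0, 100), 100, 2)
  g <- buildObjectGraph(pts, "radius", 18)
  expect_equal(unname(graphEdges(g)), unname(oracleRadiusEdges(pts, 18)))
})

test_that("knn rule symmetrizes and clamps k", {
  pts <- matrix(c(0, 0, 1, 0, 10, 0), 3, 2, byrow = TRUE)
  g <- buildObjectGraph(pts, "knn", 1)
  ## 3's nearest is 2, so the symmetrized union contains (2,3)
  expect_true(any(g@edges[, 1] == 2 & g@edges[, 2] == 3))
  expect_warning(buildObjectGraph(pts, "knn", 5), "clamped")
  ## uniform scaling leaves knn degree features unchanged
  set.seed(4)
  p <- matrix(runif(60, 0, 50), 30, 2)
  f1 <- degreeFeatures(buildObjectGraph(p, "knn", 4))
  f2 <- degreeFeatures(buildObjectGraph(p * 7.3, "knn", 4))
  expect_equal(f1, f2)
})

test_that("delaunay edges of a convex quadrilateral are sides + diagonal", {
  ## general position (an exact square is cocircular, hence degenerate)
  pts <- rbind(c(0, 0), c(0, 10), c(10, 0), c(9, 11))
  g <- buildObjectGraph(pts, "delaunay")
  expect_equal(nrow(graphEdges(g)), 5L)
  ## two points: the single edge
  expect_equal(nrow(graphEdges(buildObjectGraph(pts[1:2, ], "delaunay"))), 1L)
})

test_that("degree features match closed forms on canonical graphs", {
  ## complete graph on 4 nodes
  pts <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  f <- degreeFeatures(buildObjectGraph(pts, "radius", 10))
  expect_equal(unname(f["degMean"]), 3)
  expect_equal(unname(f["degSd"]), 0)
  expect_equal(unname(f["fracIsolated"]), 0)
  expect_equal(unname(f["localClustering"]), 1)
  ## edgeless graph on 5 nodes
  pts5 <- cbind(seq(0, 400, 100), 0)
  f0 <- degreeFeatures(buildObjectGraph(pts5, "radius", 10))
  expect_equal(unname(f0["degMean"]), 0)
  expect_equal(unname(f0["fracIsolated"]), 1)
  expect_equal(unname(f0["degEntropy"]), 0)
})

test_that("degree features equal definition-level loops on random graphs", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    pts <- matrix(runif(2 * n, 0, 60), n, 2)
    g <- buildObjectGraph(pts, "radius", 20)
    got <- degreeFeatures(g)
    want <- oracleDegreeFeatures(n, graphEdges(g))
    expect_equal(got, want[names(got)], tolerance = 1e-9)
    ## handshake lemma
    expect_equal(sum(nodeDegrees(g)), 2L * nrow(graphEdges(g)))
  }
})

test_that("degree features are invariant under node relabeling", {
  set.seed(31)
  pts <- matrix(runif(40, 0, 50), 20, 2)
  perm <- sample(20)
  f1 <- degreeFeatures(buildObjectGraph(pts, "radius", 15))
  f2 <- degreeFeatures(buildObjectGraph(pts[perm, ], "radius", 15))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("homogeneity features behave on canonical patterns", {
  ## regular lattice: Clark-Evans ratio > 1
  g <- as.matrix(expand.grid(seq(25, 475, 50), seq(25, 475, 50)))
  hf <- homogeneityFeatures(g, width = 500, height = 500)
  expect_gt(hf["clarkEvans"], 1)
  ## coincident points: zero NN distance
  co <- matrix(5, 4, 2)
  expect_equal(unname(homogeneityFeatures(co, 100, 100)["nnMean"]), 0)
  expect_error(homogeneityFeatures(g, width = 0, height = 10), "positive")
  ## fewer than 2 points: flagged missing
  expect_true(all(is.na(homogeneityFeatures(matrix(1, 1, 2), 10, 10))))
})

test_that("Clark-Evans ratio is near 1 under spatial randomness", {
  set.seed(77)
  r <- replicate(100, {
    pts <- cbind(runif(500, 0, 1000), runif(500, 0, 1000))
    homogeneityFeatures(pts, 1000, 1000)["clarkEvans"]
  })
  expect_equal(mean(r), 1, tolerance = 0.1)
  ## quadrat dispersion index also near 1 under CSR
  set.seed(78)
  q <- replicate(50, {
    pts <- cbind(runif(400, 0, 800), runif(400, 0, 800))
    homogeneityFeatures(pts, 800, 800)["quadratDispersion"]
  })
  expect_equal(mean(q), 1, tolerance = 0.15)
})
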