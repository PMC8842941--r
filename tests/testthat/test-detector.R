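test_that("patch extraction assigns the rank-weight mapping", {
  ann <- AnnotationSet(geometry = list(cbind(200, 200)),
                       class = "foreground", rank = "definite",
                       height = 400L, width = 400L)
  p <- extractPatches(NULL, ann, nNegatives = 1L, seed = 2)
  expect_equal(nrow(p), 2L)
  expect_equal(sort(p$weight), c(1L, 5L))
  expect_equal(p$label[p$weight == 5L], "LTS")
  ## empty annotations: all negatives, weight 1
  empty <- AnnotationSet(height = 400L, width = 400L)
  p0 <- extractPatches(NULL, empty, nNegatives = 10L, seed = 3)
  expect_equal(nrow(p0), 10L)
  expect_true(all(p0$weight == 1L & p0$label == "other"))
})

test_that("overlapping objects take the maximum rank weight", {
  ## probable object whose window also touches a definite neighbour
  ann <- AnnotationSet(
    geometry = list(cbind(200, 200), cbind(200, 240)),
    class = c("foreground", "foreground"),
    rank = c("probable", "definite"), height = 400L, width = 400L)
  p <- extractPatches(NULL, ann, nNegatives = 0L, seed = 1)
  expect_true(all(p$weight == 5L))
  ## a replay background object yields weight 2 negatives
  ann2 <- AnnotationSet(geometry = list(cbind(200, 200)),
                        class = "background", rank = NA_integer_,
                        height = 302L, width = 302L,
                        source = "false_positive_replay")
  p2 <- extractPatches(NULL, ann2, nNegatives = 5L, seed = 1)
  expect_true(all(p2$label == "other"))
  expect_true(any(p2$weight == 2L))
})

test_that("border objects are clamped inward and logged", {
  ann <- AnnotationSet(geometry = list(cbind(3, 3)), class = "foreground",
                       rank = "definite", height = 302L, width = 302L)
  p <- extractPatches(NULL, ann, nNegatives = 0L)
  expect_equal(attr(p, "clamped"), 1L)
  expect_true(p$row[1] >= 75 && p$col[1] >= 75)
})

test_that("the weighted loss contract holds exactly", {
  p <- c(0.3, 0.3)
  y <- c(1, 1)
  l <- weightedCrossEntropy(p, y, c(5, 1))
  expect_equal(l[1], 5 * l[2], tolerance = 1e-15)
  ## all weights 1 equals unweighted cross-entropy
  set.seed(6)
  pp <- runif(50, 0.01, 0.99); yy <- rbinom(50, 1, 0.5)
  expect_equal(weightedCrossEntropy(pp, yy, rep(1, 50)),
               -(yy * log(pp) + (1 - yy) * log(1 - pp)),
               tolerance = 1e-12)
})

test_that("training rejects single-class input and is deterministic", {
  tr <- separableSlidePatches(301, nNegatives = 10L)
  pos <- tr[tr$label == "LTS", ]
  expect_error(trainPatchClassifier(pos, trainConfig(epochs = 1)),
               "both classes")
  cfg <- trainConfig(learningRate = 0.01, epochs = 3, seed = 11)
  m1 <- trainPatchClassifier(tr, cfg)
  m2 <- trainPatchClassifier(tr, cfg)
  expect_identical(predictProba(m1, tr$window),
                   predictProba(m2, tr$window))
})

test_that("augmented training accepts the documented augmentation set", {
  tr <- separableSlidePatches(305, nNegatives = 10L)
  cfg <- trainConfig(learningRate = 0.01, epochs = 2, seed = 4,
                     augmentations = c("rotate", "flip", "brightness"))
  m <- trainPatchClassifier(tr, cfg)
  expect_s4_class(m, "PatchClassifier")
  expect_error(trainConfig(augmentations = "warp"), "augmentations")
})

test_that("sliding-window starts follow the stride geometry", {
  img <- array(200, c(311, 311, 3))
  res <- inferSlide(function(w) 0, img)
  expect_equal(res$starts$col, c(0, 40, 80, 120, 160))
  expect_equal(sum(res$grid@positive), 0L)     # constant-0 model
  expect_error(inferSlide(function(w) 0, img, stride = 0), "stride")
})

test_that("oracle-model inference matches brute-force window geometry", {
  h <- w <- 440L
  img <- array(200, c(h, w, 3))
  obj <- c(222, 287)     # planted object position (row, col), 0-based
  ## the object pixel carries a distinct intensity; the oracle scorer fires
  ## exactly when its window contains that pixel
  img[obj[1] + 1L, obj[2] + 1L, ] <- 0
  oracle <- function(win) as.numeric(min(win) == 0)
  res <- inferSlide(oracle, img)
  expect_equal(positiveCells(res$grid),
               oracleOracleCells(h, w, obj[1], obj[2]),
               ignore_attr = TRUE)
  ## positive cell count is non-increasing in the threshold
  n1 <- sum(inferSlide(oracle, img, threshold = 0.2)$grid@positive)
  n2 <- sum(inferSlide(oracle, img, threshold = 0.9)$grid@positive)
  expect_gte(n1, n2)
})

test_that("detection metrics match their definitions", {
  m <- detectionMetrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_true(all(unlist(m) == 1))
  ## the F1 identity at the published precision/recall operating point
  expect_equal(round(f1Score(0.81, 0.99), 2), 0.89)
  ## undefined sensitivity flagged when truth has no positives
  m2 <- detectionMetrics(c(0, 1), c(0, 0))
  expect_true(is.na(m2$sensitivity))
  ## permutation invariance
  set.seed(9)
  pred <- rbinom(40, 1, 0.4); truth <- rbinom(40, 1, 0.5)
  perm <- sample(40)
  expect_equal(detectionMetrics(pred, truth),
               detectionMetrics(pred[perm], truth[perm]))
})

test_that("rank AUC equals explicit pair counting", {
  set.seed(10)
  for (i in 1:20) {
    n <- 30L
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2L) truth[1:2] <- c(0L, 1L)
    scores <- round(runif(n), 2)      # coarse scores force ties
    expect_equal(rankAuc(scores, truth), oracleAuc(scores, truth),
                 tolerance = 1e-12)
  }
  ## one flip among 100 balanced items, scores = labels
  truth <- rep(c(0, 1), 50)
  scores <- truth; scores[1] <- 1 - scores[1]
  expect_equal(rankAuc(scores, truth), oracleAuc(scores, truth),
               tolerance = 1e-12)
})

test_that("the reference classifier separates clear patches", {
  tr <- rbind(separableSlidePatches(401, 25L), separableSlidePatches(402, 25L))
  te <- separableSlidePatches(403, 25L)
  m <- trainPatchClassifier(tr, trainConfig(learningRate = 0.01,
                                            epochs = 40, hidden = 24L,
                                            augmentations = c("rotate",
                                                              "flip"),
                                            seed = 5))
  acc <- mean((predictProba(m, te$window) >= 0.5) == (te$label == "LTS"))
  expect_gte(acc, 0.9)
})
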