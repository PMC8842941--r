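test_that("subject aggregation takes feature-wise max, skipping missing", {
  df <- data.frame(subjectId = c("a", "a", "a", "b"),
                   f1 = c(1, 5, 3, 2), f2 = c(2, NA, NA, NA))
  ag <- aggregateSubjects(df)
  expect_equal(ag$f1, c(5, 2))
  expect_equal(ag$f2, c(2, NA_real_))
  ## single slide is the identity
  one <- aggregateSubjects(df[4, ])
  expect_equal(one$f1, 2)
  ## alternative statistics
  expect_equal(aggregateSubjects(df, "min")$f1, c(1, 2))
  expect_equal(aggregateSubjects(df, "mean")$f1, c(3, 2))
})

test_that("feature matrix completion imputes and drops constants", {
  X <- cbind(a = c(1, NA, 3), b = c(2, 2, 2), c = c(0, 1, Inf))
  M <- completeFeatureMatrix(X)
  expect_equal(colnames(M), c("a", "c"))
  expect_equal(unname(M[2, "a"]), 0)
  expect_equal(unname(M[3, "c"]), 0)
})

test_that("repeated LASSO recovers a planted signal feature", {
  set.seed(41)
  n <- 56L; p <- 20L
  y <- rep(c(0L, 1L), c(14L, 42L))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  X[, 7] <- y + rnorm(n, 0, 0.1)          # planted
  sel <- repeatedLassoSelection(X, y, nRepeats = 100, seed = 5)
  expect_gte(sel$frequency[sel$feature == "f7"], 0.9)
  expect_equal(sel$feature[1], "f7")
  ## frequencies are proper proportions
  expect_true(all(sel$frequency >= 0 & sel$frequency <= 1))
})

test_that("pure-noise features are not selected stably", {
  set.seed(42)
  n <- 56L; p <- 60L
  y <- rep(c(0L, 1L), c(14L, 42L))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  sel <- repeatedLassoSelection(X, y, nRepeats = 200, seed = 6)
  expect_lt(max(sel$frequency), 0.6)
})

test_that("a single repeat yields binary frequencies and reproducibility", {
  set.seed(43)
  X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(0:1, 20)
  s1 <- repeatedLassoSelection(X, y, nRepeats = 1, seed = 9)
  expect_true(all(s1$frequency %in% c(0, 1)))
  s2 <- repeatedLassoSelection(X, y, nRepeats = 1, seed = 9)
  expect_identical(s1, s2)
})

test_that("elastic-net prediction is near-perfect on separable cohorts", {
  set.seed(44)
  n <- 56L
  y <- rep(c(0L, 1L), c(14L, 42L))
  X <- cbind(sig = y * 3 + rnorm(n, 0, 0.2),
             noise = rnorm(n))
  fit <- fitPredictElasticnet(X, y, nRepeats = 60, seed = 2)
  expect_gte(fit$summary$mean[fit$summary$metric == "accuracy"], 0.99)
  ## determinism of the whole repeated protocol
  fit2 <- fitPredictElasticnet(X, y, nRepeats = 60, seed = 2)
  expect_identical(fit$perRepeat, fit2$perRepeat)
})

test_that("label shuffling drops accuracy to the class prior", {
  set.seed(45)
  n <- 56L
  y <- rep(c(0L, 1L), c(14L, 42L))
  X <- cbind(sig = y * 3 + rnorm(n, 0, 0.2), noise = rnorm(n))
  ysh <- sample(y)
  fit <- fitPredictElasticnet(X, ysh, nRepeats = 60, seed = 3)
  prior <- max(mean(y), 1 - mean(y))
  expect_equal(fit$summary$mean[fit$summary$metric == "accuracy"], prior,
               tolerance = 0.1)
})

test_that("stage prediction separates an ordinal encoding and nulls out", {
  set.seed(46)
  stage <- rep(0:3, c(14, 15, 13, 14))
  X <- cbind(ord = stage * 2 + rnorm(56, 0, 0.1), noise = rnorm(56))
  res <- predictStage(X, stage, nRepeats = 40, seed = 4)
  expect_gte(res[["0-3"]]$mean, 0.95)
  expect_equal(res[["1-3"]]$n, 42L)           # controls excluded
  ## balanced random labels: accuracy near 1/4 (absolute band)
  set.seed(47)
  ystar <- sample(rep(0:3, 14))
  Xn <- matrix(rnorm(56 * 4), 56, 4)
  resN <- predictStage(Xn, ystar, variants = "0-3", nRepeats = 40, seed = 5)
  expect_lt(abs(resN[["0-3"]]$mean - 0.25), 0.15)
})

test_that("expert-score derivatives follow the rubric", {
  sc <- data.frame(subjectId = c("s1", "s1", "s1", "s2"),
                   score = c(0L, 1L, 3L, 2L))
  b <- expertScoreBaseline(sc)
  expect_equal(b$maxScore, c(3, 2))
  expect_equal(b$meanScore, c(4 / 3, 2))
  expect_equal(b$nPositive, c(2, 1))
  expect_equal(b$anyPositive, c(TRUE, TRUE))
  allz <- expertScoreBaseline(data.frame(subjectId = "s", score = c(0, 0, 0)))
  expect_equal(allz$maxScore, 0)
  expect_false(allz$anyPositive)
  expect_error(expertScoreBaseline(data.frame(subjectId = "s", score = 4)),
               "0, 1, 2, 3")
})

test_that("duplicating a feature does not raise the original's frequency", {
  set.seed(48)
  n <- 56L
  y <- rep(c(0L, 1L), c(14L, 42L))
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  X[, 1] <- y + rnorm(n, 0, 0.15)
  f1 <- repeatedLassoSelection(X, y, nRepeats = 80, seed = 7)
  Xdup <- cbind(X, dup = X[, 1] + rnorm(n, 0, 1e-6))
  f2 <- repeatedLassoSelection(Xdup, y, nRepeats = 80, seed = 7)
  freq1 <- f1$frequency[f1$feature == "f1"]
  freq2 <- f2$frequency[f2$feature == "f1"]
  expect_lte(freq2, freq1 + 0.05)
})
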