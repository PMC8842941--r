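test_that("empty slide spec yields a clean slide with no foreground", {
  sp <- slideSpec(nDefinite = 0, nProbable = 0, nPossible = 0,
                  nBackground = 0, seed = 5)
  sl <- generateSlide(sp)
  expect_equal(max(sl@dabField), 0)
  expect_equal(nObjects(sl@annotations), 0L)
  ## image equals pure hematoxylin rendering: white outside tissue
  expect_true(all(sl@image[!sl@tissue] == 255 |
                    abs(sl@image[rep(!sl@tissue, 3)] - 255) < 1e-9))
})

test_that("slide generation is deterministic and conserves object counts", {
  sp <- slideSpec(nDefinite = 10, nProbable = 0, nPossible = 0,
                  nBackground = 3, seed = 77)
  a <- generateSlide(sp)
  b <- generateSlide(sp)
  expect_identical(a@image, b@image)
  expect_identical(a@annotations@objects$geometry,
                   b@annotations@objects$geometry)
  fg <- a@annotations@objects[a@annotations@objects$class == "foreground", ]
  expect_equal(nrow(fg), 10L)
  expect_true(all(fg$rank == 3L))
  expect_equal(sum(a@annotations@objects$class == "background"), 3L)
  ## annotations-only call reproduces the same ground truth
  expect_identical(a@annotations,
                   generateSlide(sp, render = FALSE)@annotations)
})

test_that("slide spec validation rejects degenerate inputs", {
  expect_error(slideSpec(height = 200), "302")
  expect_error(slideSpec(nDefinite = -1), "non-negative")
  expect_error(slideSpec(dabRange = c(0, 1)), "positive")
})

test_that("controls have zero burden when their stage mean is zero", {
  spec <- cohortSpec(nControl = 3, nEarly = 2, nModerate = 2, nAdvanced = 2,
                     slidesPerSubject = 3,
                     stageBurdenMeans = c(0, 8, 8, 8), seed = 21)
  co <- generateCohort(spec, annotations = FALSE)
  ctrl <- co$slides[co$slides$stage == 0, ]
  expect_true(all(ctrl$nForeground == 0L))
  expect_true(all(ctrl$score == 0L))
})

test_that("the default cohort matches the study design counts", {
  spec <- cohortSpec(slidesPerSubject = 2, seed = 3)
  co <- generateCohort(spec, annotations = FALSE)
  expect_equal(nrow(co$subjects), 56L)
  expect_equal(table(co$subjects$stage),
               table(factor(rep(0:3, c(14, 15, 13, 14)))),
               ignore_attr = TRUE)
  expect_equal(nrow(co$slides), 56L * 2L)
  ## stage 0 <=> control status
  expect_equal(co$subjects$status, as.integer(co$subjects$stage > 0))
})

test_that("simulated clinical covariates couple to the true burden", {
  co <- generateCohort(cohortSpec(slidesPerSubject = 4, seed = 12),
                       annotations = FALSE)
  sdat <- spearmanRho(co$subjects$trueBurden, co$subjects$DAT_SBR)
  expect_lt(sdat$rho, 0)
  supdrs <- spearmanRho(co$subjects$trueBurden, co$subjects$UPDRS3)
  expect_gt(supdrs$rho, 0)
})

test_that("mean slide burden is non-decreasing across stages", {
  co <- generateCohort(cohortSpec(slidesPerSubject = 6, seed = 8),
                       annotations = FALSE)
  m <- tapply(co$slides$nForeground, co$slides$stage, mean)
  expect_true(all(diff(m) >= 0))
})

test_that("expert scores follow the count thresholds", {
  co <- generateCohort(cohortSpec(slidesPerSubject = 4, seed = 31),
                       annotations = FALSE)
  expected <- findInterval(co$slides$nForeground, c(1, 10, 50))
  expect_equal(co$slides$score, expected)
})

test_that("rater simulation honours the confusion matrix", {
  cats <- c("definite", "probable", "possible", "background")
  conf <- diag(4); dimnames(conf) <- list(cats, cats)
  truth <- sample(cats, 50, replace = TRUE)
  rt <- simulateRaters(truth, nRaters = 5, conf, seed = 4)
  expect_s4_class(rt, "RatingTable")
  expect_equal(dim(rt@ratings), c(50L, 5L))
  expect_true(all(rt@ratings == truth))       # identity reproduces truth
  ## 600 x 5 concordance-study shape
  rt600 <- simulateRaters(sample(cats, 600, replace = TRUE), 5, conf,
                          seed = 9)
  expect_equal(dim(rt600@ratings), c(600L, 5L))
  ## non-stochastic rows are rejected
  bad <- conf; bad[1, 1] <- 0.5
  expect_error(simulateRaters(truth, 3, bad, seed = 1), "probability")
})

test_that("stain round trip recovers the generator fields", {
  sp <- slideSpec(nDefinite = 6, nProbable = 4, nPossible = 3,
                  nBackground = 5, noiseSd = 0, seed = 14)
  m <- hdabStainModel()
  sl <- generateSlide(sp, model = m)
  ch <- deconvolveStains(odTransform(sl@image, m@background), m)
  expect_lt(max(abs(ch@hematoxylin - sl@hematoxylinField)), 1e-6)
  expect_lt(max(abs(ch@dab - sl@dabField)), 1e-6)
})
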