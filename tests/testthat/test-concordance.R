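test_that("Fleiss' kappa matches hand-computed reference cases", {
  expect_equal(fleissKappa(RatingTable(matrix("a", 10, 5))), 1)
  ## two raters, two items, perfectly crossed: Pbar = 0, Pe = 0.5 -> -1
  t2 <- RatingTable(rbind(c("A", "B"), c("B", "A")))
  expect_equal(fleissKappa(t2), -1)
  ## the classic two-category mixed table: independent halves
  t3 <- RatingTable(rbind(c("A", "A"), c("A", "B"), c("B", "A"),
                          c("B", "B")))
  ## Pbar = 1/2, Pe = 1/2 -> kappa 0
  expect_equal(fleissKappa(t3), 0)
})

test_that("kappa is invariant to relabeling and permutations", {
  set.seed(11)
  m <- matrix(sample(c("x", "y", "z"), 60, replace = TRUE), 20, 3)
  k0 <- fleissKappa(RatingTable(m))
  relab <- matrix(c(x = "b", y = "c", z = "a")[m], 20, 3)
  expect_equal(fleissKappa(RatingTable(relab)), k0, tolerance = 1e-12)
  expect_equal(fleissKappa(RatingTable(m[sample(20), sample(3)])), k0,
               tolerance = 1e-12)
})

test_that("pairwise agreement and two-rater kappa behave", {
  t1 <- RatingTable(matrix("a", 10, 4))
  pa <- pairwiseAgreement(t1)
  expect_true(all(pa$agreement == 1))
  ## two raters who never agree
  t2 <- RatingTable(cbind(rep("A", 6), rep("B", 6)))
  expect_equal(pairwiseAgreement(t2)$agreement[1, 2], 0)
  ## random independent uniform ratings, 2 categories: agreement ~ 0.5
  set.seed(5)
  t3 <- RatingTable(matrix(sample(c("A", "B"), 2000, replace = TRUE),
                           1000, 2))
  expect_equal(pairwiseAgreement(t3)$agreement[1, 2], 0.5, tolerance = 0.05)
})

test_that("two-rater Fleiss equals the pairwise kappa on the same table", {
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(sample(c("A", "B", "C"), 40, replace = TRUE), 20, 2)
    rt <- RatingTable(m)
    expect_equal(fleissKappa(rt), pairwiseAgreement(rt)$kappa[1, 2],
                 tolerance = 1e-12)
  }
})

test_that("excludeRank filters annotations and conserves the rest", {
  ann <- AnnotationSet(
    geometry = replicate(5, cbind(50, 50), simplify = FALSE),
    class = rep("foreground", 5),
    rank = c(3L, 3L, 3L, 1L, 1L), height = 400L, width = 400L)
  out <- excludeRank(ann, "possible")
  expect_equal(nObjects(out), 3L)
  expect_true(all(objectRanks(out) == 3L))
  ## excluding an absent rank is the identity
  expect_equal(excludeRank(ann, "probable")@objects, ann@objects)
  expect_error(excludeRank(ann, "certain"), "unknown rank")
})

test_that("excludeRank on tables drops items and guards degeneracy", {
  m <- rbind(c("definite", "definite"), c("possible", "definite"),
             c("probable", "probable"), c("definite", "definite"))
  rt <- RatingTable(m)
  out <- excludeRank(rt, "possible")
  expect_equal(nrow(out@ratings), 3L)
  expect_false("possible" %in% out@categories)
  ## filtering below 2 items raises rather than producing a degenerate table
  small <- RatingTable(rbind(c("a", "a"), c("b", "b"), c("b", "b")))
  expect_error(excludeRank(small, "b"), "fewer than 2")
})

test_that("kappa on rank-filtered random tables stays well defined", {
  set.seed(13)
  for (i in 1:10) {
    m <- matrix(sample(c("definite", "probable", "possible", "background"),
                       120, replace = TRUE, prob = c(.3, .3, .2, .2)),
                40, 3)
    rt <- RatingTable(m)
    filtered <- tryCatch(excludeRank(rt, "possible"),
                         error = function(e) NULL)
    if (!is.null(filtered)) expect_true(is.finite(fleissKappa(filtered)))
  }
})
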