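test_that("Spearman rho hits its boundary cases and tie handling", {
  x <- c(1, 2, 5, 9)
  expect_equal(spearmanRho(x, x * 2 + 1)$rho, 1)
  expect_equal(spearmanRho(x, -x)$rho, -1)
  expect_equal(spearmanRho(x, x)$p, 0)
  ## tied data: rho equals Pearson on mid-ranks
  xt <- c(1, 2, 2, 3, 5, 5, 5)
  yt <- c(2, 1, 4, 4, 6, 6, 7)
  expect_equal(spearmanRho(xt, yt)$rho, cor(rank(xt), rank(yt)),
               tolerance = 1e-12)
  ## invariant under strictly monotone transforms
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearmanRho(exp(a), b)$rho, spearmanRho(a, b)$rho,
               tolerance = 1e-12)
  expect_error(spearmanRho(1:2, 1:2), "at least 3")
})

test_that("Pearson r matches closed forms and flags zero variance", {
  x <- c(1, 3, 4, 8)
  expect_equal(pearsonR(x, 2 * x + 1)$r, 1)
  ## orthogonal-by-construction vector has r = 0
  set.seed(9)
  a <- rnorm(20)
  b0 <- rnorm(20)
  b <- b0 - mean(b0) - cov(a, b0) / var(a) * (a - mean(a))
  expect_equal(pearsonR(a, b)$r, 0, tolerance = 1e-12)
  ## n = 3 worked example: r and p against direct formulas
  x3 <- c(0, 1, 2); y3 <- c(1, 0, 4)
  ct <- pearsonR(x3, y3)
  r <- sum((x3 - 1) * (y3 - mean(y3))) /
    sqrt(sum((x3 - 1)^2) * sum((y3 - mean(y3))^2))
  expect_equal(ct$r, r, tolerance = 1e-12)
  tstat <- r * sqrt(1 / (1 - r^2))
  expect_equal(ct$p, 2 * pt(-abs(tstat), 1), tolerance = 1e-9)
  expect_true(is.na(pearsonR(c(1, 1, 1), c(1, 2, 3))$r))
})

test_that("Mann-Whitney U matches its conventions", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$method, "exact enumeration")
  ## identical samples: p ~ 1
  expect_gte(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  ## U_a + U_b = n_a * n_b
  set.seed(12)
  a <- rnorm(8); b <- rnorm(9)
  rk <- rank(c(a, b))
  Ua <- sum(rk[1:8]) - 8 * 9 / 2
  expect_equal(mannWhitneyU(a, b)$U, min(Ua, 72 - Ua))
})

test_that("exact Mann-Whitney p equals the 70-arrangement brute force", {
  set.seed(17)
  for (i in 1:20) {
    a <- sample(1:6, 4, replace = TRUE)    # replacement forces ties
    b <- sample(1:6, 4, replace = TRUE)
    expect_equal(mannWhitneyU(a, b)$p, oracleMannWhitneyP(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis delegates with the tie-corrected H", {
  ## all-constant input is flagged, not an error
  kw0 <- kruskalWallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(kw0$H, 0)
  expect_true(kw0$allTies)
  ## three fully ordered groups: H from the rank formula by hand
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskalWallis(g)
  H <- 12 / (9 * 10) * (3 * (2 - 5)^2 + 3 * (5 - 5)^2 + 3 * (8 - 5)^2)
  expect_equal(kw$H, H, tolerance = 1e-12)
  expect_equal(kw$df, 2L)
})

test_that("two-group Kruskal-Wallis agrees with the Mann-Whitney z", {
  ## for 2 groups (continuous data), H = z^2 so the p-values coincide
  set.seed(19)
  for (i in 1:100) {
    a <- rnorm(10); b <- rnorm(12)
    pKW <- kruskalWallis(list(a, b))$p
    pMW <- mannWhitneyU(a, b, exactLimit = 0)$p
    expect_equal(pKW, pMW, tolerance = 1e-10)
  }
})

test_that("the cohort stat table runs feature-wise", {
  set.seed(23)
  df <- data.frame(subjectId = sprintf("s%02d", 1:20),
                   burden = c(rnorm(6, 0), rnorm(14, 3)))
  status <- rep(c(0L, 1L), c(6L, 14L))
  stage <- c(rep(0L, 6L), rep(1:3, length.out = 14L))
  tab <- cohortStatTable(df, status, stage, features = "burden")
  expect_equal(nrow(tab), 1L)
  expect_lt(tab$pMW, 0.05)
  expect_true(is.finite(tab$H))
})
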