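test_that("the OD transform matches its closed form and round-trips", {
  img <- array(255, c(2, 2, 3))
  expect_equal(odTransform(img), array(0, c(2, 2, 3)), ignore_attr = TRUE)
  img[1, 1, 2] <- 25.5
  od <- odTransform(img)
  expect_equal(od[1, 1, 2], 1)
  set.seed(3)
  img2 <- array(runif(2 * 3 * 3, 1, 255), c(2, 3, 3))
  expect_equal(odInverse(odTransform(img2)), img2, tolerance = 1e-12,
               ignore_attr = TRUE)
  ## zero intensities are clamped, not an error
  img3 <- array(0, c(1, 1, 3))
  od3 <- odTransform(img3)
  expect_equal(attr(od3, "clamped"), 3L)
  expect_true(all(is.finite(od3)))
})

test_that("deconvolution inverts the forward stain model", {
  m <- hdabStainModel()
  od <- array(0.7 * m@hematoxylin + 0.3 * m@dab, c(1, 1, 3))
  ch <- deconvolveStains(od, m)
  expect_equal(as.numeric(ch@hematoxylin), 0.7, tolerance = 1e-9)
  expect_equal(as.numeric(ch@dab), 0.3, tolerance = 1e-9)
  expect_equal(as.numeric(ch@residual), 0, tolerance = 1e-9)
  ## zero OD -> all channels zero; pure H -> no DAB
  z <- deconvolveStains(array(0, c(2, 2, 3)), m)
  expect_true(all(z@hematoxylin == 0) && all(z@dab == 0))
  pureH <- deconvolveStains(array(rep(0.5 * m@hematoxylin, each = 4),
                                  c(2, 2, 3)), m)
  expect_lt(max(abs(pureH@dab)), 1e-9)
  ## collinear stain vectors are rejected
  expect_error(hdabStainModel(dab = c(0.650, 0.704, 0.286)), "collinear")
})

test_that("deconvolution is linear before clamping", {
  m <- hdabStainModel()
  set.seed(8)
  od1 <- array(runif(12, -0.2, 1), c(2, 2, 3))
  od2 <- array(runif(12, -0.2, 1), c(2, 2, 3))
  a <- 1.7; b <- -0.6
  lhs <- deconvolveStains(a * od1 + b * od2, m, clamp = FALSE)
  c1 <- deconvolveStains(od1, m, clamp = FALSE)
  c2 <- deconvolveStains(od2, m, clamp = FALSE)
  expect_equal(lhs@hematoxylin, a * c1@hematoxylin + b * c2@hematoxylin,
               tolerance = 1e-10)
  expect_equal(lhs@dab, a * c1@dab + b * c2@dab, tolerance = 1e-10)
})

test_that("stain statistics pool pixels inside positive cells", {
  h <- w <- 120L
  dab <- matrix(0, h, w); hem <- matrix(0.2, h, w)
  grid <- PatchGrid(rbind(c(1L, 1L)), slideHeight = h, slideWidth = w)
  dab[41:80, 41:80] <- 0.4
  ch <- new("StainChannels", hematoxylin = hem, dab = dab,
            residual = matrix(0, h, w), negativeClamped = 0L)
  st <- stainStatistics(ch, grid)
  expect_equal(unname(st["dab_mean"]), 0.4)
  expect_equal(unname(st["dab_median"]), 0.4)
  expect_equal(unname(st["dab_sd"]), 0)
  ## one 40x40 cell of constant 0.5 -> sum 0.5 * 1600 = 800
  dab[41:80, 41:80] <- 0.5
  ch@dab <- dab
  expect_equal(unname(stainStatistics(ch, grid)["dab_sum"]), 800)
  ## empty grid -> flagged missing
  eg <- PatchGrid(matrix(FALSE, 3, 3), slideHeight = h, slideWidth = w)
  expect_true(all(is.na(stainStatistics(ch, eg))))
})

test_that("pooled statistics match a naive masked recomputation", {
  set.seed(21)
  h <- w <- 160L
  ch <- new("StainChannels",
            hematoxylin = matrix(runif(h * w), h, w),
            dab = matrix(runif(h * w), h, w),
            residual = matrix(0, h, w), negativeClamped = 0L)
  pos <- rbind(c(0L, 0L), c(2L, 3L), c(1L, 1L))
  grid <- PatchGrid(pos, slideHeight = h, slideWidth = w)
  st <- stainStatistics(ch, grid)
  mask <- matrix(FALSE, h, w)
  for (k in seq_len(nrow(pos)))
    mask[(pos[k, 1] * 40 + 1):(pos[k, 1] * 40 + 40),
         (pos[k, 2] * 40 + 1):(pos[k, 2] * 40 + 40)] <- TRUE
  px <- ch@dab[mask]
  expect_equal(unname(st["dab_sum"]), sum(px), tolerance = 1e-12)
  expect_equal(unname(st["dab_mean"]), mean(px), tolerance = 1e-12)
  expect_equal(unname(st["dab_median"]), median(px), tolerance = 1e-12)
  expect_equal(unname(st["dab_sd"]), sqrt(mean((px - mean(px))^2)),
               tolerance = 1e-12)
  ## the mean is bounded by the masked range
  expect_gte(st["dab_mean"], min(px))
  expect_lte(st["dab_mean"], max(px))
})

test_that("tissue mask thresholds OD magnitude sensibly", {
  m <- hdabStainModel()
  blank <- array(255, c(60, 60, 3))
  tm <- tissueMask(blank, m)
  expect_equal(attr(tm, "count"), 0L)
  expect_true(all(tissueMask(blank, m, threshold = 0)))
  sl <- generateSlide(slideSpec(seed = 19))
  tm2 <- tissueMask(sl@image, m)
  expect_equal(mean(tm2), mean(sl@tissue), tolerance = 0.02)
})
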