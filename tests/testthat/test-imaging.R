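# Grid segmentation and per-seed color summaries.

test_that("a default synthetic cabinet image segments into 96 cells", {
  sim <- generateSeedImage(seedCohortSpec(), seed = 1)
  regions <- segmentSeedGrid(sim$image)
  expect_equal(nrow(regions), 96)
  expect_equal(nrow(unique(regions[, c("row", "col")])), 96)
  expect_setequal(regions$row, 1:8)
  expect_setequal(regions$col, 1:12)
})

test_that("a uniform background yields no regions", {
  img <- array(235, c(60, 60, 3))
  regions <- segmentSeedGrid(img, gridRows = 1, gridCols = 1,
                             thresholdMode = "fixed", threshold = 80)
  expect_equal(nrow(regions), 0)
})

test_that("a single ellipse is located within a pixel of its center", {
  L <- ellipseScene(100, 100, list(c(40, 60)))
  regions <- segmentSeedGrid(L, gridRows = 1, gridCols = 1,
                             thresholdMode = "fixed", threshold = 70)
  expect_equal(nrow(regions), 1)
  expect_lt(abs(regions$centroid_y - 40), 1)
  expect_lt(abs(regions$centroid_x - 60), 1)
})

test_that("translating the scene translates all centroids equally", {
  centers <- list(c(40, 40), c(40, 120), c(40, 200))
  L1 <- ellipseScene(100, 240, centers)
  L2 <- ellipseScene(100, 240, lapply(centers, function(p) p + 7))
  r1 <- segmentSeedGrid(L1, 1, 3, thresholdMode = "fixed", threshold = 70)
  r2 <- segmentSeedGrid(L2, 1, 3, thresholdMode = "fixed", threshold = 70)
  expect_equal(nrow(r1), 3)
  expect_equal(r2$centroid_x, r1$centroid_x + 7, tolerance = 1e-9)
  expect_equal(r2$centroid_y, r1$centroid_y + 7, tolerance = 1e-9)
})

test_that("regions are pairwise disjoint and conserve foreground area", {
  sim <- generateSeedImage(seedCohortSpec(), seed = 3)
  regions <- segmentSeedGrid(sim$image)
  px <- unlist(regions$pixels)
  expect_equal(anyDuplicated(px), 0)
  L <- matrix(srgbToLab(matrix(sim$image, ncol = 3))[, "L"],
              dim(sim$image)[1])
  expect_lte(length(px), sum(L < 85))
})

test_that("small regions are dropped with a warning, collisions error", {
  L <- ellipseScene(100, 100, list(c(50, 30)))
  L[10, 10] <- 40   # 1-px speckle
  expect_warning(
    r <- segmentSeedGrid(L, 1, 1, thresholdMode = "fixed",
                         threshold = 70),
    "below minAreaPx")
  expect_equal(nrow(r), 1)
  # two full-size blobs whose centroids land in the same (only) cell
  L2 <- ellipseScene(100, 200, list(c(50, 50), c(50, 150)))
  expect_error(
    segmentSeedGrid(L2, 1, 1, thresholdMode = "fixed", threshold = 70),
    "ambiguous")
})

test_that("uniform regions recover their exact color, means average", {
  img <- array(0, c(10, 12, 3))
  col <- c(120, 80, 40)
  for (ch in 1:3) img[, , ch] <- 235
  img[3:6, 3:8, 1] <- col[1]; img[3:6, 3:8, 2] <- col[2]
  img[3:6, 3:8, 3] <- col[3]
  regions <- segmentSeedGrid(img, 1, 1, minAreaPx = 4,
                             thresholdMode = "fixed", threshold = 80)
  cc <- summarizeSeedColors(regions, img)
  expect_equal(unname(c(cc$L, cc$a, cc$b)), unname(srgbToLab(col)),
               tolerance = 1e-9)
  # two-pixel region: L is the mean of the two pixelwise L values
  img2 <- array(235, c(4, 4, 3))
  img2[2, 2, ] <- c(50, 50, 50); img2[2, 3, ] <- c(20, 60, 90)
  reg2 <- data.frame(row = 1, col = 1, area_px = 2,
                     centroid_x = 2.5, centroid_y = 2)
  reg2$pixels <- list(c(2 + 4, 2 + 8))   # linear indices of the 2 px
  cc2 <- summarizeSeedColors(reg2, img2)
  labs <- srgbToLab(rbind(c(50, 50, 50), c(20, 60, 90)))
  expect_equal(cc2$L, mean(labs[, "L"]), tolerance = 1e-9)
})

test_that("mean color of a noisy seed converges at the sqrt(n) rate", {
  set.seed(4)
  base <- c(110, 90, 60)
  img <- array(235, c(40, 40, 3))
  noise <- array(rnorm(40 * 40 * 3, 0, 3), c(40, 40, 3))
  for (ch in 1:3)
    img[8:32, 8:32, ch] <- pmin(pmax(base[ch] + noise[8:32, 8:32, ch],
                                     0), 255)
  regions <- segmentSeedGrid(img, 1, 1, thresholdMode = "fixed",
                             threshold = 80)
  cc <- summarizeSeedColors(regions, img)
  truth <- srgbToLab(base)
  # ~625 px at channel SD 3: the mean L is within a fraction of a unit
  expect_lt(abs(cc$L - truth["L"]), 4 * 3 / sqrt(625))
})

test_that("an image round-trips through PNG unchanged", {
  sim <- generateSeedImage(seedCohortSpec(), rows = 2, cols = 3,
                           seed = 9)
  fp <- tempfile(fileext = ".png")
  png::writePNG(sim$image / 255, fp)
  back <- readSeedImage(fp)
  expect_equal(back, sim$image, tolerance = 1e-12)
})
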