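# Force-distance curve parsing and texture-parameter extraction.

test_that("curve files are parsed, trimmed and re-zeroed", {
  fp <- tempfile(fileext = ".csv")
  d <- seq(0, 0.4, by = 0.002)
  write.csv(data.frame(distance_mm = d, force_N = 100 * d), fp,
            row.names = FALSE)
  cv <- readCurve(fp)
  # the d = 0 sample (force 0 < trigger) is trimmed, distance re-zeroed
  expect_equal(length(cv), length(d) - 1)
  expect_equal(curveDistance(cv)[1], 0)
  expect_equal(diff(curveDistance(cv))[1], 0.002, tolerance = 1e-12)

  # time mode at 500 samples/s and 1 mm/s: 0.002 mm spacing
  fp2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = seq(0, 0.4, by = 0.002),
                       force_N = seq(1, 50, length.out = 201)), fp2,
            row.names = FALSE)
  cv2 <- readCurve(fp2)
  expect_equal(unique(round(diff(curveDistance(cv2)), 9)), 0.002)

  # short files are allowed only when minSamples permits
  fp3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(distance_mm = c(0, 0.1, 0.2),
                       force_N = c(1, 2, 3)), fp3, row.names = FALSE)
  expect_error(readCurve(fp3), "fewer than")
  expect_equal(length(readCurve(fp3, minSamples = 3)), 3)

  fp4 <- tempfile(fileext = ".csv")
  writeLines(c("force_N", "1", "2"), fp4)
  expect_error(readCurve(fp4), "two columns")
})

test_that("moving-average smoothing has the analytic response", {
  d <- seq(0, 0.2, by = 0.002)
  flat <- ForceDistanceCurve(d, rep(5, length(d)))
  expect_equal(curveForce(smoothCurve(flat, 7)), rep(5, length(d)))
  spike <- rep(0, length(d)); spike[51] <- 1
  sp <- ForceDistanceCurve(d, spike)
  expect_equal(smoothCurve(sp, 1), sp)
  expect_equal(max(curveForce(smoothCurve(sp, 5))), 1 / 5,
               tolerance = 1e-12)
  expect_error(smoothCurve(sp, 4), "odd")
  expect_error(smoothCurve(sp, 1001), "larger than")
})

test_that("peak detection counts prominent maxima only", {
  rising <- polylineCurve(c(0, 1), c(0, 60))
  expect_length(detectPeaks(rising), 0)
  bumps <- polylineCurve(c(0, .1, .2, .3, .4, .5, .6, .7, .8, .9),
                         c(0, 30, 20, 30, 20, 30, 20, 30, 20, 20))
  expect_length(detectPeaks(bumps, 1), 4)
  expect_lt(length(detectPeaks(bumps, 20)), 4)
})

test_that("raising the prominence threshold never adds peaks", {
  spec <- seedCohortSpec()
  set.seed(8)
  for (i in 1:5) {
    g <- generateCurve(spec, stage = sample(1:5, 1), noiseSd = 1)
    sm <- smoothCurve(g$curve, 5)
    counts <- vapply(c(0.5, 1, 2, 5, 10, 20),
                     function(p) length(detectPeaks(sm, p)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the break is the first qualifying drop", {
  cv <- polylineCurve(c(0, 0.55, 0.57, 0.9, 1.0),
                      c(0, 60, 38, 50, 45))
  br <- detectBreak(cv, detectPeaks(cv))
  expect_equal(br$distance, 0.55, tolerance = 1e-9)
  expect_equal(br$forceBefore, 60, tolerance = 1e-9)
  expect_equal(br$forceBefore - br$forceAfterMin, 22, tolerance = 1e-9)

  # an early 5% dip does not qualify; the 50% drop does
  cv2 <- polylineCurve(c(0, 0.2, 0.24, 0.5, 0.55, 0.8),
                       c(0, 20, 19, 60, 30, 40))
  br2 <- detectBreak(cv2, detectPeaks(cv2))
  expect_equal(br2$distance, 0.5, tolerance = 1e-9)

  rising <- polylineCurve(c(0, 1), c(0, 60))
  expect_error(detectBreak(rising, detectPeaks(rising)), "no break")
})

test_that("elasticity is the exact pre-break slope", {
  d <- seq(0, 0.6, by = 0.002)
  f <- ifelse(d <= 0.5, 100 * d, 50 - 400 * (d - 0.5))
  cv <- ForceDistanceCurve(d, f)
  bIdx <- which.max(f)
  expect_equal(elasticity(cv, bIdx), 100, tolerance = 1e-9)
  # an intercept is absorbed
  cv2 <- ForceDistanceCurve(d, ifelse(d <= 0.5, 100 * d + 5,
                                      55 - 400 * (d - 0.5)))
  expect_equal(elasticity(cv2, which.max(curveForce(cv2))), 100,
               tolerance = 1e-9)
  # noisy segment: slope 98 recovered within 2%
  set.seed(9)
  cv3 <- ForceDistanceCurve(d, 98 * d + rnorm(length(d), 0, 0.5))
  expect_equal(elasticity(cv3, length(d)), 98, tolerance = 0.02)
  # break below the force floor
  low <- ForceDistanceCurve(d, 8 * d / 0.6)
  expect_error(elasticity(low, length(d)), "10")
})

test_that("trapezoidal energies are exact on piecewise-linear curves", {
  tri <- polylineCurve(c(0, 0.5), c(0, 60))
  expect_equal(integrateEnergy(tri, 1, length(tri)), 15,
               tolerance = 1e-9)
  zero <- ForceDistanceCurve(seq(0, 1, 0.002), rep(0, 501))
  expect_equal(integrateEnergy(zero, 1, 501), 0)
  expect_error(integrateEnergy(tri, 10, 3), "smaller")
  g <- generateCurve(seedCohortSpec(), stage = 2, noiseSd = 0, seed = 10)
  bp <- g$breakpoints
  expect_equal(integrateEnergy(g$curve, 1, length(g$curve)),
               polylineArea(bp$distance, bp$force), tolerance = 1e-9)
})

test_that("profiles satisfy the defining identities and bounds", {
  spec <- seedCohortSpec()
  set.seed(12)
  for (i in 1:10) {
    g <- generateCurve(spec, stage = sample(1:5, 1), noiseSd = 1)
    p <- textureProfile(g$curve)
    v <- as.data.frame(p)
    expect_equal(v$Si, v$Bd / v$Th, tolerance = 1e-9)
    expect_equal(v$Ar, v$Be / v$De, tolerance = 1e-9)
    expect_lte(v$Be, v$De)
    expect_lte(v$Bd, v$Th / 2)
    expect_lte(v$Bdc, v$Bf)
  }
})

test_that("a prescribed curve reproduces its known parameters", {
  g <- generateCurve(seedCohortSpec(), stage = 3, bf = 60, e = 60 / 0.55,
                     th = 3.2, np = 4, bdc = 22, noiseSd = 0, seed = 13)
  p <- textureProfile(g$curve)
  expect_equal(p@np, 4)
  expect_equal(p@bf, 60, tolerance = 1e-6)
  expect_equal(p@bd, 0.55, tolerance = 0.002)
  expect_equal(p@th, 3.2, tolerance = 0.004)
  expect_equal(p@si, 0.171875, tolerance = 1e-3)
})

test_that("batch extraction flags curves without a break", {
  dirp <- tempfile(); dir.create(dirp)
  g <- generateCurve(seedCohortSpec(), stage = 1, noiseSd = 0, seed = 14)
  write.csv(as.data.frame(g$curve), file.path(dirp, "ok.csv"),
            row.names = FALSE)
  d <- seq(0, 1, by = 0.002)
  write.csv(data.frame(distance_mm = d, force_N = 60 * d),
            file.path(dirp, "nobreak.csv"), row.names = FALSE)
  res <- textureProfiles(dirp)
  expect_equal(res$profiles$seed_id, "ok")
  expect_equal(res$flagged$seed_id, "nobreak")
  expect_match(res$flagged$reason, "no break|peak")
})
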