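# Panel performance: three-way ANOVA, SNK, homogeneity PCA, screening.

test_that("constant scores give zero SS and inapplicable F", {
  g <- scoreGrid(4, 3); g$score <- 5
  a <- threeWayAnova(SensoryScores(g), "color")
  expect_equal(sum(a$sum_sq), 0, tolerance = 1e-9)
  expect_true(all(is.na(a$f[a$effect != "residual"])))
})

test_that("a pure stage signal concentrates all SS in the sample effect", {
  g <- scoreGrid(4, 3)
  g$score <- as.numeric(sub("MS", "", g$sample))
  a <- threeWayAnova(SensoryScores(g), "color")
  expect_gt(a$sum_sq[a$effect == "sample"], 0)
  expect_equal(sum(a$sum_sq[a$effect != "sample"]), 0, tolerance = 1e-9)
})

test_that("the balanced decomposition adds up to the total SS", {
  set.seed(15)
  g <- scoreGrid(6, 4)
  g$score <- pmin(pmax(rnorm(nrow(g), 5, 1.5), 0), 10)
  a <- threeWayAnova(SensoryScores(g), "color")
  total <- sum((g$score - mean(g$score))^2)
  expect_equal(sum(a$sum_sq), total, tolerance = 1e-6)
  dfTotal <- nrow(g) - 1
  expect_equal(sum(a$df), dfTotal)
})

test_that("incomplete designs are rejected with the offending cell", {
  g <- scoreGrid(4, 3); g$score <- 5
  g <- g[-1, ]
  expect_error(threeWayAnova(SensoryScores(g), "color"),
               "unbalanced.*judge")
})

test_that("SNK on two groups agrees with the pooled t-test", {
  set.seed(16)
  for (delta in c(0, 0.3, 0.8, 2)) {
    d <- data.frame(group = rep(c("A", "B"), each = 12),
                    value = rnorm(24, rep(c(0, delta), each = 12), 1))
    snk <- snkTest(d)
    shared <- length(intersect(strsplit(snk$groups$letters[1], "")[[1]],
                               strsplit(snk$groups$letters[2], "")[[1]]))
    tt <- t.test(value ~ group, d, var.equal = TRUE)
    expect_equal(shared == 0, tt$p.value < 0.05)
  }
})

test_that("SNK letters reflect separation", {
  d0 <- data.frame(group = rep(c("A", "B", "C"), each = 6),
                   value = rep(5, 18) + rep(c(0, 0, 0), each = 6) +
                     rnorm(18, 0, 1e-8))
  s0 <- snkTest(d0)
  expect_true(all(s0$groups$letters == s0$groups$letters[1]))

  set.seed(17)
  d1 <- data.frame(group = rep(c("A", "B", "C"), each = 8),
                   value = rnorm(24, rep(c(0, 10, 20), each = 8), 0.5))
  s1 <- snkTest(d1)
  expect_equal(s1$groups$letters, c("a", "b", "c"))
  # summary-statistics input gives the same grouping
  stats <- do.call(rbind, lapply(split(d1$value, d1$group), function(v)
    data.frame(mean = mean(v), sd = sd(v), n = length(v))))
  stats$group <- rownames(stats)
  expect_equal(snkTest(stats)$groups$letters, c("a", "b", "c"))
})

test_that("SNK never rejects more pairs than unadjusted pooled t-tests", {
  set.seed(18)
  for (rep in 1:10) {
    k <- sample(3:5, 1)
    d <- data.frame(group = rep(LETTERS[1:k], each = 10),
                    value = rnorm(10 * k, rep(runif(k, 0, 2), each = 10)))
    snk <- snkTest(d)
    lets <- strsplit(snk$groups$letters, "")
    names(lets) <- snk$groups$group
    pt <- pairwise.t.test(d$value, d$group, pool.sd = TRUE,
                          p.adjust.method = "none")$p.value
    snkRej <- 0; tRej <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      gi <- LETTERS[i]; gj <- LETTERS[j]
      if (!length(intersect(lets[[gi]], lets[[gj]])))
        snkRej <- snkRej + 1
      p <- pt[gj, gi]; if (is.na(p)) p <- pt[gi, gj]
      if (p < 0.05) tRej <- tRej + 1
    }
    expect_lte(snkRej, tRej)
  }
})

test_that("homogeneity PCA separates scale effects from disagreement", {
  spec <- seedCohortSpec(residSd = 0)
  # positive per-judge scalings of one profile: rank-1, same-sign
  g1 <- generatePanelScores(spec, nJudges = 6, nSessions = 3,
                            attributes = "vegetal",
                            judgeGains = c(0.6, 0.8, 1, 1.1, 1.3, 0.9),
                            seed = 19)
  h1 <- panelHomogeneityPca(g1$scores, "vegetal")
  expect_equal(h1$diagnosis, "scale_effects")
  expect_gt(h1$explained[1], 99)
  # two blocks with opposite polarity: signs split (reversed-scale
  # judges get a bias of 10 so scores stay on the scale)
  gains2 <- c(1, 1.1, 0.9, -1, -1.2, -0.8)
  g2 <- generatePanelScores(spec, nJudges = 6, nSessions = 3,
                            attributes = "vegetal",
                            judgeGains = gains2,
                            judgeBiases = ifelse(gains2 < 0, 10, 0),
                            seed = 20)
  h2 <- panelHomogeneityPca(g2$scores, "vegetal")
  expect_equal(h2$diagnosis, "disagreement")
  # noisy shared profile still diagnoses scale effects strongly
  g3 <- generatePanelScores(seedCohortSpec(residSd = 0.3), nJudges = 8,
                            nSessions = 4, attributes = "vegetal",
                            seed = 21)
  h3 <- panelHomogeneityPca(g3$scores, "vegetal")
  expect_equal(h3$diagnosis, "scale_effects")
  expect_gt(h3$explained[1], 90)
})

test_that("the diagnosis is invariant to positive judge rescaling", {
  g <- generatePanelScores(seedCohortSpec(), nJudges = 6, nSessions = 4,
                           seed = 22)
  df <- scoreTable(g$scores)
  h0 <- panelHomogeneityPca(g$scores, "color")
  df2 <- df
  sel <- df2$judge == "J3"
  df2$score[sel] <- df2$score[sel] * 0.5   # stays on the 0-10 scale
  h1 <- panelHomogeneityPca(SensoryScores(df2), "color")
  expect_equal(h1$diagnosis, h0$diagnosis)
})

test_that("judge screening flags only outlying dispersion", {
  g <- scoreGrid(8, 4); g$score <- as.numeric(sub("MS", "", g$sample))
  s0 <- judgeScreening(SensoryScores(g))
  expect_length(s0$flagged, 0)

  set.seed(23)
  g$score <- g$score + rnorm(nrow(g), 0, 0.3)
  noisy <- g$judge == "J5"
  g$score[noisy] <- pmin(pmax(g$score[noisy] +
                                rnorm(sum(noisy), 0, 3), 0), 10)
  s1 <- judgeScreening(SensoryScores(g))
  expect_equal(s1$flagged, "J5")

  s2 <- judgeScreening(SensoryScores(g), ruleMultiple = Inf)
  expect_length(s2$flagged, 0)
})

test_that("stage regression recovers exact trends and flags constants", {
  g <- scoreGrid(4, 3)
  g$score <- 1 + 0.8 * as.numeric(sub("MS", "", g$sample))
  r <- attributeStageRegression(SensoryScores(g), "color")
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(r$slope, 0.8, tolerance = 1e-9)
  g$score <- 5
  r0 <- attributeStageRegression(SensoryScores(g), "color")
  expect_true(r0$degenerate)
  expect_equal(r0$r_squared, 0)
})
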