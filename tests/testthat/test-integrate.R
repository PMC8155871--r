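# Stage summaries, correlations, redundancy pruning, PCA.

makeProfiles <- function(perStage = 1, jitter = 0) {
  base <- syrahStageMeans()$means
  do.call(rbind, lapply(1:5, function(s) {
    reps <- base[rep(s, perStage), , drop = FALSE]
    df <- as.data.frame(reps + jitter * matrix(rnorm(length(reps)),
                                               nrow(reps)))
    df$stage <- s
    df
  }))
}

makeScores <- function() {
  g <- scoreGrid(3, 2, attr = "color")
  g$score <- as.numeric(sub("MS", "", g$sample))
  SensoryScores(g)
}

test_that("single and duplicated seeds give exact means and zero SD", {
  s1 <- stageSummary(makeProfiles(1), makeScores())
  expect_equal(stageMeans(s1)[, "Bf"],
               syrahStageMeans()$means[, "Bf"], ignore_attr = TRUE)
  expect_equal(unname(stageSDs(s1)[, "Bf"]), rep(0, 5))
  s2 <- stageSummary(makeProfiles(2), makeScores())
  expect_equal(unname(stageSDs(s2)[, "De"]), rep(0, 5))
  expect_equal(unname(stageN(s2)[, "De"]), rep(2, 5))
})

test_that("a stage missing from either source is an error", {
  prof <- makeProfiles(1)
  expect_error(stageSummary(prof[prof$stage != 3, ], makeScores()),
               "empty stage")
})

test_that("correlation matrix has unit diagonal and honest extremes", {
  set.seed(24)
  x <- cbind(a = rnorm(10), b = rnorm(10))
  x <- cbind(x, c = -x[, "a"])
  r <- correlationMatrix(x)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r["a", "c"], -1, tolerance = 1e-12)
  expect_true(all(r >= -1 & r <= 1))
  expect_equal(r, t(r))
  xz <- cbind(x, z = rep(2, 10))
  expect_warning(rz <- correlationMatrix(xz), "zero-variance")
  expect_true(all(is.na(rz["z", c("a", "b", "c")])))
})

test_that("stage-mean correlations reproduce the reference table", {
  r <- roundHalfUp(correlationMatrix(syrahStageMeans()$means), 2)
  expect_equal(r["Np", "Bf"], 0.99)
  expect_equal(r["Th", "De"], 1.00)
  expect_equal(r["Bf", "Be"], 0.95)
})

test_that("redundancy pruning follows the priority order", {
  m <- diag(3); dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  m["A", "B"] <- m["B", "A"] <- 0.85
  res <- pruneRedundant(m, priority = c("A", "B", "C"))
  expect_setequal(res$kept, c("A", "C"))
  expect_equal(res$dropped$dropped_var, "B")

  m2 <- m; m2["A", "B"] <- m2["B", "A"] <- 0.5
  expect_equal(pruneRedundant(m2, priority = c("A", "B", "C"))$kept,
               c("A", "B", "C"))

  # chain A~B, B~C strong, A~C weak: B goes, A and C stay
  m3 <- diag(3); dimnames(m3) <- dimnames(m)
  m3["A", "B"] <- m3["B", "A"] <- 0.9
  m3["B", "C"] <- m3["C", "B"] <- 0.9
  m3["A", "C"] <- m3["C", "A"] <- 0.1
  res3 <- pruneRedundant(m3, priority = c("A", "B", "C"))
  expect_setequal(res3$kept, c("A", "C"))

  # invariance to column order given fixed priorities
  perm <- c("C", "A", "B")
  res4 <- pruneRedundant(m3[perm, perm], priority = c("A", "B", "C"))
  expect_setequal(res4$kept, res3$kept)
})

test_that("PCA of k stages has k-1 non-null components summing to 100%", {
  p <- pcaBiplot(syrahStageMeans()$means)
  expect_equal(sum(p$explained[1:4]), 100, tolerance = 1e-9)
  expect_lt(p$explained[5], 1e-9)
  expect_true(all(diff(p$explained) <= 1e-12))

  rank1 <- outer(1:5, seq(0.5, 2, length.out = 4))
  colnames(rank1) <- paste0("v", 1:4)
  p1 <- pcaBiplot(rank1)
  expect_equal(p1$explained[1], 100, tolerance = 1e-9)

  set.seed(25)
  wide <- matrix(rnorm(200 * 5), 200, 5,
                 dimnames = list(NULL, paste0("v", 1:5)))
  pw <- pcaBiplot(wide)
  expect_true(all(abs(pw$eigenvalues - 1) < 0.35))
})

test_that("half-up rounding matches report conventions", {
  expect_equal(roundHalfUp(0.245, 2), 0.25)
  expect_equal(roundHalfUp(-0.245, 2), -0.25)
  expect_equal(roundHalfUp(0.244, 2), 0.24)
})
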