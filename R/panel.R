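## Sensory panel performance statistics. The panel design is balanced:
## every judge scores every sample (maturity stage) in every session,
## once. With a single observation per cell the three-way interaction
## is confounded with error and serves as the residual.

.stageIndex <- function(s) {
  s <- as.character(s)
  num <- suppressWarnings(as.numeric(sub("^MS", "", s)))
  if (anyNA(num)) as.numeric(factor(s, levels = unique(sort(s)))) else num
}

#' Balanced three-way fixed-effects ANOVA for one attribute
#'
#' Fits `score ~ sample + session + judge` plus all two-way
#' interactions on the scores of one attribute. The design must be
#' complete and balanced with exactly one observation per
#' judge x session x sample cell; the residual is then the three-way
#' interaction. Constant scores give zero sums of squares and the F
#' statistics are reported as `NA` (not applicable).
#'
#' @param scores a [SensoryScores] or equivalent data.frame.
#' @param attribute one of [sensoryAttributes()].
#' @return data.frame with columns `effect`, `df`, `sum_sq`, `mean_sq`,
#'   `f`, `p`; effects are `sample`, `session`, `judge`,
#'   `sample:session`, `sample:judge`, `session:judge`, `residual`.
#' @examples
#' sim <- generatePanelScores(seedCohortSpec(), nJudges = 6,
#'                            nSessions = 4, seed = 1)
#' threeWayAnova(sim$scores, "color")
#' @export
threeWayAnova <- function(scores, attribute) {
  df <- scoreTable(scores)
  df <- df[df$attribute == attribute, , drop = FALSE]
  if (!nrow(df)) stop("no scores for attribute '", attribute, "'")
  df$judge <- factor(df$judge); df$session <- factor(df$session)
  df$sample <- factor(df$sample)
  tab <- table(df$judge, df$session, df$sample)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    cells <- apply(head(bad, 5), 1, function(r)
      paste0("judge ", dimnames(tab)[[1]][r[1]], "/session ",
             dimnames(tab)[[2]][r[2]], "/sample ",
             dimnames(tab)[[3]][r[3]]))
    stop("unbalanced design: cell(s) without exactly one observation: ",
         paste(cells, collapse = "; "),
         if (nrow(bad) > 5) " ..." else "")
  }
  fit <- aov(score ~ (sample + session + judge)^2, data = df)
  s <- summary(fit)[[1]]
  eff <- trimws(rownames(s))
  eff[eff == "Residuals"] <- "residual"
  out <- data.frame(effect = eff, df = s$Df, sum_sq = s$`Sum Sq`,
                    mean_sq = s$`Mean Sq`, f = s$`F value`,
                    p = s$`Pr(>F)`, row.names = NULL)
  out$f[!is.finite(out$f)] <- NA
  out$p[!is.finite(out$p)] <- NA
  if (sum(out$sum_sq) < 1e-9 * (1 + mean(df$score)^2) * nrow(df)) {
    out$sum_sq <- 0                       # constant scores: F undefined
    out$mean_sq <- 0
    out$f <- NA_real_
    out$p <- NA_real_
  }
  out
}

## ---- Student-Newman-Keuls -------------------------------------------

# stepwise range testing on sorted means; marks homogeneous intervals
.snkIntervals <- function(means, se, dfErr, alpha) {
  k <- length(means)
  homog <- matrix(FALSE, k, k)
  sig <- function(i, j) {
    p <- j - i + 1
    delta <- means[j] - means[i]
    if (se == 0) return(delta > 0)
    qobs <- delta / se
    qobs > qtukey(1 - alpha, p, dfErr)
  }
  recurse <- function(i, j) {
    if (i >= j) return(invisible())
    if (homog[i, j]) return(invisible())
    if (!sig(i, j)) {
      homog[i, j] <<- TRUE
    } else {
      recurse(i, j - 1)
      recurse(i + 1, j)
    }
  }
  recurse(1, k)
  homog
}

#' Student-Newman-Keuls multiple comparison with letters display
#'
#' Stepwise studentized-range procedure on the sorted group means: the
#' full range is tested first and sub-ranges are examined only inside
#' significant stretches, with the critical value `q(1 - alpha, p, df)`
#' depending on the number of means `p` spanned. Groups spanned by a
#' non-significant stretch share a letter; letters are assigned in
#' ascending-mean order. Critical values come from the studentized
#' range distribution ([stats::qtukey()]), not from tables.
#'
#' @param x either a data.frame of raw scores with columns `group` and
#'   `value`, or a data.frame/matrix of group statistics with columns
#'   `mean`, `sd`, `n` (and optionally `group`).
#' @param alpha significance level (default 0.05).
#' @return list of class `"SnkGrouping"`: `groups` (data.frame sorted
#'   by mean with columns `group`, `mean`, `n`, `letters`), `alpha`,
#'   `mse`, `df`.
#' @examples
#' d <- data.frame(group = rep(c("A", "B", "C"), each = 10),
#'                 value = rnorm(30, rep(c(0, 5, 10), each = 10), 0.5))
#' snkTest(d)
#' @export
snkTest <- function(x, alpha = 0.05) {
  if (!is.null(x$value) && !is.null(x$group)) {
    grp <- factor(x$group)
    if (nlevels(grp) < 2) stop("at least 2 groups required")
    ns <- tapply(x$value, grp, length)
    if (any(ns < 2))
      stop("each group needs at least 2 raw observations")
    means <- tapply(x$value, grp, mean)
    vars <- tapply(x$value, grp, var)
    dfErr <- sum(ns - 1)
    mse <- sum((ns - 1) * vars) / dfErr
    names <- levels(grp)
  } else {
    x <- as.data.frame(x)
    if (is.null(x$mean) || is.null(x$sd) || is.null(x$n))
      stop("x must be raw scores (group, value) or stats (mean, sd, n)")
    if (nrow(x) < 2) stop("at least 2 groups required")
    means <- x$mean; ns <- x$n
    dfErr <- sum(ns - 1)
    mse <- sum((ns - 1) * x$sd^2) / dfErr
    names <- if (!is.null(x$group)) as.character(x$group) else
      paste0("G", seq_len(nrow(x)))
  }
  ord <- order(means)
  m <- as.numeric(means)[ord]
  nh <- length(ns) / sum(1 / ns)          # harmonic mean for unequal n
  se <- sqrt(mse / nh)
  homog <- .snkIntervals(m, se, dfErr, alpha)
  k <- length(m)
  # maximal homogeneous intervals (plus uncovered singletons)
  iv <- which(homog, arr.ind = TRUE)
  if (nrow(iv)) {
    keep <- vapply(seq_len(nrow(iv)), function(r) {
      !any(iv[, 1] <= iv[r, 1] & iv[, 2] >= iv[r, 2] &
             (iv[, 1] != iv[r, 1] | iv[, 2] != iv[r, 2]))
    }, logical(1))
    iv <- iv[keep, , drop = FALSE]
  }
  covered <- rep(FALSE, k)
  for (r in seq_len(nrow(iv))) covered[iv[r, 1]:iv[r, 2]] <- TRUE
  singles <- which(!covered)
  iv <- rbind(iv, cbind(singles, singles))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  lets <- rep("", k)
  for (r in seq_len(nrow(iv))) {
    span <- iv[r, 1]:iv[r, 2]
    lets[span] <- paste0(lets[span], letters[r])
  }
  out <- data.frame(group = names[ord], mean = m,
                    n = as.numeric(ns)[ord], letters = lets)
  structure(list(groups = out, alpha = alpha, mse = mse, df = dfErr),
            class = "SnkGrouping")
}

#' @export
print.SnkGrouping <- function(x, ...) {
  cat("SNK grouping (alpha =", x$alpha, ")\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Judges-as-variables homogeneity PCA
#'
#' Distinguishes scale effects from true disagreement behind a
#' significant judge x sample interaction. The samples x judges matrix
#' of session-averaged scores is column-standardized and decomposed by
#' PCA; if all judge loadings on the first component share a sign and
#' that component explains at least `varianceThreshold` percent, the
#' judges agree on the sample ordering and differ only in how they use
#' the scale (`"scale_effects"`); otherwise the diagnosis is
#' `"disagreement"`. Standardization makes the diagnosis invariant to
#' positive per-judge rescaling.
#'
#' @param scores a [SensoryScores] or data.frame.
#' @param attribute attribute to analyse.
#' @param varianceThreshold percent of variance component 1 must reach
#'   (default 60).
#' @return list of class `"PanelPcaResult"`: `loadings` (judges x
#'   components), `explained` (percent per component), `diagnosis`,
#'   `droppedJudges`.
#' @export
panelHomogeneityPca <- function(scores, attribute,
                                varianceThreshold = 60) {
  df <- scoreTable(scores)
  df <- df[df$attribute == attribute, , drop = FALSE]
  if (!nrow(df)) stop("no scores for attribute '", attribute, "'")
  M <- tapply(df$score, list(df$sample, df$judge), mean)
  if (anyNA(M)) stop("incomplete sample x judge design")
  sds <- apply(M, 2, sd)
  dropped <- colnames(M)[sds == 0]
  if (length(dropped)) {
    warning("zero-variance judge column(s) dropped: ",
            paste(dropped, collapse = ", "))
    M <- M[, sds > 0, drop = FALSE]
  }
  if (nrow(M) < 3 || ncol(M) < 3)
    stop("need at least 3 samples and 3 judges with variance")
  pr <- prcomp(M, center = TRUE, scale. = TRUE)
  explained <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  l1 <- pr$rotation[, 1]
  sameSign <- all(l1 >= 0) || all(l1 <= 0)
  diagnosis <- if (sameSign && explained[1] >= varianceThreshold)
    "scale_effects" else "disagreement"
  structure(list(loadings = pr$rotation, explained = explained,
                 diagnosis = diagnosis, droppedJudges = dropped),
            class = "PanelPcaResult")
}

#' @export
print.PanelPcaResult <- function(x, ...) {
  cat("Panel homogeneity PCA: diagnosis =", x$diagnosis, "\n")
  cat("  component 1 explains", sprintf("%.1f%%", x$explained[1]), "\n")
  invisible(x)
}

#' Screen out judges with outlying dispersion
#'
#' Computes, per judge, the mean within-(sample, attribute) score
#' variance across sessions (a repeatability statistic) and flags
#' judges whose dispersion exceeds the panel mean by more than
#' `ruleMultiple` panel standard deviations. Refuses to screen if
#' fewer than `minJudges` would remain.
#'
#' @param scores a [SensoryScores] or data.frame.
#' @param ruleMultiple dispersion cutoff in panel SDs (default 1.5).
#' @param minJudges minimum retained panel size (default 3).
#' @return list with `retained`, `flagged` (judge ids) and
#'   `dispersion` (data.frame judge, dispersion).
#' @export
judgeScreening <- function(scores, ruleMultiple = 1.5, minJudges = 3) {
  df <- scoreTable(scores)
  v <- tapply(df$score, list(df$judge, df$sample, df$attribute), var)
  disp <- apply(v, 1, mean, na.rm = TRUE)
  cut <- mean(disp) + ruleMultiple * sd(disp)
  flagged <- names(disp)[disp > cut & !is.na(disp)]
  retained <- setdiff(names(disp), flagged)
  if (length(retained) < minJudges)
    stop("screening would leave fewer than ", minJudges,
         " judges; refusing")
  list(retained = retained, flagged = flagged,
       dispersion = data.frame(judge = names(disp),
                               dispersion = as.numeric(disp)))
}

#' Linear trend of an attribute across maturity stages
#'
#' Ordinary least squares of the per-stage mean score on the stage
#' index (1..k). Attributes that track ripening closely (color,
#' vegetal) fit this regression with high R-squared.
#'
#' @param scores a [SensoryScores] or data.frame.
#' @param attribute attribute to analyse.
#' @return list with `slope`, `intercept`, `r_squared`, `degenerate`
#'   (TRUE when the stage means are constant and R-squared is reported
#'   as 0).
#' @export
attributeStageRegression <- function(scores, attribute) {
  df <- scoreTable(scores)
  df <- df[df$attribute == attribute, , drop = FALSE]
  if (!nrow(df)) stop("no scores for attribute '", attribute, "'")
  means <- tapply(df$score, df$sample, mean)
  idx <- .stageIndex(names(means))
  ord <- order(idx)
  means <- means[ord]; idx <- idx[ord]
  if (length(means) < 3) stop("need at least 3 stages")
  if (sd(means) == 0)
    return(list(slope = 0, intercept = unname(means[1]), r_squared = 0,
                degenerate = TRUE))
  fit <- lm(means ~ idx)
  r2 <- 1 - sum(fit$residuals^2) / sum((means - mean(means))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, degenerate = FALSE)
}
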