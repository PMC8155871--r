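## Sensory-instrumental integration: per-stage summaries, correlation
## matrices, redundancy pruning, and Kaiser-criterion PCA of the stage
## by variable matrix.

#' Reference stage means of the texture parameters for Syrah seeds
#'
#' Stage-mean values (and SDs) of the ten instrumental texture
#' parameters across five color-based maturity stages of Syrah grape
#' seeds, packaged as reference data for worked examples and
#' validation of the integration functions.
#'
#' @return list with `means` and `sds`, both 5 x 10 matrices (rows
#'   MS1..MS5; columns Np, Bf, Bdc, E, Be, De, Th, Bd, Si, Ar).
#' @examples
#' ref <- syrahStageMeans()
#' round(ref$means["MS1", "Bd"] / ref$means["MS1", "Th"], 2)  # Si
#' @export
syrahStageMeans <- function() {
  path <- system.file("extdata", "syrah_texture_stage_means.csv",
                      package = "seedstage", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  params <- unique(df$parameter)
  stages <- unique(df$stage)
  means <- matrix(NA_real_, length(stages), length(params),
                  dimnames = list(stages, params))
  sds <- means
  for (i in seq_len(nrow(df))) {
    means[df$stage[i], df$parameter[i]] <- df$mean[i]
    sds[df$stage[i], df$parameter[i]] <- df$sd[i]
  }
  list(means = means, sds = sds)
}

#' Per-stage means and SDs of instrumental and sensory variables
#'
#' Combines a texture-profile table (one row per seed, `stage` column
#' plus the ten parameter columns) and a sensory score table (scores
#' per judge x session x stage x attribute) into a stage x variable
#' summary. Every stage must be represented in both sources.
#'
#' @param profiles data.frame of texture profiles with a `stage` (or
#'   `label`) column.
#' @param scores a [SensoryScores] or data.frame; samples are stages.
#' @return A [StageSummary] with 16 columns (10 instrumental, 6
#'   sensory) when both sources carry the full variable sets.
#' @export
stageSummary <- function(profiles, scores) {
  texVars <- intersect(c("Np", "Bf", "Bdc", "E", "Be", "De", "Th",
                         "Bd", "Si", "Ar"), names(profiles))
  if (!length(texVars)) stop("profiles carry no texture parameter columns")
  pstage <- if (!is.null(profiles$label)) as.character(profiles$label)
            else as.character(profiles$stage)
  pstage <- ifelse(grepl("^MS", pstage), pstage, paste0("MS", pstage))
  sdf <- scoreTable(scores)
  sstage <- as.character(sdf$sample)
  sstage <- ifelse(grepl("^MS", sstage), sstage, paste0("MS", sstage))
  stages <- sort(union(unique(pstage), unique(sstage)))
  missP <- setdiff(stages, unique(pstage))
  missS <- setdiff(stages, unique(sstage))
  if (length(missP) || length(missS))
    stop("empty stage(s): ",
         paste(c(missP, missS), collapse = ", "),
         " not present in both data sources")
  attrs <- intersect(sensoryAttributes(), unique(sdf$attribute))
  vars <- c(texVars, attrs)
  means <- matrix(NA_real_, length(stages), length(vars),
                  dimnames = list(stages, vars))
  sds <- means; n <- means
  for (st in stages) {
    sub <- profiles[pstage == st, texVars, drop = FALSE]
    means[st, texVars] <- colMeans(sub)
    sds[st, texVars] <- apply(sub, 2, sd)
    n[st, texVars] <- nrow(sub)
    for (at in attrs) {
      v <- sdf$score[sstage == st & sdf$attribute == at]
      means[st, at] <- mean(v)
      sds[st, at] <- sd(v)
      n[st, at] <- length(v)
    }
  }
  sds[is.na(sds) & n == 1] <- 0
  StageSummary(means, sds, n)
}

#' Pearson correlation matrix over variables
#'
#' Computes Pearson correlations between all variable columns, either
#' of a [StageSummary] (correlations across the stage means, matching
#' the structure of published stage-level correlation tables) or of
#' any numeric observations x variables matrix (e.g. per-seed values).
#' Zero-variance variables yield `NA` entries with a warning; the
#' diagonal is always 1.
#'
#' @param x a [StageSummary], matrix or data.frame.
#' @return square correlation matrix with variable labels.
#' @examples
#' r <- correlationMatrix(syrahStageMeans()$means)
#' roundHalfUp(r["Np", "Bf"], 2)  # 0.99
#' @export
correlationMatrix <- function(x) {
  m <- if (is(x, "StageSummary")) stageMeans(x) else as.matrix(x)
  if (!is.numeric(m)) stop("x must be numeric")
  if (nrow(m) < 3) stop("need at least 3 observations per variable pair")
  sds <- apply(m, 2, sd)
  r <- suppressWarnings(cor(m))
  if (any(sds == 0)) {
    warning("zero-variance variable(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
    r[sds == 0, ] <- NA
    r[, sds == 0] <- NA
  }
  diag(r) <- 1
  r
}

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going away from zero (0.245 ->
#' 0.25 at 2 digits), the convention used in printed report tables.
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return rounded numeric of the same shape.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Drop redundant variables from a correlation matrix
#'
#' For every pair with `|r|` above the threshold, the less
#' interpretable member (the one later in the priority order) is
#' dropped; pairs are visited in priority order, so the result does
#' not depend on the column order of the matrix. The default priority
#' keeps Bf over Be, Bd over Be and Si over Ar, preferring the
#' parameters that are easier to read mechanically.
#'
#' @param corMat square correlation matrix with variable names.
#' @param threshold absolute correlation above which a pair is
#'   redundant (default 0.80, strict inequality).
#' @param priority character vector: earlier variables are kept
#'   preferentially. Variables absent from it rank after it, in name
#'   order. Default: `Np, Bf, Bdc, E, Th, Bd, Si, De, Be, Ar` followed
#'   by anything else.
#' @return list with `kept` (character), `dropped` (data.frame
#'   `kept_var`, `dropped_var`, `r`).
#' @export
pruneRedundant <- function(corMat, threshold = 0.80, priority = NULL) {
  vars <- colnames(corMat)
  if (is.null(vars)) stop("corMat must have variable names")
  if (is.null(priority))
    priority <- c("Np", "Bf", "Bdc", "E", "Th", "Bd", "Si", "De",
                  "Be", "Ar")
  rank <- c(intersect(priority, vars),
            sort(setdiff(vars, priority)))
  keep <- setNames(rep(TRUE, length(rank)), rank)
  dropped <- list()
  for (i in seq_along(rank)) {
    for (j in seq_along(rank)) {
      if (j <= i) next
      a <- rank[i]; b <- rank[j]
      if (!keep[a] || !keep[b]) next
      r <- corMat[a, b]
      if (!is.na(r) && abs(r) > threshold) {
        keep[b] <- FALSE
        dropped[[length(dropped) + 1]] <-
          data.frame(kept_var = a, dropped_var = b, r = r)
      }
    }
  }
  list(kept = rank[keep],
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(kept_var = character(), dropped_var = character(),
                    r = numeric()))
}

#' Kaiser-criterion PCA of the stage x variable matrix
#'
#' Column-standardized (by default) principal component analysis of a
#' stage-mean matrix. Constant columns are dropped with a warning.
#' Eigenvalues, percent explained variance, the number of components
#' retained under the Kaiser criterion (eigenvalue > 1), variable
#' loadings and stage scores are returned; with k centered rows at
#' most k - 1 components are non-null and they explain 100% of the
#' variance.
#'
#' @param x a [StageSummary], matrix or data.frame (rows = stages).
#' @param standardize scale columns to unit variance (default TRUE).
#' @return list of class `"PcaBiplotResult"`: `eigenvalues`,
#'   `explained` (percent), `kaiser` (retained count), `loadings`,
#'   `scores`, `dropped` (constant columns).
#' @examples
#' p <- pcaBiplot(syrahStageMeans()$means)
#' sum(p$explained[1:4])  # 100
#' @export
pcaBiplot <- function(x, standardize = TRUE) {
  m <- if (is(x, "StageSummary")) stageMeans(x) else as.matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 stages and 2 variables")
  sds <- apply(m, 2, sd)
  droppedCols <- colnames(m)[sds == 0]
  if (length(droppedCols)) {
    warning("constant column(s) dropped: ",
            paste(droppedCols, collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  pr <- prcomp(m, center = TRUE, scale. = standardize)
  ev <- pr$sdev^2
  structure(list(eigenvalues = ev,
                 explained = 100 * ev / sum(ev),
                 kaiser = sum(ev > 1),
                 loadings = pr$rotation,
                 scores = pr$x,
                 dropped = droppedCols),
            class = "PcaBiplotResult")
}

#' @export
print.PcaBiplotResult <- function(x, ...) {
  cat("PCA:", length(x$eigenvalues), "components;",
      x$kaiser, "retained (eigenvalue > 1)\n")
  cat("  explained %:",
      paste(sprintf("%.1f", x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Draw a PCA biplot of stages and variables
#'
#' Base-graphics biplot of a [pcaBiplot()] result: stage scores as
#' points, variable loadings as arrows, both on the first two
#' components.
#'
#' @param result a `"PcaBiplotResult"`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `result`.
#' @export
plotPcaBiplot <- function(result, ...) {
  sc <- result$scores; ld <- result$loadings
  scale <- max(abs(sc[, 1:2])) / max(abs(ld[, 1:2]))
  graphics::plot(sc[, 1], sc[, 2],
       xlab = sprintf("PC1 (%.1f%%)", result$explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", result$explained[2]),
       pch = 19, ...)
  graphics::text(sc[, 1], sc[, 2], rownames(sc), pos = 3, cex = 0.8)
  graphics::arrows(0, 0, ld[, 1] * scale * 0.8, ld[, 2] * scale * 0.8,
                   length = 0.08, col = "grey40")
  graphics::text(ld[, 1] * scale * 0.85, ld[, 2] * scale * 0.85,
                 rownames(ld), col = "grey20", cex = 0.8)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey70")
  invisible(result)
}
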