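## Percentile allocation of seeds into equal-size maturity stages from
## their CIELAB lightness and chroma. Seeds darken and lose chroma as
## they ripen, so the ripeness score is oriented to increase as L*
## decreases.

#' One-dimensional ripeness score from seed color records
#'
#' The default `"composite"` mode standardizes L* and C*ab and projects
#' them onto their first principal axis; the sign is fixed so that the
#' score increases as lightness decreases (darker seed = riper).
#' Single-variable modes use -L* or -C*ab directly. A coordinate with
#' zero variance is ignored in composite mode; if both are constant the
#' input is degenerate and an error is raised.
#'
#' @param records data.frame with columns `seed_id`, `L` and `C_ab`
#'   (a `C_ab` column is computed from `a`/`b` columns if absent).
#' @param mode `"composite"` (default), `"L"`, or `"C"`.
#' @return data.frame with columns `seed_id` and `score`, in input
#'   order.
#' @export
ripenessScore <- function(records, mode = c("composite", "L", "C")) {
  mode <- match.arg(mode)
  if (nrow(records) < 2) stop("at least 2 records required")
  if (is.null(records$L)) stop("records need an L column")
  if (is.null(records$C_ab)) {
    if (is.null(records$a) || is.null(records$b))
      stop("records need a C_ab column (or a and b columns)")
    records$C_ab <- sqrt(records$a^2 + records$b^2)
  }
  if (is.null(records$seed_id))
    records$seed_id <- seq_len(nrow(records))
  L <- records$L; C <- records$C_ab
  score <- switch(mode,
    L = -L,
    C = -C,
    composite = {
      cols <- list()
      if (sd(L) > 0) cols$L <- as.numeric(scale(L))
      if (sd(C) > 0) cols$C <- as.numeric(scale(C))
      if (!length(cols))
        stop("degenerate input: zero variance in both L and C_ab")
      X <- do.call(cbind, cols)
      s <- if (ncol(X) == 1) X[, 1] else prcomp(X, center = FALSE)$x[, 1]
      # polarity: riper seeds are darker (and, as fallback, less chromatic)
      or <- if (sd(L) > 0) -cor(s, L) else -cor(s, C)
      if (or < 0) s <- -s
      s
    })
  data.frame(seed_id = records$seed_id, score = score)
}

#' Allocate seeds to equal-size maturity stages by score percentiles
#'
#' Sorts seeds by score (ties broken by `seed_id` for determinism) and
#' splits them into `k` contiguous groups whose sizes differ by at most
#' one; sizes are exactly equal when `k` divides `n`, and the first
#' `n %% k` groups take the extra seed otherwise. Stage 1 collects the
#' lowest scores (least mature).
#'
#' @param scores data.frame from [ripenessScore()] (columns `seed_id`,
#'   `score`) or a numeric vector of scores.
#' @param k number of stages (default 5).
#' @return data.frame with columns `seed_id`, `score`, `stage`
#'   (integer 1..k) and `label` (factor `"MS1"`..`"MSk"`), in input
#'   order.
#' @examples
#' a <- classifyByPercentiles(data.frame(seed_id = 1:100,
#'                                       score = rnorm(100)))
#' table(a$stage)  # five groups of 20
#' @export
classifyByPercentiles <- function(scores, k = 5) {
  if (is.numeric(scores))
    scores <- data.frame(seed_id = seq_along(scores), score = scores)
  n <- nrow(scores)
  if (n < k) stop("need at least k = ", k, " seeds, got ", n)
  ord <- order(scores$score, scores$seed_id)
  q <- n %/% k; r <- n %% k
  sizes <- rep(q, k) + c(rep(1L, r), rep(0L, k - r))
  stage <- integer(n)
  stage[ord] <- rep(seq_len(k), times = sizes)
  labels <- paste0("MS", seq_len(k))
  data.frame(seed_id = scores$seed_id, score = scores$score,
             stage = stage,
             label = factor(labels[stage], levels = labels))
}

#' Stratified split of staged seeds into sensory and texture sets
#'
#' Randomly draws `textureN` seeds for the instrumental texture subset,
#' stratified to preserve stage proportions (equal stages give an equal
#' per-stage allocation; any remainder is assigned to the lowest
#' stages). The remaining seeds form the sensory set. Reproducible for
#' a fixed `seed`.
#'
#' @param assignments data.frame from [classifyByPercentiles()].
#' @param textureN total number of seeds for the texture set.
#' @param seed RNG seed.
#' @return list with elements `sensory` and `texture`, each a subset of
#'   `assignments`.
#' @export
splitSets <- function(assignments, textureN = 50, seed = 1) {
  if (textureN > nrow(assignments))
    stop("requested ", textureN, " texture seeds but only ",
         nrow(assignments), " available")
  stages <- sort(unique(assignments$stage))
  k <- length(stages)
  counts <- table(factor(assignments$stage, levels = stages))
  prop <- as.numeric(counts) / sum(counts)
  alloc <- floor(textureN * prop)
  rem <- textureN - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  if (any(alloc > counts))
    stop("requested per-stage allocation exceeds availability in stage ",
         paste(stages[alloc > counts], collapse = ", "))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  texIdx <- unlist(lapply(seq_len(k), function(i) {
    idx <- which(assignments$stage == stages[i])
    idx[sample.int(length(idx), alloc[i])]
  }))
  texIdx <- sort(texIdx)
  list(sensory = assignments[-texIdx, , drop = FALSE],
       texture = assignments[texIdx, , drop = FALSE])
}
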