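## Synthetic cohorts with known ground truth: gridded seed images,
## piecewise-linear force-distance curves, and panel score tables.
## Defaults emulate the study conditions: five maturity stages, a
## greenish-light to dark-brown color trend, texture trends anchored on
## the reference stage means, and a panel whose judges agree on sample
## ordering but use the scale with different gain and offset.

#' Specification of a synthetic seed cohort
#'
#' Bundles every tunable of the generators: the per-stage CIELAB color
#' palette (L* decreasing, chroma decreasing, hue drifting from
#' green-yellow toward brown), per-stage texture parameter trends
#' (means/SDs for Bf, E, Th, Np, Bdc), per-stage sensory attribute
#' means (color/hardness/cracking increasing, vegetal/bitterness/
#' astringency decreasing), judge scale-effect magnitudes, and noise
#' levels.
#'
#' @param nSeeds cohort size (default 480 = five 96-seed images).
#' @param kStages number of maturity stages (default 5).
#' @param pixelNoiseSd per-channel RGB noise SD in 8-bit units
#'   (default 2).
#' @param forceNoiseSd force noise SD in N for generated curves
#'   (default 1).
#' @param residSd residual SD of panel scores (default 0.8).
#' @param judgeGainSd,judgeBiasSd SDs of the per-judge multiplicative
#'   gain (around 1) and additive bias (around 0).
#' @param sessionSd SD of per-session shifts; 0 by default so the
#'   session main effect is null by construction.
#' @param rngSeed default RNG seed for the generators.
#' @return list of class `"CohortSpec"`.
#' @export
seedCohortSpec <- function(nSeeds = 480, kStages = 5,
                           pixelNoiseSd = 2, forceNoiseSd = 1,
                           residSd = 0.8, judgeGainSd = 0.15,
                           judgeBiasSd = 0.5, sessionSd = 0,
                           rngSeed = 101) {
  if (nSeeds < kStages) stop("nSeeds must be at least kStages")
  stages <- seq_len(kStages)
  frac <- (stages - 1) / max(kStages - 1, 1)
  palette <- data.frame(
    stage = stages,
    L = 64 - 32 * frac,           # 64 -> 32: light to dark
    C = 34 - 23 * frac,           # 34 -> 11: chromatic to dull
    h = 100 - 30 * frac,          # green-yellow -> brown hue
    sdL = 2, sdC = 2)
  textureTrends <- data.frame(
    stage = stages,
    bf = approx(c(1, kStages), c(50.4, 56.8), n = kStages)$y,
    bfSd = 5,
    e = approx(c(1, kStages), c(98, 104), n = kStages)$y,
    eSd = 6,
    th = approx(c(1, kStages), c(2.2, 3.3), n = kStages)$y,
    thSd = 0.15,
    np = approx(c(1, kStages), c(3.7, 4.2), n = kStages)$y,
    bdc = approx(c(1, kStages), c(20, 19), n = kStages)$y,
    bdcSd = 4)
  sensoryTrends <- rbind(
    color       = approx(c(1, kStages), c(2.0, 5.5), n = kStages)$y,
    hardness    = approx(c(1, kStages), c(4.0, 7.0), n = kStages)$y,
    cracking    = approx(c(1, kStages), c(3.5, 6.5), n = kStages)$y,
    vegetal     = approx(c(1, kStages), c(7.0, 3.0), n = kStages)$y,
    bitterness  = approx(c(1, kStages), c(6.5, 4.1), n = kStages)$y,
    astringency = approx(c(1, kStages), c(6.0, 4.0), n = kStages)$y)
  colnames(sensoryTrends) <- paste0("MS", stages)
  structure(list(nSeeds = nSeeds, kStages = kStages, palette = palette,
                 textureTrends = textureTrends,
                 sensoryTrends = sensoryTrends,
                 pixelNoiseSd = pixelNoiseSd,
                 forceNoiseSd = forceNoiseSd, residSd = residSd,
                 judgeGainSd = judgeGainSd, judgeBiasSd = judgeBiasSd,
                 sessionSd = sessionSd,
                 seedAxesFrac = c(0.33, 0.23),  # ellipse semi-axes / cell
                 rngSeed = rngSeed),
            class = "CohortSpec")
}

#' Generate a synthetic cabinet image of gridded seeds
#'
#' Draws one non-touching ellipse per grid cell on a light-gray
#' background (emulating the white cabinet plate), colored from the
#' per-stage palette in CIELAB with per-seed (L*, C*ab) jitter, plus
#' optional per-pixel RGB noise. Colors are quantized to 8 bits, and
#' the ground truth records the stage and the realized (quantized)
#' CIELAB color of every cell, so noise-free regions can be checked
#' for exact recovery.
#'
#' @param spec a [seedCohortSpec()].
#' @param rows,cols grid layout (default 8 x 12).
#' @param cellPx cell edge length in pixels (default 40).
#' @param stages optional integer vector (length rows * cols) of true
#'   stages per cell, row-major; default: a balanced random
#'   assignment.
#' @param noiseSd per-channel pixel noise SD; default
#'   `spec$pixelNoiseSd`.
#' @param seed RNG seed; default `spec$rngSeed`.
#' @return list with `image` (rows*cellPx x cols*cellPx x 3 array,
#'   8-bit values) and `truth` (data.frame `row`, `col`, `stage`, `L`,
#'   `C` with the realized per-seed color).
#' @export
generateSeedImage <- function(spec, rows = 8, cols = 12, cellPx = 40,
                              stages = NULL, noiseSd = spec$pixelNoiseSd,
                              seed = spec$rngSeed) {
  set.seed(seed)
  nCells <- rows * cols
  if (is.null(stages))
    stages <- sample(rep(seq_len(spec$kStages), length.out = nCells))
  if (length(stages) != nCells)
    stop("stages must have length rows * cols")
  ax <- spec$seedAxesFrac * cellPx
  if (max(ax) > cellPx / 2 - 4)
    stop("ellipse radii too large for the grid cell")
  H <- rows * cellPx; W <- cols * cellPx
  img <- array(230, c(H, W, 3))
  truth <- data.frame(row = integer(nCells), col = integer(nCells),
                      stage = integer(nCells), L = numeric(nCells),
                      C = numeric(nCells))
  cell <- 0
  for (r in seq_len(rows)) for (cl in seq_len(cols)) {
    cell <- cell + 1
    st <- stages[cell]
    pal <- spec$palette[spec$palette$stage == st, ]
    L <- rnorm(1, pal$L, pal$sdL)
    C <- max(rnorm(1, pal$C, pal$sdC), 0.5)
    hrad <- pal$h * pi / 180
    rgb <- round(labToSrgb(c(L, C * cos(hrad), C * sin(hrad))))
    cy <- (r - 0.5) * cellPx + round(runif(1, -3, 3))
    cx <- (cl - 0.5) * cellPx + round(runif(1, -3, 3))
    a <- ax[1] * runif(1, 0.85, 1)    # column direction
    b <- ax[2] * runif(1, 0.85, 1)    # row direction
    yy <- max(1, floor(cy - b)):min(H, ceiling(cy + b))
    xx <- max(1, floor(cx - a)):min(W, ceiling(cx + a))
    sel <- outer((yy - cy)^2 / b^2, (xx - cx)^2 / a^2, "+") <= 1
    for (ch in 1:3) {
      plane <- img[yy, xx, ch]
      plane[sel] <- rgb[ch]
      img[yy, xx, ch] <- plane
    }
    lab <- srgbToLab(rgb)
    truth$row[cell] <- r; truth$col[cell] <- cl
    truth$stage[cell] <- st
    truth$L[cell] <- lab["L"]
    truth$C[cell] <- unname(chromaHue(lab["a"], lab["b"])["C_ab"])
  }
  if (noiseSd > 0)
    img <- img + array(rnorm(length(img), 0, noiseSd), dim(img))
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, truth = truth)
}

# exact area under a polyline up to a breakpoint index
.polyArea <- function(d, f, upto = length(d)) {
  i <- seq_len(upto - 1)
  sum((d[i + 1] - d[i]) * (f[i + 1] + f[i]) / 2)
}

#' Generate a piecewise-linear compression curve with known truth
#'
#' Builds the canonical seed-compression template: a linear rise at
#' slope E to the break point (Bd, Bf), a sharp drop of Bdc, then
#' Np - 1 subfragmentation bumps, ending when the probe reaches half
#' the seed thickness. Breakpoint distances are snapped to the sample
#' grid (probe speed / sample rate), so the trapezoidal energies of
#' the sampled curve equal the recorded closed-form values exactly.
#' Gaussian force noise is added on request.
#'
#' @param spec a [seedCohortSpec()].
#' @param stage maturity stage (1..kStages) whose trend parameters are
#'   drawn from.
#' @param bf,e,th,np,bdc optional overrides of the drawn parameters.
#' @param noiseSd force noise SD in N; default `spec$forceNoiseSd`.
#' @param seed optional RNG seed.
#' @return list with `curve` (a [ForceDistanceCurve]), `truth` (a
#'   [TextureProfile]) and `breakpoints` (data.frame of the underlying
#'   polyline).
#' @export
generateCurve <- function(spec, stage, bf = NULL, e = NULL, th = NULL,
                          np = NULL, bdc = NULL,
                          noiseSd = spec$forceNoiseSd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- spec$textureTrends[spec$textureTrends$stage == stage, ]
  if (!nrow(tr)) stop("stage ", stage, " not in spec")
  if (is.null(bf)) bf <- max(rnorm(1, tr$bf, tr$bfSd), 25)
  if (is.null(e)) e <- max(rnorm(1, tr$e, tr$eSd), 40)
  if (is.null(th)) th <- max(rnorm(1, tr$th, tr$thSd), 1.2)
  if (is.null(np)) np <- max(1, round(rnorm(1, tr$np, 1)))
  if (is.null(bdc)) bdc <- rnorm(1, tr$bdc, tr$bdcSd)
  bdc <- min(max(bdc, 0.25 * bf), 0.9 * bf)  # guarantees the 20% rule
  dx <- 1.0 / 500                            # probe speed / sample rate, mm
  snap <- function(d) round(d / dx) * dx
  dEnd <- snap(th / 2)
  bd <- snap(bf / e)
  if (bd > dEnd - dx)
    stop("inconsistent parameters: break distance exceeds half the ",
         "thickness (bd = ", round(bf / e, 3), ", th/2 = ",
         round(th / 2, 3), ")")
  bf <- e * bd                               # keep the rise exactly linear
  dropW <- 2 * dx
  d <- c(0, bd, min(bd + dropW, dEnd))
  f <- c(0, bf, bf - bdc)
  room <- dEnd - d[length(d)]
  minBump <- 8 * dx
  m <- min(np - 1, floor(room / minBump))
  if (m > 0) {
    edges <- snap(seq(d[length(d)], dEnd, length.out = m + 1))
    vallPrev <- bf - bdc
    for (i in seq_len(m)) {
      pk <- snap((edges[i] + edges[i + 1]) / 2)
      # each bump must rise clear of the previous valley so that it is
      # a genuine local maximum with prominence well above threshold
      hgt <- runif(1, max(0.6 * bf, vallPrev + 6), 0.9 * bf)
      vall <- max(hgt - runif(1, 8, 14), 1)
      d <- c(d, pk, edges[i + 1])
      f <- c(f, hgt, vall)
      vallPrev <- vall
    }
  } else if (d[length(d)] < dEnd) {
    d <- c(d, dEnd)
    f <- c(f, bf - bdc)
  }
  keep <- !duplicated(d)
  d <- d[keep]; f <- f[keep]
  trueNp <- 1 + m
  grid <- dx * (0:round(dEnd / dx))
  force <- approx(d, f, xout = grid, rule = 2)$y
  be <- .polyArea(d, f, upto = which.min(abs(d - bd)))
  de <- .polyArea(d, f)
  truth <- TextureProfile(np = trueNp, bf = bf, bdc = bdc, e = e,
                          be = be, de = de, th = 2 * dEnd, bd = bd)
  if (noiseSd > 0) force <- force + rnorm(length(force), 0, noiseSd)
  list(curve = ForceDistanceCurve(grid, force),
       truth = truth,
       breakpoints = data.frame(distance = d, force = f))
}

#' Generate a balanced panel score table with known effect components
#'
#' Scores follow `clip(gain_j * stageMean + bias_j + sessionShift +
#' residual, 0, 10)`: a real sample (stage) effect, per-judge
#' multiplicative and additive scale effects, a session main effect
#' that is zero by construction (default `sessionSd = 0`), and
#' Gaussian residual noise. Default effect sizes keep the means well
#' inside the 0-10 scale so clipping is negligible.
#'
#' @param spec a [seedCohortSpec()].
#' @param nJudges number of judges (>= 3; default 17).
#' @param nSessions number of sessions (>= 2; default 8).
#' @param attributes attributes to generate (default all six).
#' @param judgeGains optional vector of per-judge gains (overrides the
#'   random gains; negative values simulate disagreeing judges).
#' @param judgeBiases optional vector of per-judge additive biases
#'   (e.g. a bias near 10 keeps a negative-gain judge on the scale).
#' @param nullSample if TRUE the stage means are flattened to their
#'   average, removing the sample effect (for calibration studies).
#' @param seed RNG seed; default `spec$rngSeed`.
#' @return list with `scores` (a [SensoryScores]) and `truth` (list:
#'   `stageMeans`, `gains`, `biases`, `sessionShifts`).
#' @export
generatePanelScores <- function(spec, nJudges = 17, nSessions = 8,
                                attributes = sensoryAttributes(),
                                judgeGains = NULL, judgeBiases = NULL,
                                nullSample = FALSE,
                                seed = spec$rngSeed) {
  if (nJudges < 3) stop("need at least 3 judges")
  if (nSessions < 2) stop("need at least 2 sessions")
  set.seed(seed)
  k <- spec$kStages
  stageLabels <- paste0("MS", seq_len(k))
  trends <- spec$sensoryTrends[attributes, , drop = FALSE]
  if (nullSample)
    trends <- matrix(rowMeans(trends), nrow(trends), ncol(trends),
                     dimnames = dimnames(trends))
  gains <- if (is.null(judgeGains))
    pmax(rnorm(nJudges, 1, spec$judgeGainSd), 0.2) else judgeGains
  biases <- if (is.null(judgeBiases))
    rnorm(nJudges, 0, spec$judgeBiasSd) else judgeBiases
  shifts <- if (spec$sessionSd > 0)
    rnorm(nSessions, 0, spec$sessionSd) else rep(0, nSessions)
  grid <- expand.grid(judge = seq_len(nJudges),
                      session = seq_len(nSessions),
                      sample = seq_len(k),
                      attribute = attributes,
                      stringsAsFactors = FALSE)
  mu <- trends[cbind(match(grid$attribute, rownames(trends)),
                     grid$sample)]
  raw <- gains[grid$judge] * mu + biases[grid$judge] +
    shifts[grid$session] + rnorm(nrow(grid), 0, spec$residSd)
  grid$score <- pmin(pmax(raw, 0), 10)
  grid$judge <- paste0("J", grid$judge)
  grid$session <- paste0("S", grid$session)
  grid$sample <- stageLabels[grid$sample]
  list(scores = SensoryScores(grid),
       truth = list(stageMeans = trends, gains = gains, biases = biases,
                    sessionShifts = shifts))
}
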