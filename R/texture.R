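## Force-distance curve analysis for single-seed compression tests.
## A seed compressed at constant speed shows a near-linear force rise
## until it breaks (the force drops sharply), then successive smaller
## subfragmentation peaks until the probe reaches half the initial
## seed height. Ten parameters summarize each curve; see
## [TextureProfile-class].

#' Read a force-distance (or time-force) curve file
#'
#' Accepts CSV or TSV with a header naming either `distance_mm,force_N`
#' or `time_s,force_N` (a bare `distance`/`time`/`force` prefix also
#' matches). Time series are converted to distance via the probe speed.
#' Leading samples below the activation (trigger) force are trimmed and
#' distance is re-zeroed at the trigger sample.
#'
#' @param path path to the curve file.
#' @param sampleRate,probeSpeed,activationForce acquisition settings
#'   (defaults: 500 samples/s, 1.0 mm/s, 0.049 N, i.e. 5 g).
#' @param minSamples minimum number of post-trigger samples (default
#'   10).
#' @return A [ForceDistanceCurve].
#' @export
readCurve <- function(path, sampleRate = 500, probeSpeed = 1.0,
                      activationForce = 0.049, minSamples = 10) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  dCol <- grep("^distance", nm)
  tCol <- grep("^time", nm)
  fCol <- grep("^force", nm)
  if (length(fCol) != 1 || (length(dCol) + length(tCol)) != 1)
    stop("curve file must have two columns: force plus distance or time")
  force <- df[[fCol]]
  dist <- if (length(dCol)) df[[dCol]] else df[[tCol]] * probeSpeed
  if (!is.numeric(force) || !is.numeric(dist) ||
      anyNA(force) || anyNA(dist))
    stop("non-numeric rows in curve file: ", path)
  trig <- which(force >= activationForce)
  if (!length(trig))
    stop("no sample reaches the activation force in ", path)
  keep <- trig[1]:length(force)
  dist <- dist[keep] - dist[trig[1]]
  force <- force[keep]
  if (length(force) < minSamples)
    stop("fewer than ", minSamples, " post-trigger samples in ", path)
  ForceDistanceCurve(dist, force, sampleRate = sampleRate,
                     probeSpeed = probeSpeed,
                     activationForce = activationForce)
}

#' Smooth the force signal with a centered moving average
#'
#' Averages over an odd window of samples centered on each point;
#' near the ends the window shrinks symmetrically so the average stays
#' centered. Distances are unchanged. `window = 1` is the identity.
#'
#' @param curve a [ForceDistanceCurve].
#' @param window odd window length in samples (default 5, i.e. 0.01 mm
#'   at 500 samples/s and 1 mm/s).
#' @return A smoothed [ForceDistanceCurve].
#' @export
smoothCurve <- function(curve, window = 5) {
  n <- length(curve)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window > n) stop("window (", window, ") larger than curve (", n, ")")
  if (window == 1) return(curve)
  h <- (window - 1) / 2
  f <- curve@force
  cs <- c(0, cumsum(f))
  i <- seq_len(n)
  hi <- pmin(h, i - 1, n - i)    # symmetric shrink at the ends
  sm <- (cs[i + hi + 1] - cs[i - hi]) / (2 * hi + 1)
  ForceDistanceCurve(curve@distance, sm, sampleRate = curve@sampleRate,
                     probeSpeed = curve@probeSpeed,
                     activationForce = curve@activationForce)
}

#' Detect force peaks by topographic prominence
#'
#' Local maxima of the (already smoothed) force signal whose prominence
#' is at least `minProminence`. The prominence of a peak is its height
#' above the higher of the two lowest points separating it from higher
#' terrain on either side (or from the signal ends). Endpoints and a
#' final plateau are never counted as peaks.
#'
#' @param curve a [ForceDistanceCurve], normally smoothed first.
#' @param minProminence minimum prominence in N (default 1).
#' @return integer vector of peak sample indices in distance order
#'   (possibly empty).
#' @export
detectPeaks <- function(curve, minProminence = 1) {
  f <- curve@force
  n <- length(f)
  if (n < 3) return(integer(0))
  # candidate local maxima; plateaus contribute their middle sample
  cand <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (f[i] > f[i - 1]) {
      j <- i
      while (j < n && f[j + 1] == f[j]) j <- j + 1
      if (j < n && f[j + 1] < f[j]) cand <- c(cand, (i + j) %/% 2)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    hp <- f[p]
    leftHigher <- which(f[seq_len(p - 1)] > hp)
    ls <- if (length(leftHigher)) max(leftHigher) + 1 else 1
    leftMin <- if (ls <= p - 1) min(f[ls:(p - 1)]) else hp
    rseg <- (p + 1):n
    rightHigher <- rseg[f[rseg] > hp]
    re <- if (length(rightHigher)) min(rightHigher) - 1 else n
    rightMin <- if (p + 1 <= re) min(f[(p + 1):re]) else hp
    hp - max(leftMin, rightMin)
  }, numeric(1))
  cand[prom >= minProminence]
}

#' Locate the seed break on a force-distance curve
#'
#' The break is the first detected peak that is followed, before the
#' next peak (or the end of the curve), by a relative force drop of at
#' least `dropFraction` of the peak force. This quantifies the rapid
#' decrease of the load signal when the seed cracks. Because a purely
#' relative rule would fire on newton-scale wiggles low on the rise,
#' the drop must also exceed `minDrop` newtons; a genuine seed crunch
#' releases tens of newtons, so the default 4 N only guards the noise
#' floor.
#'
#' @param curve the [ForceDistanceCurve] the peaks were detected on.
#' @param peaks integer peak indices from [detectPeaks()].
#' @param dropFraction minimum relative drop (default 0.2).
#' @param minDrop minimum absolute drop in N (default 4; set to 0 for
#'   the purely relative rule).
#' @return A list of class `"BreakEvent"` with `index`, `distance`
#'   (mm), `forceBefore` (peak force, N) and `forceAfterMin` (minimum
#'   force before the next peak, N).
#' @export
detectBreak <- function(curve, peaks, dropFraction = 0.2, minDrop = 4) {
  f <- curve@force
  n <- length(f)
  if (!length(peaks))
    stop("no break detected: curve has no prominent peaks")
  bounds <- c(peaks[-1], n)
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    seg <- f[p:bounds[i]]
    drop <- f[p] - min(seg)
    if (drop >= dropFraction * f[p] && drop >= minDrop) {
      return(structure(list(index = p, distance = curve@distance[p],
                            forceBefore = f[p],
                            forceAfterMin = min(seg)),
                       class = "BreakEvent"))
    }
  }
  stop("no break detected: no peak shows a relative force drop >= ",
       dropFraction)
}

#' @export
print.BreakEvent <- function(x, ...) {
  cat(sprintf("BreakEvent at sample %d (%.3f mm): %.2f N -> %.2f N\n",
              x$index, x$distance, x$forceBefore, x$forceAfterMin))
  invisible(x)
}

#' Elasticity (pre-break slope) of a compression curve
#'
#' Ordinary least-squares slope of force against distance from the
#' first sample whose force reaches `forceFloor` (10 N by default, to
#' skip contact-settling fluctuations) through the break sample.
#'
#' @param curve raw [ForceDistanceCurve].
#' @param breakEvent a `"BreakEvent"` (or a break sample index).
#' @param forceFloor starting force, N.
#' @return slope in N/mm.
#' @export
elasticity <- function(curve, breakEvent, forceFloor = 10) {
  bIdx <- if (inherits(breakEvent, "BreakEvent")) breakEvent$index
          else as.integer(breakEvent)
  f <- curve@force; d <- curve@distance
  start <- which(f[seq_len(bIdx)] >= forceFloor)
  if (!length(start) || start[1] >= bIdx)
    stop("no usable pre-break segment: force never reaches ",
         forceFloor, " N before the break")
  seg <- start[1]:bIdx
  unname(coef(lm(f[seg] ~ d[seg]))[2])
}

#' Work done over a portion of a force-distance curve
#'
#' Trapezoidal integration of force over distance between two sample
#' indices. With force in N and distance in mm the result is in
#' N.mm = mJ.
#'
#' @param curve a [ForceDistanceCurve].
#' @param from,to sample indices, `from < to`.
#' @return energy in mJ.
#' @export
integrateEnergy <- function(curve, from, to) {
  if (from >= to) stop("'from' must be smaller than 'to'")
  n <- length(curve)
  if (from < 1 || to > n) stop("indices outside the curve")
  idx <- from:to
  pracma::trapz(curve@distance[idx], curve@force[idx])
}

#' Extract the ten texture parameters from a compression curve
#'
#' Pipeline: truncate the retract segment (everything after the maximum
#' distance), smooth the force with a centered moving average, detect
#' prominent peaks and the break on the smoothed signal, then measure
#' all quantities on the raw curve. The break sample is refined to the
#' raw local maximum within half a smoothing window of the smoothed
#' peak, so that smoothing locates features without biasing the
#' measured forces. Np counts all prominent maxima over the whole
#' assay (break plus subfragmentation peaks).
#'
#' Parameters: Np (peak count), Bf (force at the break), Bdc (drop from
#' Bf to the minimum force before the next peak), E (pre-break slope
#' from the 10 N crossing), Be (energy up to the break), De (energy
#' over the whole curve), Th (twice the total probe travel, because the
#' test stops at half the seed height), Bd (distance at the break),
#' Si = Bd/Th and Ar = Be/De, both stored as fractions.
#'
#' @param curve a raw [ForceDistanceCurve] (post-trigger).
#' @param window smoothing window in samples (odd, default 5).
#' @param minProminence peak prominence threshold in N (default 1).
#' @param dropFraction break drop rule (default 0.2).
#' @param minDrop absolute break-drop floor in N (default 4), see
#'   [detectBreak()].
#' @param forceFloor elasticity floor in N (default 10).
#' @return A [TextureProfile].
#' @examples
#' sim <- generateCurve(seedCohortSpec(), stage = 3, noiseSd = 0,
#'                      seed = 1)
#' textureProfile(sim$curve)
#' @export
textureProfile <- function(curve, window = 5, minProminence = 1,
                           dropFraction = 0.2, minDrop = 4,
                           forceFloor = 10) {
  # drop the probe-retract segment, if recorded
  last <- which.max(curve@distance)
  if (last < length(curve))
    curve <- ForceDistanceCurve(curve@distance[seq_len(last)],
                                curve@force[seq_len(last)],
                                sampleRate = curve@sampleRate,
                                probeSpeed = curve@probeSpeed,
                                activationForce = curve@activationForce)
  n <- length(curve)
  sm <- smoothCurve(curve, window)
  peaks <- detectPeaks(sm, minProminence)
  br <- detectBreak(sm, peaks, dropFraction, minDrop)
  h <- (window - 1) %/% 2
  nb <- max(1, br$index - h):min(n, br$index + h)
  bIdx <- nb[which.max(curve@force[nb])]
  bf <- curve@force[bIdx]
  bd <- curve@distance[bIdx]
  nextPeak <- peaks[peaks > br$index]
  hi <- if (length(nextPeak)) nextPeak[1] else n
  bdc <- bf - min(curve@force[bIdx:hi])
  e <- elasticity(curve, bIdx, forceFloor)
  be <- integrateEnergy(curve, 1, bIdx)
  de <- integrateEnergy(curve, 1, n)
  th <- 2 * max(curve@distance)
  TextureProfile(np = length(peaks), bf = bf, bdc = bdc, e = e,
                 be = be, de = de, th = th, bd = bd)
}

#' Batch texture extraction over curve files
#'
#' Runs [readCurve()] + [textureProfile()] over a directory (or an
#' explicit vector of paths). Curves without a detectable break are
#' flagged and omitted from the profile table, mirroring the QC
#' behaviour of the single-curve extractor.
#'
#' @param paths a directory containing curve CSV/TSV files, or a
#'   character vector of file paths.
#' @param seedIds optional ids (default: file name without extension).
#' @param ... passed to [textureProfile()].
#' @return list with `profiles` (data.frame: `seed_id`, the ten
#'   parameter columns, `qc = "ok"`) and `flagged` (data.frame:
#'   `seed_id`, `reason`).
#' @export
textureProfiles <- function(paths, seedIds = NULL, ...) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.(csv|tsv)$",
                             full.names = TRUE))
  if (is.null(seedIds))
    seedIds <- tools::file_path_sans_ext(basename(paths))
  rows <- list(); flagged <- list()
  for (i in seq_along(paths)) {
    res <- tryCatch(
      textureProfile(readCurve(paths[i]), ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      flagged[[length(flagged) + 1]] <-
        data.frame(seed_id = seedIds[i], reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <-
        cbind(data.frame(seed_id = seedIds[i]), as.data.frame(res),
              data.frame(qc = "ok"))
    }
  }
  list(profiles = if (length(rows)) do.call(rbind, rows) else
         data.frame(),
       flagged = if (length(flagged)) do.call(rbind, flagged) else
         data.frame(seed_id = character(), reason = character()))
}
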