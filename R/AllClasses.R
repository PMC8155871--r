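## Core S4 containers. Validity methods enforce the physical identities
## that every downstream computation relies on.

#' ForceDistanceCurve: a compression-test trace
#'
#' Ordered (distance, force) samples from a single-seed compression
#' test, together with the acquisition settings of the texture
#' analyzer. Distances are in mm and non-decreasing, forces in N.
#'
#' @slot distance numeric vector of probe travel, mm, non-decreasing.
#' @slot force numeric vector of load-cell force, N, finite.
#' @slot sampleRate acquisition rate, samples per second (default 500).
#' @slot probeSpeed probe speed during the test, mm/s (default 1.0).
#' @slot activationForce trigger force, N (default 0.049, i.e. 5 g).
#'
#' @param distance,force numeric vectors of equal length.
#' @param sampleRate,probeSpeed,activationForce acquisition settings.
#' @return A `ForceDistanceCurve` object.
#' @examples
#' fd <- ForceDistanceCurve(distance = seq(0, 1, by = 0.002),
#'                          force = 100 * seq(0, 1, by = 0.002))
#' length(fd)
#' @export
setClass("ForceDistanceCurve",
  representation(distance = "numeric", force = "numeric",
                 sampleRate = "numeric", probeSpeed = "numeric",
                 activationForce = "numeric"))

setValidity("ForceDistanceCurve", function(object) {
  msg <- NULL
  if (length(object@distance) != length(object@force))
    msg <- c(msg, "distance and force must have the same length")
  if (length(object@distance) >= 2 && any(diff(object@distance) < 0))
    msg <- c(msg, "distances must be non-decreasing")
  if (any(!is.finite(object@force)))
    msg <- c(msg, "forces must be finite")
  if (length(object@sampleRate) != 1 || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a positive scalar")
  if (length(object@probeSpeed) != 1 || object@probeSpeed <= 0)
    msg <- c(msg, "probeSpeed must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' @rdname ForceDistanceCurve-class
#' @export
ForceDistanceCurve <- function(distance, force, sampleRate = 500,
                               probeSpeed = 1.0, activationForce = 0.049) {
  new("ForceDistanceCurve", distance = as.numeric(distance),
      force = as.numeric(force), sampleRate = sampleRate,
      probeSpeed = probeSpeed, activationForce = activationForce)
}

#' @describeIn ForceDistanceCurve-class number of samples
#' @param x a `ForceDistanceCurve`.
#' @export
setMethod("length", "ForceDistanceCurve", function(x) length(x@distance))

#' @describeIn ForceDistanceCurve-class coerce to a two-column data frame
#' @param row.names,optional,... passed through (unused).
#' @export
setMethod("as.data.frame", "ForceDistanceCurve",
  function(x, row.names = NULL, optional = FALSE, ...)
    data.frame(distance_mm = x@distance, force_N = x@force))

setMethod("show", "ForceDistanceCurve", function(object) {
  cat("ForceDistanceCurve with", length(object@distance), "samples\n")
  cat(sprintf("  distance: %.4g .. %.4g mm | force max %.4g N\n",
              min(object@distance), max(object@distance),
              if (length(object@force)) max(object@force) else NA))
  cat(sprintf("  sampleRate %g /s, probeSpeed %g mm/s, trigger %.3f N\n",
              object@sampleRate, object@probeSpeed, object@activationForce))
})

#' @describeIn ForceDistanceCurve-class probe travel, mm
#' @export
curveDistance <- function(x) x@distance

#' @describeIn ForceDistanceCurve-class load-cell force, N
#' @export
curveForce <- function(x) x@force

#' TextureProfile: the ten compression-test texture parameters
#'
#' One seed's texture parameters: number of peaks (Np), breaking force
#' (Bf, N), breaking decline (Bdc, N), elasticity (E, N/mm), breaking
#' energy (Be, mJ), deformation energy (De, mJ), thickness (Th, mm),
#' breaking distance (Bd, mm), strain index (Si = Bd/Th) and area ratio
#' (Ar = Be/De). Si and Ar are stored as fractions in (0, 1], not
#' percentages. Because the compression stops at half the seed height,
#' Bd <= Th/2 and therefore Si <= 0.5.
#'
#' @slot np,bf,bdc,e,be,de,th,bd,si,ar numeric scalars, see description.
#'
#' @param np,bf,bdc,e,be,de,th,bd,si,ar parameter values; `si` and `ar`
#'   default to the identities Bd/Th and Be/De.
#' @return A `TextureProfile` object.
#' @examples
#' TextureProfile(np = 4, bf = 60, bdc = 22, e = 110, be = 16.5,
#'                de = 80, th = 3.2, bd = 0.55)
#' @export
setClass("TextureProfile",
  representation(np = "numeric", bf = "numeric", bdc = "numeric",
                 e = "numeric", be = "numeric", de = "numeric",
                 th = "numeric", bd = "numeric", si = "numeric",
                 ar = "numeric"))

setValidity("TextureProfile", function(object) {
  msg <- NULL
  tol <- 1e-9
  if (object@np < 1 || object@np != round(object@np))
    msg <- c(msg, "np must be a positive integer count")
  if (object@bd > object@th / 2 + tol)
    msg <- c(msg, "bd must not exceed th/2 (test ends at half thickness)")
  if (abs(object@si - object@bd / object@th) > tol)
    msg <- c(msg, "si must equal bd/th")
  if (abs(object@ar - object@be / object@de) > tol)
    msg <- c(msg, "ar must equal be/de")
  if (object@be > object@de + tol * abs(object@de))
    msg <- c(msg, "be must not exceed de")
  if (object@bdc > object@bf + tol)
    msg <- c(msg, "bdc must not exceed bf")
  if (any(c(object@bf, object@e, object@be, object@de,
            object@th, object@bd) <= 0))
    msg <- c(msg, "bf, e, be, de, th, bd must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @rdname TextureProfile-class
#' @export
TextureProfile <- function(np, bf, bdc, e, be, de, th, bd,
                           si = bd / th, ar = be / de) {
  new("TextureProfile", np = as.numeric(np), bf = bf, bdc = bdc, e = e,
      be = be, de = de, th = th, bd = bd, si = si, ar = ar)
}

#' @describeIn TextureProfile-class one-row data frame with the standard
#'   column names Np, Bf, Bdc, E, Be, De, Th, Bd, Si, Ar
#' @param x a `TextureProfile`.
#' @param row.names,optional,... passed through (unused).
#' @export
setMethod("as.data.frame", "TextureProfile",
  function(x, row.names = NULL, optional = FALSE, ...)
    data.frame(Np = x@np, Bf = x@bf, Bdc = x@bdc, E = x@e, Be = x@be,
               De = x@de, Th = x@th, Bd = x@bd, Si = x@si, Ar = x@ar))

setMethod("show", "TextureProfile", function(object) {
  cat("TextureProfile\n")
  v <- unlist(as.data.frame(object))
  cat(paste(sprintf("  %-3s %8.4g", names(v), v), collapse = "\n"), "\n")
})

#' @describeIn TextureProfile-class named numeric vector of the ten
#'   parameters
#' @export
profileValues <- function(x) unlist(as.data.frame(x)[1, ])

#' SensoryScores: long-format sensory panel scores
#'
#' Wraps a long-format table of panel scores with one row per judge x
#' session x sample x attribute observation, validated against the
#' six-attribute vocabulary (color, hardness, cracking, vegetal,
#' bitterness, astringency) and the structured 0-10 rating scale.
#'
#' @slot scores a data.frame with columns `judge`, `session`, `sample`,
#'   `attribute`, `score`.
#'
#' @param scores a data.frame as described above.
#' @return A `SensoryScores` object.
#' @export
setClass("SensoryScores", representation(scores = "data.frame"))

#' Vocabulary of sensory attributes
#'
#' The six attributes scored by the panel, in canonical order.
#' @return character vector of length 6.
#' @export
sensoryAttributes <- function() {
  c("color", "hardness", "cracking", "vegetal", "bitterness", "astringency")
}

setValidity("SensoryScores", function(object) {
  df <- object@scores
  need <- c("judge", "session", "sample", "attribute", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  msg <- NULL
  bad <- setdiff(unique(as.character(df$attribute)), sensoryAttributes())
  if (length(bad))
    msg <- c(msg, paste("unknown attributes:", paste(bad, collapse = ", ")))
  if (!is.numeric(df$score) || any(!is.finite(df$score)))
    msg <- c(msg, "scores must be finite numbers")
  else if (any(df$score < 0 | df$score > 10))
    msg <- c(msg, "scores must lie on the 0-10 scale")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SensoryScores-class
#' @export
SensoryScores <- function(scores) {
  scores$judge <- factor(scores$judge)
  scores$session <- factor(scores$session)
  scores$sample <- factor(scores$sample)
  scores$attribute <- as.character(scores$attribute)
  new("SensoryScores", scores = scores)
}

#' @describeIn SensoryScores-class the underlying long-format data frame
#' @param x a `SensoryScores`.
#' @export
scoreTable <- function(x) {
  if (is(x, "SensoryScores")) x@scores else as.data.frame(x)
}

setMethod("show", "SensoryScores", function(object) {
  df <- object@scores
  cat("SensoryScores:", nrow(df), "observations |",
      nlevels(df$judge), "judges x", nlevels(df$session), "sessions x",
      nlevels(df$sample), "samples,",
      length(unique(df$attribute)), "attributes\n")
})

#' Read a long-format sensory score CSV
#'
#' Expects columns `judge,session,sample,attribute,score`; the attribute
#' vocabulary and the 0-10 scale are validated on construction.
#'
#' @param path path to a CSV file.
#' @return A [SensoryScores] object.
#' @export
readSensoryScores <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  SensoryScores(read.csv(path, stringsAsFactors = FALSE))
}

#' StageSummary: per-stage means and dispersions
#'
#' Per-maturity-stage arithmetic means, standard deviations and counts
#' for a set of instrumental and/or sensory variables. Rows are stages
#' (MS1, MS2, ...), columns are variables.
#'
#' @slot means,sds,n numeric matrices of identical dimension.
#'
#' @param means,sds,n matrices stages x variables.
#' @return A `StageSummary` object.
#' @export
setClass("StageSummary",
  representation(means = "matrix", sds = "matrix", n = "matrix"))

setValidity("StageSummary", function(object) {
  msg <- NULL
  if (!all(dim(object@means) == dim(object@sds)) ||
      !all(dim(object@means) == dim(object@n)))
    msg <- c(msg, "means, sds and n must share dimensions")
  if (any(object@sds < 0, na.rm = TRUE))
    msg <- c(msg, "standard deviations must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' @rdname StageSummary-class
#' @export
StageSummary <- function(means, sds, n) {
  new("StageSummary", means = means, sds = sds, n = n)
}

#' @describeIn StageSummary-class matrix of stage means
#' @param x a `StageSummary`.
#' @export
stageMeans <- function(x) x@means

#' @describeIn StageSummary-class matrix of stage standard deviations
#' @export
stageSDs <- function(x) x@sds

#' @describeIn StageSummary-class matrix of per-cell observation counts
#' @export
stageN <- function(x) x@n

setMethod("show", "StageSummary", function(object) {
  cat("StageSummary:", nrow(object@means), "stages x",
      ncol(object@means), "variables\n")
  print(round(object@means, 3))
})
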