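## sRGB <-> CIELAB under the D65 illuminant and the 2-degree standard
## observer. The forward chain is the standard one: 8-bit sRGB ->
## inverse companding -> linear RGB -> XYZ (sRGB primaries, D65) ->
## CIELAB. Cabinet images are assumed to be rendered in sRGB.

# sRGB -> XYZ matrix (D65 reference white); rows sum to the white point.
.srgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                      0.2126729, 0.7151522, 0.0721750,
                      0.0193339, 0.1191920, 0.9503041),
                    nrow = 3, byrow = TRUE)
.whiteD65 <- rowSums(.srgb2xyz)   # X_n, Y_n, Z_n

.labF <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.labFinv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' Convert 8-bit sRGB colors to CIELAB (D65, 2 degrees)
#'
#' Applies the standard chain sRGB -> linear RGB -> XYZ -> CIELAB with
#' the D65 reference white. The reference white (255, 255, 255) maps to
#' L* = 100, a* = b* = 0.
#'
#' @param rgb a length-3 vector or an n x 3 matrix of channel values in
#'   `[0, 255]` (fractional values are allowed).
#' @return For vector input, a named vector `c(L, a, b)`; for matrix
#'   input an n x 3 matrix with columns `L`, `a`, `b`.
#' @examples
#' srgbToLab(c(255, 255, 255))
#' srgbToLab(c(128, 64, 32))
#' @seealso [labToSrgb()], [chromaHue()]
#' @export
srgbToLab <- function(rgb) {
  vec <- is.null(dim(rgb))
  m <- if (vec) matrix(rgb, nrow = 1) else as.matrix(rgb)
  if (ncol(m) != 3) stop("rgb must have 3 channels")
  if (any(!is.finite(m)) || any(m < 0) || any(m > 255))
    stop("rgb channel values must lie in [0, 255]")
  c01 <- m / 255
  lin <- ifelse(c01 <= 0.04045, c01 / 12.92, ((c01 + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb2xyz)
  f <- .labF(sweep(xyz, 2, .whiteD65, "/"))
  lab <- cbind(L = 116 * f[, 2] - 16,
               a = 500 * (f[, 1] - f[, 2]),
               b = 200 * (f[, 2] - f[, 3]))
  if (vec) lab[1, ] else lab
}

#' Convert CIELAB (D65, 2 degrees) to 8-bit sRGB
#'
#' Inverse of [srgbToLab()]. Out-of-gamut results are clipped to
#' `[0, 255]`; values are returned un-quantized.
#'
#' @param lab a length-3 vector or an n x 3 matrix of (L*, a*, b*).
#' @return sRGB channel values in `[0, 255]`, same shape convention as
#'   [srgbToLab()].
#' @export
labToSrgb <- function(lab) {
  vec <- is.null(dim(lab))
  m <- if (vec) matrix(lab, nrow = 1) else as.matrix(lab)
  if (ncol(m) != 3) stop("lab must have 3 columns")
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(.labFinv(fx), .labFinv(fy), .labFinv(fz))
  xyz <- sweep(xyz, 2, .whiteD65, "*")
  lin <- xyz %*% t(solve(.srgb2xyz))
  c01 <- ifelse(lin <= 0.0031308, 12.92 * lin,
                1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
  out <- pmin(pmax(c01 * 255, 0), 255)
  colnames(out) <- c("R", "G", "B")
  if (vec) out[1, ] else out
}

#' Chroma and hue angle from CIELAB opponent coordinates
#'
#' C*ab = sqrt(a*^2 + b*^2); h_ab = atan2(b*, a*) expressed in degrees
#' and mapped to `[0, 360)`. The hue of the achromatic origin
#' (a* = b* = 0) is reported as 0 by convention.
#'
#' @param a,b numeric vectors of a* and b* values.
#' @return A two-column matrix with columns `C_ab` and `h_ab` (a named
#'   vector for scalar input).
#' @examples
#' chromaHue(3, 4)    # C_ab = 5
#' chromaHue(-5, 0)   # h_ab = 180
#' @export
chromaHue <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  C <- sqrt(a^2 + b^2)
  h <- (atan2(b, a) * 180 / pi) %% 360
  h[C == 0] <- 0
  out <- cbind(C_ab = C, h_ab = h)
  if (length(a) == 1) out[1, ] else out
}
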