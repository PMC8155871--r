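## Least-squares algebraic ellipsoid fit to a 3-D point cloud, used as
## a standalone seed-morphology utility.

#' Fit an ellipsoid to a 3-D point cloud
#'
#' Fits the general quadric `x'Ax + b'x + c = 0` to the points by
#' algebraic least squares (the coefficient vector is the right
#' singular vector of the design matrix with the smallest singular
#' value), then extracts center, semi-axes and orientation from the
#' quadric. At least 9 points in general position are required;
#' coplanar or collinear clouds raise a rank-deficiency error.
#'
#' @param points an n x 3 matrix of coordinates, n >= 9.
#' @return A list of class `"EllipsoidFit"` with elements `center`
#'   (3-vector), `semiAxes` (descending), `orientation` (3 x 3 rotation
#'   with determinant +1, columns matching `semiAxes`), and
#'   `rmsResidual` (RMS first-order geometric distance of the points to
#'   the fitted surface, in coordinate units).
#' @examples
#' th <- seq(0, pi, length.out = 7)[-c(1, 7)]
#' ph <- seq(0, 2 * pi, length.out = 9)[-9]
#' sph <- cbind(c(outer(sin(th), cos(ph))), c(outer(sin(th), sin(ph))),
#'              rep(cos(th), 8))
#' fitEllipsoid(sph)$semiAxes  # ~ (1, 1, 1)
#' @export
fitEllipsoid <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) != 3) stop("points must be an n x 3 matrix")
  if (nrow(p) < 9)
    stop("ellipsoid fit is under-determined: at least 9 points required")
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  D <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z, 1)
  sv <- svd(D, nu = 0)
  if (sv$d[9] < sv$d[1] * 1e-10)
    stop("degenerate point cloud (coplanar or collinear): ",
         "ellipsoid fit is rank-deficient")
  v <- sv$v[, 10]
  A <- matrix(c(v[1], v[4] / 2, v[5] / 2,
                v[4] / 2, v[2], v[6] / 2,
                v[5] / 2, v[6] / 2, v[3]), 3, 3)
  bvec <- v[7:9]
  cc <- v[10]
  center <- tryCatch(-solve(A, bvec) / 2,
                     error = function(e) stop("degenerate quadric: ",
                                              "cannot locate a center"))
  k <- drop(t(center) %*% A %*% center + sum(bvec * center) + cc)
  eig <- eigen(A, symmetric = TRUE)
  ax2 <- -k / eig$values
  if (any(!is.finite(ax2)) || any(ax2 <= 0))
    stop("fitted quadric is not an ellipsoid (degenerate or ",
         "non-elliptic point cloud)")
  semi <- sqrt(ax2)
  ord <- order(semi, decreasing = TRUE)
  semi <- semi[ord]
  R <- eig$vectors[, ord, drop = FALSE]
  if (det(R) < 0) R[, 3] <- -R[, 3]
  # first-order geometric residual: |Q(p)| / ||grad Q(p)||
  q <- rowSums((p %*% A) * p) + p %*% bvec + cc
  g <- 2 * p %*% A + matrix(bvec, nrow(p), 3, byrow = TRUE)
  gn <- sqrt(rowSums(g^2))
  res <- sqrt(mean((q / pmax(gn, .Machine$double.eps))^2))
  structure(list(center = drop(center), semiAxes = semi,
                 orientation = R, rmsResidual = res),
            class = "EllipsoidFit")
}

#' @export
print.EllipsoidFit <- function(x, ...) {
  cat("EllipsoidFit\n  center   :", sprintf("%.4g", x$center), "\n")
  cat("  semi-axes:", sprintf("%.4g", x$semiAxes), "\n")
  cat("  rms residual:", format(x$rmsResidual, digits = 4), "\n")
  invisible(x)
}
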