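#' @useDynLib pocketmc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Geometric primitives shared by the move, energy and analysis code.
# All coordinates are in Angstrom; all angles at the user interface are
# in degrees, mapped to (-180, 180].

#' Wrap an angle in degrees into (-180, 180]
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles.
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

#' Dihedral angle defined by four points
#'
#' Signed dihedral about the p2-p3 axis, in degrees in (-180, 180],
#' using the standard atan2 formulation.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- unit(p3 - p2)
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(pracma_cross(b1, v) * w)
  wrap_angle(atan2(y, x) * 180 / pi)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotate points about an axis (Rodrigues formula)
#'
#' @param coords n x 3 matrix of points.
#' @param origin point on the rotation axis.
#' @param axis direction of the axis (need not be unit length).
#' @param angle rotation angle in degrees (right-handed about `axis`).
#' @return rotated n x 3 matrix.
#' @export
rotate_about_axis <- function(coords, origin, axis, angle) {
  coords <- matrix(coords, ncol = 3)
  if (abs(angle) < 1e-15) return(coords)
  k <- unit(axis)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  p <- sweep(coords, 2, origin)
  kx <- cbind(k[2] * p[, 3] - k[3] * p[, 2],
              k[3] * p[, 1] - k[1] * p[, 3],
              k[1] * p[, 2] - k[2] * p[, 1])
  kdp <- as.vector(p %*% k)
  out <- p * ct + kx * st + outer(kdp * (1 - ct), k)
  sweep(out, 2, origin, `+`)
}

#' Random rotation matrix with bounded angle
#'
#' Uniform random axis, rotation angle drawn uniformly in
#' `[0, max_angle]` degrees. Uses the current RNG stream.
#' @param max_angle maximum rotation angle, degrees.
#' @return 3 x 3 rotation matrix.
#' @keywords internal
random_rotation <- function(max_angle) {
  ax <- stats::rnorm(3)
  while (vnorm(ax) < 1e-8) ax <- stats::rnorm(3)
  ax <- unit(ax)
  ang <- stats::runif(1, 0, max_angle) * pi / 180
  ct <- cos(ang); st <- sin(ang)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + st * K + (1 - ct) * (K %*% K)
}

#' Best-fit plane normal of a point set
#'
#' Unit normal of the least-squares plane through the points (smallest
#' principal axis of the centred coordinates).
#'
#' @param coords n x 3 matrix, n >= 3.
#' @return unit length-3 normal vector.
#' @export
best_fit_plane_normal <- function(coords) {
  coords <- matrix(coords, ncol = 3)
  if (nrow(coords) < 3) stop("need at least 3 points to fit a plane")
  p <- sweep(coords, 2, colMeans(coords))
  sv <- svd(p)
  # collinear points leave the plane orientation undetermined
  if (sv$d[2] < 1e-6 * max(sv$d[1], 1e-12))
    stop("points are collinear; plane normal undefined")
  sv$v[, 3]
}

#' Angle between two planes (by their normals)
#' @param n1,n2 plane normal vectors.
#' @return acute angle between the planes in degrees, in [0, 90].
#' @export
plane_angle <- function(n1, n2) {
  c_ang <- abs(sum(unit(n1) * unit(n2)))
  acos(min(1, max(-1, c_ang))) * 180 / pi
}
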