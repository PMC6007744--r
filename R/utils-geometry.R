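## Small 3-vector helpers used throughout the geometry code. All angles are
## degrees in (-180, 180] unless stated otherwise; coordinates are Angstroms.

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

## wrap into (-180, 180]
wrapAngle <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[x <= -180 | abs(x + 180) < 1e-12] <- 180
  x
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## rotation about z by theta degrees (3x3)
rotZ <- function(theta) {
  th <- deg2rad(theta)
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}

## Kabsch superposition: proper rotation R and translation t minimizing
## ||R x_i + t - y_i||^2. Works for planar point sets (rank-2); the sign of
## the out-of-plane axis is fixed by forcing det(R) = +1, which keeps the
## fitted base normal consistent with the template's atom-order chirality.
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3L, ncol(y) == 3L)
  cx <- colMeans(x)
  cy <- colMeans(y)
  h <- crossprod(sweep(x, 2L, cx), sweep(y, 2L, cy))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = rot, translation = cy - as.vector(rot %*% cx))
}

#' Dihedral angle of four points
#'
#' Signed torsion angle about the p2--p3 bond, IUPAC sign convention: the
#' angle is the \code{atan2} of the binormal triple product over the normal
#' dot product, reported in degrees in \eqn{(-180, 180]}. It is invariant
#' under rigid motion and order reversal, and changes sign under mirror
#' reflection.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstroms, or any common unit).
#' @return Angle in degrees in \eqn{(-180, 180]}.
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)) # 180 (trans)
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))  # -90
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("dihedral undefined: coincident consecutive points")
  c12 <- vcross(b1, b2)
  c23 <- vcross(b2, b3)
  if (vnorm(c12) < 1e-9 || vnorm(c23) < 1e-9)
    stop("dihedral undefined: collinear points")
  x <- sum(c12 * c23)
  y <- sum(vcross(c12, c23) * unitv(b2))
  wrapAngle(rad2deg(atan2(y, x)))
}

## angle p1-p2-p3 in degrees
bondAngle <- function(p1, p2, p3) {
  a <- unitv(p1 - p2)
  b <- unitv(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(a * b)))))
}
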