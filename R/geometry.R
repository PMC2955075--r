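# Small 3D geometry kernel used throughout the package. All angles returned
# in degrees unless noted; coordinates are plain numeric length-3 vectors or
# n x 3 matrices in Angstroms.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two 3D vectors
#'
#' @param a,b numeric length-3 vectors.
#' @return Angle in degrees in \[0, 180\].
#' @keywords internal
angleBetween <- function(a, b) {
  ct <- sum(unitv(a) * unitv(b))
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Wrap an angle into (-180, 180]
#' @param x angle(s) in degrees.
#' @keywords internal
wrapAngle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Periodic absolute difference between two angles in degrees
#'
#' The difference between -179 and +179 degrees is 2, not 358.
#' @param a,b angles in degrees; NA propagates.
#' @return absolute difference in \[0, 180\].
#' @export
angleDiff <- function(a, b) abs(wrapAngle(a - b))

#' Torsion (dihedral) angle of four points
#'
#' Standard IUPAC convention, degrees in (-180, 180].
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return torsion in degrees, or NA if the construction is degenerate.
#' @keywords internal
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- crossp(b1, b2)
  n2 <- crossp(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8) return(NA_real_)
  m1 <- crossp(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrapAngle(atan2(y, x) * 180 / pi)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation; right-handed about \code{axis}.
#' @param axis numeric length-3 direction (need not be unit).
#' @param theta angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotationMatrix <- function(axis, theta) {
  u <- unitv(axis)
  th <- theta * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Apply a rigid transform (rotation R then translation t) to an n x 3 matrix.
applyTransform <- function(xyz, trans) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3)
  sweep(xyz %*% t(trans$R), 2, trans$t, "+")
}

identityTransform <- function() list(R = diag(3), t = c(0, 0, 0))
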