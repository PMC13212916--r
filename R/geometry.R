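# Elementary 3D geometry: dihedrals, rigid superposition, axis rotations.

#' @noRd
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
vnorm <- function(a) sqrt(sum(a * a))

#' @noRd
vunit2 <- function(v) v / sqrt(sum(v * v))

#' @noRd
vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

#' Torsion (dihedral) angle of four points
#'
#' Signed dihedral angle about the p2-p3 bond following the right-hand
#' (IUPAC) convention, reported in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @export
#' @examples
#' dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0))  # 0 (cis)
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (min(vnorm(b1), vnorm(b2), vnorm(b3)) < 1e-9) {
    stop("degenerate dihedral: zero-length bond vector")
  }
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 * vnorm(b1) * vnorm(b2) ||
      vnorm(n2) < 1e-9 * vnorm(b2) * vnorm(b3)) {
    stop("degenerate dihedral: collinear bond vectors")
  }
  m1 <- vcross(n1, vunit(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) / DEG
  if (ang <= -180 + 1e-12) ang <- 180
  ang
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1) and translation `t`
#' minimizing the RMSD between `R %*% movable + t` and `fixed`.
#'
#' @param movable,fixed n x 3 coordinate matrices (equal n >= 3,
#'   non-collinear).
#' @return list with `rotation` (3 x 3), `translation` (length-3),
#'   `rmsd` (fit RMSD in Angstrom) and `transform(mat)`, a closure
#'   applying the transform to any n x 3 matrix.
#' @export
superpose_points <- function(movable, fixed) {
  movable <- as.matrix(movable)
  fixed <- as.matrix(fixed)
  stopifnot(ncol(movable) == 3, ncol(fixed) == 3)
  if (nrow(movable) != nrow(fixed)) {
    stop("point sets must have equal length")
  }
  if (nrow(movable) < 3) stop("need at least 3 points to superpose")
  cm <- colMeans(movable)
  cf <- colMeans(fixed)
  pm <- sweep(movable, 2, cm)
  pf <- sweep(fixed, 2, cf)
  if (svd(pm)$d[2] < 1e-9 || svd(pf)$d[2] < 1e-9) {
    stop("degenerate point set: points are collinear")
  }
  h <- t(pm) %*% pf
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cf - as.vector(rot %*% cm)
  moved <- pm %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - pf)^2)))
  list(
    rotation = rot,
    translation = trans,
    rmsd = rmsd,
    transform = function(mat) {
      mat <- as.matrix(mat)
      sweep(mat %*% t(rot), 2, trans, "+")
    }
  )
}

#' Rotate coordinates about an arbitrary axis
#'
#' Rodrigues rotation of an n x 3 coordinate matrix by `angle` degrees
#' about the axis through `origin` with direction `axis` (right-hand
#' rule).
#'
#' @param coords n x 3 matrix.
#' @param origin point on the axis (3-vector).
#' @param axis axis direction (3-vector, need not be unit).
#' @param angle rotation angle in degrees.
#' @return rotated n x 3 matrix.
#' @export
rotate_about_axis <- function(coords, origin, axis, angle) {
  coords <- as.matrix(coords)
  k <- vunit(axis)
  th <- angle * DEG
  kx <- matrix(c(0, k[3], -k[2],
                 -k[3], 0, k[1],
                 k[2], -k[1], 0), 3, 3)
  rot <- diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
  centered <- sweep(coords, 2, origin)
  sweep(centered %*% t(rot), 2, origin, "+")
}
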