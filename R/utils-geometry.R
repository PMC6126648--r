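# Small 3D geometry helpers shared across modules. All coordinates are in
# angstroms; matrices of points are n x 3 with one atom per row.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at `b` formed by points `a`-`b`-`c`, in degrees
#' @noRd
point_angle <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Torsion angle of the four points, in degrees in (-180, 180]
#' @noRd
point_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Place a fourth point D from reference points A, B, C and the internal
#' coordinates bond = |C-D|, angle = B-C-D (deg), torsion = A-B-C-D (deg).
#' This is the standard natural-extension (NeRF) construction used to grow
#' a polymer from internal coordinates.
#' @noRd
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Orthogonalization matrix for a crystallographic cell
#'
#' Returns the 3x3 matrix M such that cartesian = M %*% fractional, using
#' the standard PDB convention (a along x, b in the xy plane).
#' @param cell numeric(6): a, b, c (angstrom), alpha, beta, gamma (degrees)
#' @noRd
orthogonalization_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    a, b * cos(ga), c * cos(be),
    0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0, c * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

#' Signed chiral volume at a center atom (scalar triple product), in cubic
#' angstroms; positive for an L-amino-acid C-alpha with (N, C, CB) order.
#' @noRd
chiral_volume <- function(center, p1, p2, p3) {
  a <- p1 - center; b <- p2 - center; c <- p3 - center
  sum(vcross(a, b) * c)
}

#' Distances from points to their least-squares plane
#' @param pts n x 3 matrix, n >= 3
#' @return numeric(n) of signed distances
#' @noRd
plane_deviations <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  normal <- sv$v[, 3]
  as.numeric(sweep(pts, 2, ctr) %*% normal)
}

#' Random proper rotation matrix (uniform over SO(3))
#' @noRd
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  quaternion_to_matrix(q)
}

#' Convert a unit quaternion (w, x, y, z) to a 3x3 rotation matrix
#' @noRd
quaternion_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Row-wise euclidean distance between two equally sized n x 3 matrices
#' @noRd
rowwise_dist <- function(a, b) sqrt(rowSums((a - b)^2))

#' RMSD between two coordinate matrices (paired rows)
#' @noRd
coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
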