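#' Quaternion least-squares rigid-body superposition
#'
#' Computes the proper rotation and translation that minimize the
#' (optionally weighted) sum of squared distances between paired points,
#' using Horn's closed-form quaternion method: the optimal rotation is the
#' eigenvector with the largest eigenvalue of the 4x4 key matrix built from
#' the covariance of the centered point sets.
#'
#' @param fixed n x 3 matrix of reference points (angstrom).
#' @param moving n x 3 matrix of points to be moved onto `fixed`; rows pair
#'   with `fixed` rows.
#' @param weights optional non-negative weights, length n.
#' @param rmsd_subset optional logical vector (length n) naming the rows
#'   over which the reported RMSD is computed (e.g. backbone atoms only
#'   when side-chain atoms also joined the fit). Default: all rows.
#' @return An object of class `rigid_transform`: list with `q` (unit
#'   quaternion, w-first), `R` (3x3 proper rotation), `t` (translation),
#'   and `rmsd` (angstrom). Apply with [apply_transform()]:
#'   `y = R x + t`.
#' @examples
#' pts <- matrix(rnorm(30), ncol = 3)
#' tr <- superpose_quaternion(pts, pts)
#' tr$rmsd  # 0
#' @export
superpose_quaternion <- function(fixed, moving, weights = NULL,
                                 rmsd_subset = NULL) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  stopifnot(ncol(fixed) == 3, ncol(moving) == 3,
            nrow(fixed) == nrow(moving))
  n <- nrow(fixed)
  if (n < 3) stop("superposition needs at least 3 point pairs")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)

  cf <- colSums(fixed * w)
  cm <- colSums(moving * w)
  x <- sweep(moving, 2, cm)  # moving, centered
  y <- sweep(fixed, 2, cf)   # fixed, centered

  # degenerate geometry check: points effectively collinear or coincident
  svx <- svd(x * sqrt(w))
  if (svx$d[2] < 1e-8) stop("degenerate geometry: point set is collinear or coincident")

  s <- t(x * w) %*% y  # 3x3 covariance
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  key <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz
  ), nrow = 4, byrow = TRUE)
  eig <- eigen(key, symmetric = TRUE)
  q <- eig$vectors[, 1]
  if (q[1] < 0) q <- -q
  q <- q / vnorm(q)
  rot <- quaternion_to_matrix(q)

  tr <- cf - as.numeric(rot %*% cm)
  moved <- sweep(moving %*% t(rot), 2, tr, "+")
  idx <- if (is.null(rmsd_subset)) rep(TRUE, n) else rmsd_subset
  rmsd <- sqrt(mean(rowSums((moved[idx, , drop = FALSE] -
                               fixed[idx, , drop = FALSE])^2)))
  structure(list(q = q, R = rot, t = tr, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `rigid_transform` from [superpose_quaternion()], or
#'   `NULL` for the identity.
#' @param xyz n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, xyz) {
  xyz <- as.matrix(xyz)
  if (is.null(transform)) return(xyz)
  sweep(xyz %*% t(transform$R), 2, transform$t, "+")
}

#' Identity rigid transform
#' @return a `rigid_transform` with zero rotation and translation.
#' @export
identity_transform <- function() {
  structure(list(q = c(1, 0, 0, 0), R = diag(3), t = c(0, 0, 0), rmsd = 0),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- 2 * acos(min(1, abs(x$q[1]))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.2f deg, |t| = %.2f A, rmsd = %.4f A\n",
              ang, vnorm(x$t), x$rmsd))
  invisible(x)
}
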