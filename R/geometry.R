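# Small geometry helpers shared across modules. All coordinates are in
# Angstrom; rotations are 3x3 orthonormal matrices acting on column vectors.

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` radians about the (normalised) `axis`.
#' @param axis length-3 numeric, need not be unit length.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotation taking unit vector `from` onto unit vector `to`.
rotation_between <- function(from, to) {
  f <- unit(from); t2 <- unit(to)
  c0 <- sum(f * t2)
  if (c0 > 1 - 1e-12) return(diag(3))
  if (c0 < -1 + 1e-12) {
    # pick any perpendicular axis for the half-turn
    p <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(cross3(f, p))
    return(rotation_about_axis(ax, pi))
  }
  rotation_about_axis(cross3(f, t2), acos(c0))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds rotation R and translation t minimising ||R x + t - y|| over
#' paired coordinate sets.
#' @param x,y n x 3 matrices of paired coordinates (x is moved onto y).
#' @return list with `R` (3x3), `t` (length 3) and `rmsd`.
#' @keywords internal
kabsch_fit <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(xc %*% t(R), 2, cy, "+")
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fit - y)^2))))
}

# Apply a rigid transform (list(R, t)) to an n x 3 coordinate matrix.
apply_transform <- function(xyz, tr) {
  sweep(as.matrix(xyz) %*% t(tr$R), 2, tr$t, "+")
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

# Dihedral angle (radians, in (-pi, pi]) over four points given as rows,
# IUPAC sign convention: atan2((n1 x n2).b2_hat, n1.n2).
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  atan2(sum(cross3(n1, n2) * unit(b2)), sum(n1 * n2))
}

# Interior angle at p2 (radians).
bend_angle <- function(p1, p2, p3) {
  a <- unit(p1 - p2); b <- unit(p3 - p2)
  acos(max(-1, min(1, sum(a * b))))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
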