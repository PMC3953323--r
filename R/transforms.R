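# Rigid-body transforms are 4x4 homogeneous matrices (rotation block R,
# translation t, bottom row 0 0 0 1).  Planar poses use length-3 vectors
# (x, y, theta).  All angles are radians internally; user surfaces expose
# degrees.

#' Build a rigid transform from a rotation and a translation
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (Angstrom for molecular chains).
#' @return 4x4 homogeneous transform.
#' @export
tf_new <- function(R = diag(3), t = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  T
}

#' @rdname tf_new
#' @param T 4x4 transform.
#' @export
tf_rot <- function(T) T[1:3, 1:3, drop = FALSE]

#' @rdname tf_new
#' @export
tf_origin <- function(T) T[1:3, 4]

#' Invert a rigid transform
#'
#' Uses rigidity (inverse rotation is the transpose), so the input must have
#' an orthonormal rotation block.
#' @param T 4x4 rigid transform.
#' @export
tf_inverse <- function(T) {
  R <- t(T[1:3, 1:3])
  tf_new(R, -R %*% T[1:3, 4])
}

#' Rotation matrix about an arbitrary unit axis (Rodrigues formula)
#'
#' @param axis unit 3-vector.
#' @param angle rotation angle in radians.
#' @export
rot_axis_angle <- function(axis, angle) {
  c1 <- cos(angle); s1 <- sin(angle)
  K <- so3_hat(axis)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

#' @rdname rot_axis_angle
#' @export
rot_z <- function(angle) {
  c1 <- cos(angle); s1 <- sin(angle)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}

# 4x4 rotation about local z; frequent inner-loop helper.
tf_rot_z <- function(angle) tf_new(rot_z(angle))

#' Skew-symmetric (hat) operator
#' @param v length-3 vector.
#' @export
so3_hat <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Rotation-vector logarithm of a rotation matrix
#'
#' Returns the axis-angle vector r with |r| = rotation angle in \[0, pi\].
#' Zero exactly and only at the identity, which makes it a valid closure
#' residual (unlike cross-product orientation errors, which also vanish at
#' half-turns).  Angles near pi are recovered from the symmetric part.
#' @param R 3x3 rotation matrix.
#' @export
so3_log <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  c_th <- max(-1, min(1, (tr - 1) / 2))
  th <- acos(c_th)
  if (th < 1e-7) {
    # first-order: R ~ I + hat(r)
    return(0.5 * c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]))
  }
  if (th > pi - 1e-4) {
    # near pi the antisymmetric part degenerates; use R + I column of max norm
    B <- R + diag(3)
    j <- which.max(colSums(B^2))
    ax <- B[, j] / sqrt(sum(B[, j]^2))
    # fix sign so it matches the antisymmetric part when it is not exactly 0
    w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (sum(w * ax) < 0) ax <- -ax
    return(th * ax)
  }
  (th / (2 * sin(th))) * c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
}

# Inverse left Jacobian of SO(3) at rotation vector r: maps world angular
# velocity to the time derivative of the rotation vector.  Needed for exact
# Newton steps on frame-closure residuals.
so3_dlog <- function(r) {
  th <- sqrt(sum(r^2))
  K <- so3_hat(r)
  if (th < 1e-6) return(diag(3) - 0.5 * K + (K %*% K) / 12)
  diag(3) - 0.5 * K + ((1 / th^2) - (1 + cos(th)) / (2 * th * sin(th))) * (K %*% K)
}

#' Wrap angles into \[-pi, pi)
#' @param a numeric vector of angles in radians.
#' @export
wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

#' Six-component error between two rigid frames
#'
#' First three components: origin difference (Angstrom); last three: rotation
#' vector of the relative rotation.  Zero iff the frames coincide.
#' @param Tc,Tg current and goal 4x4 transforms.
#' @export
frame_error <- function(Tc, Tg) {
  c(Tc[1:3, 4] - Tg[1:3, 4], so3_log(Tc[1:3, 1:3] %*% t(Tg[1:3, 1:3])))
}

#' Check that a matrix is a proper rotation
#' @param R 3x3 matrix.
#' @param tol tolerance on orthonormality and determinant.
#' @export
is_rigid_rotation <- function(R, tol = 1e-8) {
  max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Dihedral angle defined by four points
#'
#' IUPAC convention: 0 at the cis (eclipsed) conformation, positive for a
#' clockwise rotation of d looking from b towards c. Radians in \[-pi, pi).
#' @param a,b,c,d length-3 coordinate vectors.
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Frame attached to the rotatable bond a->b, with reference atom p defining
# the zero of torsion: origin at b, z along the bond, x towards p's
# projection on the normal plane.  The torsion dihedral (p,a,b,d) equals the
# polar angle of d - b in this right-handed frame, so a torsion joint
# rotates about the frame's +z axis.
bond_frame <- function(p, a, b) {
  z <- b - a; z <- z / sqrt(sum(z^2))
  u <- p - a
  x <- u - sum(u * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("reference atom collinear with bond; torsion frame undefined")
  x <- x / nx
  y <- cross3(z, x)
  tf_new(cbind(x, y, z), b)
}
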