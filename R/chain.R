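# Articulated chains.  A chain couples N revolute joints: frame j is
#   T_j = T_{j-1} %*% rel_j %*% R(axis_j, q_j)
# so each frame's origin lies on its own joint axis.  Planar chains are the
# specialization with all axes +z and in-plane translations; they carry a fast
# (x, y, theta) path that is tested to agree with the generic 3D path.

#' Construct a kinematic chain
#'
#' @param axes 3 x N matrix of unit joint axes, expressed in the local frame
#'   in which the joint rotation is applied.
#' @param rel 4 x 4 x N array of fixed relative transforms (`rel_j` above),
#'   each rigid.
#' @param base fixed base frame `T_0` (4x4).
#' @param end_constraint optional fixed goal frame for `T_N`; when present the
#'   chain is a closed loop and every sampled state must reproduce it.
#' @param planar logical; planar chains additionally store `lengths`.
#' @param lengths link lengths for planar chains.
#' @param meta free-form list (e.g. backbone bookkeeping).
#' @return an object of class `slik_chain`.
#' @export
new_chain <- function(axes, rel, base = diag(4), end_constraint = NULL,
                      planar = FALSE, lengths = NULL, meta = list()) {
  axes <- as.matrix(axes)
  n <- ncol(axes)
  stopifnot(nrow(axes) == 3, dim(rel)[3] == n)
  nrm <- sqrt(colSums(axes^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("joint axes must be unit vectors")
  for (j in seq_len(n)) {
    if (!is_rigid_rotation(rel[1:3, 1:3, j], 1e-6)) {
      stop("relative transform ", j, " is not rigid")
    }
  }
  structure(list(n_joints = n, axes = axes, rel = rel, base = base,
                 end_constraint = end_constraint, planar = planar,
                 lengths = lengths, meta = meta),
            class = "slik_chain")
}

#' @export
print.slik_chain <- function(x, ...) {
  cat(sprintf("<slik_chain> %d joints, %s%s\n", x$n_joints,
              if (x$planar) "planar" else "spatial",
              if (!is.null(x$end_constraint)) ", closed (fixed end frame)" else ""))
  invisible(x)
}

#' Forward kinematics
#'
#' Computes frames `T_0 .. T_N` for the given joint angles by chaining the
#' fixed relative transforms with the joint rotations.
#'
#' @param chain a `slik_chain`.
#' @param angles joint angles in radians, length `chain$n_joints`.
#' @param base base frame; defaults to the chain's.
#' @return 4 x 4 x (N+1) array of frames; slice `j+1` is `T_j`.
#' @export
forward_kinematics <- function(chain, angles, base = chain$base) {
  n <- chain$n_joints
  if (length(angles) != n) {
    stop(sprintf("expected %d angles, got %d", n, length(angles)))
  }
  if (!is_rigid_rotation(base[1:3, 1:3], 1e-6)) stop("base frame is not rigid")
  out <- array(0, dim = c(4, 4, n + 1))
  out[, , 1] <- base
  T <- base
  for (j in seq_len(n)) {
    T <- T %*% chain$rel[, , j] %*%
      tf_new(rot_axis_angle(chain$axes[, j], angles[j]))
    out[, , j + 1] <- T
  }
  out
}

#' Planar chain constructor
#'
#' Links of the given lengths connected by revolute joints about +z.  The pose
#' update is `theta_j = theta_{j-1} + q_j`, origin `p_j = p_{j-1} +
#' L_j (cos theta_{j-1}, sin theta_{j-1})`: with all angles zero the chain runs
#' straight along the base frame's x axis.
#'
#' @param lengths positive link lengths.
#' @param base planar base pose `c(x, y, theta)`.
#' @param end optional planar end-pose constraint `c(x, y, theta)` making the
#'   chain a closed loop.
#' @export
planar_chain <- function(lengths, base = c(0, 0, 0), end = NULL) {
  n <- length(lengths)
  stopifnot(n >= 1, all(lengths > 0))
  rel <- array(0, dim = c(4, 4, n))
  for (j in seq_len(n)) rel[, , j] <- tf_new(diag(3), c(lengths[j], 0, 0))
  new_chain(axes = matrix(rep(c(0, 0, 1), n), 3, n), rel = rel,
            base = planar_to_tf(base),
            end_constraint = if (!is.null(end)) planar_to_tf(end),
            planar = TRUE, lengths = lengths,
            meta = list(base2d = base, end2d = end))
}

#' Planar pose helpers
#'
#' Convert between planar `c(x, y, theta)` poses and 4x4 transforms (plane
#' embedded at z = 0).
#' @param p planar pose.
#' @export
planar_to_tf <- function(p) tf_new(rot_z(p[3]), c(p[1], p[2], 0))

#' @rdname planar_to_tf
#' @param T 4x4 transform with +z rotation axis.
#' @export
tf_to_planar <- function(T) c(T[1, 4], T[2, 4], atan2(T[2, 1], T[1, 1]))

#' Fast planar forward kinematics
#'
#' @param lengths link lengths.
#' @param q joint angles (radians).
#' @param base planar base pose.
#' @return 3 x (N+1) matrix of poses (rows x, y, theta); column j+1 is `T_j`.
#' @export
fk_planar <- function(lengths, q, base = c(0, 0, 0)) {
  n <- length(lengths)
  stopifnot(length(q) == n)
  th <- base[3] + cumsum(c(0, q))        # th[j+1] = orientation of T_j
  # origin update uses the orientation *before* joint j's rotation
  x <- base[1] + cumsum(c(0, lengths * cos(th[1:n])))
  y <- base[2] + cumsum(c(0, lengths * sin(th[1:n])))
  rbind(x, y, theta = th)
}

# Closure residual of a planar chain state: difference between the final pose
# and the end constraint, angle wrapped.
planar_closure_error <- function(poses, end) {
  e <- poses[, ncol(poses)] - end
  e[3] <- wrap_angle(e[3])
  e
}

#' Verify the frame-consistency invariant of a state
#'
#' Recomputes frames from the stored angles and compares with the stored
#' frames; also checks rigidity of every rotation block and, for closed
#' chains, the terminal closure error.
#' @param chain a `slik_chain`.
#' @param state a `slik_state` (see [new_state()]).
#' @param tol tolerance on frame entries.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_state <- function(chain, state, tol = 1e-8) {
  fr <- forward_kinematics(chain, state$angles)
  if (max(abs(fr - state$frames)) > tol) stop("stored frames deviate from forward kinematics")
  for (j in seq_len(dim(fr)[3])) {
    if (!is_rigid_rotation(state$frames[1:3, 1:3, j], 1e-8)) stop("non-rigid frame ", j)
  }
  if (!is.null(chain$end_constraint)) {
    err <- frame_error(state$frames[, , chain$n_joints + 1], chain$end_constraint)
    if (max(abs(err)) > tol) stop("closure violated: max residual ", format(max(abs(err))))
  }
  invisible(TRUE)
}

#' Expanded chain state
#'
#' Bundles the joint angles with all link frames (and, for molecular chains,
#' atom positions) so that factors over spatial variables stay local.
#' @param chain a `slik_chain`.
#' @param angles joint angles (radians).
#' @return object of class `slik_state` with elements `angles`, `frames`
#'   (4 x 4 x (N+1)) and `atoms` (matrix of positions, or NULL).
#' @export
new_state <- function(chain, angles) {
  fr <- forward_kinematics(chain, angles)
  atoms <- if (!is.null(chain$meta$atom_owners)) backbone_to_atoms(chain, fr)
  structure(list(angles = as.numeric(angles), frames = fr, atoms = atoms),
            class = "slik_state")
}
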