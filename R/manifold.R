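# Differential geometry of the sub-loop chart.
#
# Fixing a block's anchors, the closed conformations of the block form a
# manifold of dimension b - 6 (b - 3 planar).  One IK branch together with the
# independent angles y gives a local chart f: y -> x_B whose rows are the
# independent angles (identity), the dependent angles (implicit Jacobian
# dz/dy) and the coordinates of every intervening frame.  The metric tensor
# G = (df/dy)' W (df/dy) converts the prior density over y into the sampling
# density over the manifold:  Q = P(y) / (s sqrt(det G)).

#' Closure-constraint Jacobian of a block
#'
#' Jacobian of the terminal-frame error with respect to all `b` block angles,
#' evaluated at an on-manifold state.  Rows: x, y (, z) position residuals
#' then orientation residual(s); columns: block joints.  Screw-axis form: for
#' a revolute joint at centre `p_j` with world axis `w_j`, the position rows
#' are `w_j x (p_end - p_j)` and the orientation rows are `w_j` (planar: the
#' orientation row is identically 1).
#'
#' @param chain a `slik_chain`.
#' @param frames 4 x 4 x (N+1) frame array of the evaluation state.
#' @param i first angle of the block.
#' @param b block size.
#' @return a `(3 or 6) x b` matrix.
#' @export
constraint_jacobian_full <- function(chain, frames, i, b) {
  n_c <- if (chain$planar) 3L else 6L
  pe <- frames[1:3, 4, i + b]            # origin of the block's terminal frame
  J <- matrix(0, n_c, b)
  for (k in seq_len(b)) {
    j <- i + k - 1
    pj <- frames[1:3, 4, j + 1]
    if (chain$planar) {
      J[1, k] <- -(pe[2] - pj[2])
      J[2, k] <- pe[1] - pj[1]
      J[3, k] <- 1
    } else {
      wj <- frames[1:3, 1:3, j + 1] %*% chain$axes[, j]
      J[1:3, k] <- cross3(wj, pe - pj)
      J[4:6, k] <- wj
    }
  }
  J
}

#' @rdname constraint_jacobian_full
#' @return `constraint_jacobians`: list with blocks `Cy` (independent
#'   columns) and `Cz` (dependent columns).
#' @export
constraint_jacobians <- function(chain, frames, i, b) {
  J <- constraint_jacobian_full(chain, frames, i, b)
  m_dep <- if (chain$planar) 3L else 6L
  m <- b - m_dep
  stopifnot(m >= 0)
  list(Cy = J[, seq_len(m), drop = FALSE],
       Cz = J[, m + seq_len(m_dep), drop = FALSE])
}

#' Implicit chart Jacobian
#'
#' Sensitivity of the dependent angles to the independent ones on the closure
#' manifold, from implicit differentiation of `C(y, z(y)) = 0`:
#' `dz/dy = -(dC/dz)^{-1} dC/dy`.  Near-singular `dC/dz` (reciprocal
#' condition number below `rcond_min`) is reported so the caller can reject
#' the step.
#'
#' @param Cy,Cz constraint Jacobian blocks from [constraint_jacobians()].
#' @param rcond_min singularity guard.
#' @return list with `dzdy` (`NULL` when singular), `rcond` and `singular`.
#' @export
implicit_chart_jacobian <- function(Cy, Cz, rcond_min = 1e-10) {
  rc <- rcond(Cz)
  if (!is.finite(rc) || rc < rcond_min) {
    return(list(dzdy = NULL, rcond = rc, singular = TRUE))
  }
  dzdy <- if (ncol(Cy) == 0) matrix(0, ncol(Cz), 0) else -solve(Cz, Cy)
  list(dzdy = dzdy, rcond = rc, singular = FALSE)
}

#' Chart Jacobian of the block map f: y -> x_B
#'
#' Stacked rows: identity over the independent angles, `dz/dy` over the
#' dependent angles, then per intervening frame its origin-velocity rows and
#' angular-velocity rows (all total derivatives through `dz/dy`).  The
#' accompanying weight vector realises the diagonal weighting `W`: by default
#' angle rows and frame-origin rows weigh 1 and angular rows 0, so that the
#' metric does not mix radians with Angstroms twice over.
#'
#' @inheritParams constraint_jacobian_full
#' @param dzdy implicit chart Jacobian from [implicit_chart_jacobian()].
#' @param w_angle,w_frame_pos,w_frame_rot diagonal weights.
#' @return list with `J` (rows as above) and `w` (weights per row).
#' @export
chart_jacobian <- function(chain, frames, i, b, dzdy,
                           w_angle = 1, w_frame_pos = 1, w_frame_rot = 0) {
  m <- ncol(dzdy)
  m_dep <- nrow(dzdy)
  stopifnot(m + m_dep == b)
  planar <- chain$planar
  n_pos <- if (planar) 2L else 3L
  n_rot <- if (planar) 1L else 3L
  n_frames <- b - 1L                     # frames T_i .. T_{i+b-2}
  J <- matrix(0, m + m_dep + n_frames * (n_pos + n_rot), m)
  w <- c(rep(w_angle, m + m_dep), rep(c(rep(w_frame_pos, n_pos), rep(w_frame_rot, n_rot)), n_frames))
  J[seq_len(m), ] <- diag(m)
  J[m + seq_len(m_dep), ] <- dzdy
  # derivative of frame k's coordinates w.r.t. block joint j (direct part)
  frame_block <- function(k, j) {
    # k, j are global indices: frame T_k, joint q_j; nonzero only for j <= k
    pk <- frames[1:3, 4, k + 1]
    pj <- frames[1:3, 4, j + 1]
    if (planar) {
      pos <- if (j < k) c(-(pk[2] - pj[2]), pk[1] - pj[1]) else c(0, 0)
      c(pos, 1)
    } else {
      wj <- frames[1:3, 1:3, j + 1] %*% chain$axes[, j]
      pos <- if (j < k) cross3(wj, pk - pj) else c(0, 0, 0)
      c(pos, wj)
    }
  }
  for (kk in seq_len(n_frames)) {
    k <- i + kk - 1                      # global frame index
    rows <- m + m_dep + (kk - 1) * (n_pos + n_rot) + seq_len(n_pos + n_rot)
    for (col in seq_len(m)) {
      jy <- i + col - 1                  # independent joint for this column
      v <- if (jy <= k) frame_block(k, jy) else numeric(n_pos + n_rot)
      for (dz_row in seq_len(m_dep)) {
        jz <- i + m + dz_row - 1         # dependent joint
        if (jz <= k && dzdy[dz_row, col] != 0) {
          v <- v + dzdy[dz_row, col] * frame_block(k, jz)
        }
      }
      J[rows, col] <- v
    }
  }
  list(J = J, w = w)
}

#' Metric tensor of a chart
#'
#' `G = J' diag(w) J`, symmetric positive semidefinite.
#' @param J chart Jacobian (rows: coordinates, columns: chart parameters).
#' @param w non-negative row weights (recycled).
#' @export
metric_tensor <- function(J, w = 1) {
  crossprod(J * sqrt(rep_len(w, nrow(J))))
}

# log det of a small SPD matrix via Cholesky; NULL signals (numerical)
# singularity.
log_det_psd <- function(G) {
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  2 * sum(log(diag(ch)))
}

#' Sampling density of the block proposal
#'
#' The density, with respect to the (weighted) volume measure of the closure
#' manifold, of the point produced by sampling independent angles from a
#' density `P(y)` and picking one of `s` IK branches uniformly:
#' `Q = P(y) / (s * sqrt(det G(y)))`.
#'
#' @param p_y prior density value at the independent angles (may be
#'   unnormalized as long as forward and reverse use the same family).
#' @param s number of IK solutions at `y` (>= 1).
#' @param G metric tensor of the chart at `y`.
#' @param det_tol reject charts with `det G` at or below this value.
#' @export
proposal_density <- function(p_y, s, G, det_tol = 1e-300) {
  stopifnot(s >= 1, p_y >= 0)
  ld <- log_det_psd(as.matrix(G))
  if (is.null(ld) || !is.finite(ld) || exp(ld) <= det_tol) {
    stop("singular chart: det G not positive")
  }
  p_y / (s * exp(ld / 2))
}

#' Push a density through a differentiable injective map
#'
#' For `v = f(u)` with full-column-rank Jacobian, the density of `v` with
#' respect to the m-dimensional volume measure on the image is
#' `g_v(v) = g_u(u) / sqrt(det G(u))` with `G = (df/du)'(df/du)`.
#'
#' @param g_u density function of `u`.
#' @param f the map, vector to vector.
#' @param u evaluation point.
#' @param eps finite-difference step for the Jacobian.
#' @return density value at `f(u)`.
#' @export
density_pushforward <- function(g_u, f, u, eps = 1e-6) {
  J <- fd_jacobian(f, u, eps)
  vol <- parallelotope_volume(J)
  if (vol < 1e-12) stop("rank-deficient Jacobian: pushforward density undefined")
  g_u(u) / vol
}

#' Volume of the parallelotope spanned by m vectors in R^n
#'
#' `sqrt(det(A'A))` with the vectors as columns of `A`; 0 when rank-deficient.
#' Equals the Gram-determinant volume element of a chart.
#' @param vectors matrix with the spanning vectors as columns.
#' @export
parallelotope_volume <- function(vectors) {
  A <- as.matrix(vectors)
  if (ncol(A) == 0) return(1)
  sqrt(max(0, det(crossprod(A))))
}

#' Dimension of the closure solution manifold at a state
#'
#' Angle-space dimension of the block minus the numerical rank of the
#' closure-constraint Jacobian (singular values above `sv_tol` times the
#' largest).
#'
#' @inheritParams constraint_jacobian_full
#' @param sv_tol relative singular-value cutoff.
#' @param i,b block position and size; default: the whole chain.
#' @return integer dimension, with attribute `"singular_values"`.
#' @export
manifold_dimension <- function(chain, frames, i = 1L, b = chain$n_joints,
                               sv_tol = 1e-8) {
  J <- constraint_jacobian_full(chain, frames, i, b)
  sv <- svd(J, nu = 0, nv = 0)$d
  rank <- sum(sv > sv_tol * max(sv, 1e-300))
  structure(as.integer(b - rank), singular_values = sv)
}

# Central-difference Jacobian, used by pushforward and as an independent
# check in tests.
fd_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    e <- numeric(length(x)); e[j] <- eps
    J[, j] <- (f(x + e) - f(x - e)) / (2 * eps)
  }
  J
}
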