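# Exact inverse-kinematics closure of dependent subchains.
#
# A block of b consecutive angles is split into b-6 independent angles (b-3 in
# the plane) that are sampled freely, and a dependent subchain of exactly 6
# (resp. 3) angles that is solved so the terminal frame of the block matches
# its fixed anchor.  The planar solver is closed-form (elbow-up/elbow-down);
# the spatial solver enumerates the discrete root set of the 6-angle problem
# by damped Gauss-Newton continuation from batches of random seeds, with
# deduplication, and is self-consistent: when the goal frame was produced by
# forward kinematics the generating configuration is recovered.

#' Planar three-angle closure
#'
#' Solves for the three revolute angles `z1, z2, z3` of a planar subchain
#' `Trans(L1) Rz(z1) Trans(L2) Rz(z2) Trans(L3) Rz(z3)` that carries
#' `anchor_start` onto `anchor_end`.  Generic reachable goals have exactly two
#' solutions; goals at the reach boundary have one (stretched, singular);
#' unreachable goals yield an empty set rather than an error.
#'
#' @param anchor_start,anchor_end planar poses `c(x, y, theta)` or 4x4
#'   transforms with +z axis.
#' @param link_lengths the three link lengths.
#' @param tol reach tolerance.
#' @return list with `solutions` (k x 3 matrix of angles, radians) and
#'   `count`.
#' @export
solve_planar <- function(anchor_start, anchor_end, link_lengths, tol = 1e-9) {
  if (is.matrix(anchor_start)) anchor_start <- tf_to_planar(anchor_start)
  if (is.matrix(anchor_end)) anchor_end <- tf_to_planar(anchor_end)
  stopifnot(length(link_lengths) == 3, all(link_lengths > 0))
  L1 <- link_lengths[1]; L2 <- link_lengths[2]; L3 <- link_lengths[3]
  # goal pose in the start frame
  dth <- anchor_start[3]
  d <- anchor_end[1:2] - anchor_start[1:2]
  p <- c(cos(dth) * d[1] + sin(dth) * d[2], -sin(dth) * d[1] + cos(dth) * d[2])
  th_loc <- wrap_angle(anchor_end[3] - anchor_start[3])
  # subtract the first (fixed-direction) link; classic two-link problem remains
  w <- p - c(L1, 0)
  r2 <- sum(w^2)
  c2 <- (r2 - L2^2 - L3^2) / (2 * L2 * L3)
  if (c2 > 1 + tol || c2 < -1 - tol) {
    return(list(solutions = matrix(0, 0, 3), count = 0L))
  }
  c2 <- max(-1, min(1, c2))
  z2s <- if (abs(c2) >= 1 - 1e-14) acos(c2) else c(acos(c2), -acos(c2))
  sols <- matrix(0, length(z2s), 3)
  for (k in seq_along(z2s)) {
    z2 <- z2s[k]
    z1 <- atan2(w[2], w[1]) - atan2(L3 * sin(z2), L2 + L3 * cos(z2))
    z3 <- th_loc - z1 - z2
    sols[k, ] <- wrap_angle(c(z1, z2, z3))
  }
  list(solutions = sols, count = nrow(sols))
}

# Forward kinematics of a bare 6-joint subchain description.
fk_subchain <- function(rel, axes, T_start, z) {
  n <- dim(rel)[3]
  fr <- array(0, dim = c(4, 4, n + 1))
  fr[, , 1] <- T_start
  T <- T_start
  for (j in seq_len(n)) {
    T <- T %*% rel[, , j] %*% tf_new(rot_axis_angle(axes[, j], z[j]))
    fr[, , j + 1] <- T
  }
  fr
}

# Closure residual and its exact Jacobian for a 6-joint subchain.  Hot path
# of the spatial solver: works on bare 3x3 rotations and origins.
subchain_residual <- function(rel, axes, T_start, T_goal, z, with_jac = TRUE) {
  n <- dim(rel)[3]
  R <- T_start[1:3, 1:3]; p <- T_start[1:3, 4]
  Rj <- vector("list", n); pj <- matrix(0, 3, n)
  for (j in seq_len(n)) {
    Rr <- rel[1:3, 1:3, j]; tr <- rel[1:3, 4, j]
    p <- p + R %*% tr
    R <- (R %*% Rr) %*% rot_axis_angle(axes[, j], z[j])
    Rj[[j]] <- R; pj[, j] <- p
  }
  r <- so3_log(R %*% t(T_goal[1:3, 1:3]))
  C <- c(p - T_goal[1:3, 4], r)
  if (!with_jac) return(list(C = C))
  D <- so3_dlog(r)
  J <- matrix(0, 6, n)
  for (j in seq_len(n)) {
    wj <- Rj[[j]] %*% axes[, j]
    J[1:3, j] <- cross3(wj, p - pj[, j])
    J[4:6, j] <- D %*% wj
  }
  list(C = C, J = J)
}

# One damped Gauss-Newton descent on ||C||^2 from seed z0.  Returns the root
# (wrapped) or NULL.  Seeds that stall far from a root are abandoned early;
# the enumeration compensates with more seeds.
newton_descend <- function(rel, axes, T_start, T_goal, z0,
                           tol = 1e-10, max_iter = 40) {
  z <- z0
  res <- subchain_residual(rel, axes, T_start, T_goal, z)
  nc <- sqrt(sum(res$C^2))
  lambda <- 0
  stalls <- 0L
  nc_ref <- nc
  for (it in seq_len(max_iter)) {
    if (nc < tol) return(wrap_angle(z))
    if (it %% 8 == 0) {                  # stall detection every few iterations
      if (nc > 1e-2 && nc > nc_ref / 2) return(NULL)
      nc_ref <- nc
    }
    step <- tryCatch({
      A <- crossprod(res$J) + lambda * diag(6)
      -solve(A, crossprod(res$J, res$C))
    }, error = function(e) NULL)
    if (is.null(step)) { lambda <- max(lambda * 10, 1e-6); next }
    t_ls <- 1
    improved <- FALSE
    for (ls in 1:5) {
      z_new <- z + t_ls * as.numeric(step)
      res_new <- subchain_residual(rel, axes, T_start, T_goal, z_new)
      nc_new <- sqrt(sum(res_new$C^2))
      if (is.finite(nc_new) && nc_new < nc * (1 - 1e-4 * t_ls)) {
        z <- z_new; res <- res_new; nc <- nc_new
        lambda <- lambda / 4
        improved <- TRUE
        break
      }
      t_ls <- t_ls / 2
    }
    if (!improved) {
      stalls <- stalls + 1L
      if (stalls > 6L) return(NULL)
      lambda <- if (lambda == 0) 1e-6 else lambda * 10
      if (lambda > 1e6) return(NULL)
    }
  }
  if (nc < tol) wrap_angle(z) else NULL
}

#' Spatial six-angle closure
#'
#' Enumerates the discrete solution set of the six-angle inverse-kinematics
#' problem: angles `z` of a 6-joint subchain (fixed intervening geometry)
#' carrying `start_frame` onto `goal_frame`.  Roots are found by damped
#' Gauss-Newton continuation from batches of random seeds and deduplicated at
#' `dedup_tol` (wrapped max-norm); the search stops once `settle` consecutive
#' batches add no new root, or at `max_seeds` seeds.  At most 16 solutions
#' exist for generic geometry; numerical failure on a seed is silently skipped
#' so the result is always a (possibly empty) set of exact roots, never a
#' partial closure.
#'
#' @param subchain either a `slik_chain` with 6 joints or a list with
#'   elements `rel` (4x4x6) and `axes` (3x6).
#' @param start_frame,goal_frame fixed end frames (4x4).
#' @param hints optional matrix of seed configurations (rows), tried first;
#'   the sampler passes the current dependent angles here.
#' @param dedup_tol solution deduplication tolerance, radians.
#' @param tol closure residual tolerance.
#' @param batch,settle,max_seeds search-effort controls.
#' @return list with `solutions` (k x 6 matrix) and `count`.
#' @seealso [solve_planar()] for the planar three-angle case.
#' @export
solve_spatial_6 <- function(subchain, start_frame, goal_frame, hints = NULL,
                            dedup_tol = 1e-4, tol = 1e-10,
                            batch = 24L, settle = 3L, max_seeds = 360L) {
  if (inherits(subchain, "slik_chain")) {
    stopifnot(subchain$n_joints == 6)
    rel <- subchain$rel; axes <- subchain$axes
  } else {
    rel <- subchain$rel; axes <- subchain$axes
  }
  # cheap reach bound: origin displacement cannot exceed the sum of the
  # relative-translation norms
  reach <- sum(sqrt(colSums(matrix(rel[1:3, 4, ], 3)^2)))
  gap <- sqrt(sum((goal_frame[1:3, 4] - (start_frame %*% rel[, , 1])[1:3, 4])^2))
  if (gap > reach + 1e-6) return(list(solutions = matrix(0, 0, 6), count = 0L))

  roots <- list()
  add_root <- function(z) {
    for (r in roots) if (max(abs(wrap_angle(z - r))) < dedup_tol) return(FALSE)
    roots[[length(roots) + 1]] <<- z
    TRUE
  }
  seeds_used <- 0L
  quiet <- 0L
  if (!is.null(hints)) {
    hints <- if (is.matrix(hints)) hints else matrix(hints, nrow = 1)
    for (k in seq_len(nrow(hints))) {
      z <- newton_descend(rel, axes, start_frame, goal_frame, hints[k, ], tol = tol)
      if (!is.null(z)) add_root(z)
      seeds_used <- seeds_used + 1L
    }
  }
  while (seeds_used < max_seeds && quiet < settle) {
    found_new <- FALSE
    for (k in seq_len(batch)) {
      z0 <- stats::runif(6, -pi, pi)
      z <- newton_descend(rel, axes, start_frame, goal_frame, z0, tol = tol)
      if (!is.null(z) && add_root(z)) found_new <- TRUE
      seeds_used <- seeds_used + 1L
    }
    quiet <- if (found_new) 0L else quiet + 1L
  }
  k <- length(roots)
  sols <- if (k) do.call(rbind, roots) else matrix(0, 0, 6)
  list(solutions = sols, count = k)
}

# Extract the description of joints j1..j2 of a chain as a bare subchain.
chain_slice <- function(chain, j1, j2) {
  idx <- j1:j2
  list(rel = chain$rel[, , idx, drop = FALSE],
       axes = chain$axes[, idx, drop = FALSE])
}

#' Sample a closed candidate conformation for one block
#'
#' Implements the block proposal: draw the independent angles `y` from the
#' prior, then close the chain by solving for the dependent angles `z`.  If
#' several closure solutions exist one branch is picked uniformly at random
#' (`pick = "random"`); failure to close is a normal outcome that the caller
#' counts as a rejected move.
#'
#' Blocks need `b >= 7` spatial angles (`b >= 4` planar) to mix: `b = 6` (3)
#' restricts the walk to a finite set and is refused unless `allow_small` is
#' set, and for `b <= 5` the closure solution set is generically just the
#' current conformation, so the state can never change.
#'
#' @param chain a `slik_chain`.
#' @param state current `slik_state` (supplies the fixed anchors).
#' @param i index of the block's first angle.
#' @param b number of angles in the block.
#' @param prior proposal prior for the independent angles; a list with
#'   `sample(idx)` and `logdens(values, idx)` (see [uniform_angle_prior()]).
#' @param pick `"random"` (uniform over branches) or `"nearest"` (branch
#'   closest to the current dependent angles).
#' @param allow_small permit non-mixing blocks (`b` below 7 spatial / 4
#'   planar), used only for diagnostics of the non-mixing regime.
#' @param ik control list for [solve_spatial_6()] effort.
#' @return list with `status` (`"ok"` or `"ik_failure"`), `angles` (full
#'   block assignment), `y`, `z`, `s` (solution count at the sampled point)
#'   and `branch`.
#' @export
sample_block <- function(chain, state, i, b, prior = uniform_angle_prior(),
                         pick = c("random", "nearest"), allow_small = FALSE,
                         ik = list()) {
  pick <- match.arg(pick)
  m_dep <- if (chain$planar) 3L else 6L
  if (b < m_dep + 1 && !allow_small) {
    stop("block of ", b, " angles cannot mix (needs at least ", m_dep + 1,
         "); set allow_small = TRUE to study the non-mixing regime")
  }
  n <- chain$n_joints
  stopifnot(i >= 1, i + b - 1 <= n)
  anchor_start <- state$frames[, , i]
  anchor_end <- if (i + b - 1 == n && !is.null(chain$end_constraint)) {
    chain$end_constraint
  } else {
    state$frames[, , i + b]
  }
  m <- max(0L, b - m_dep)
  cur <- state$angles[i:(i + b - 1)]
  if (b <= m_dep) {
    # over- or exactly-determined closure: solve for all b angles at once;
    # generically (b < m_dep + 1) the only root is the current conformation.
    sol <- solve_small_block(chain, i, b, anchor_start, anchor_end, cur, ik)
    if (sol$count == 0) return(list(status = "ik_failure"))
    k <- if (pick == "random") sample.int(sol$count, 1) else
      which.min(apply(sol$solutions, 1, function(z) max(abs(wrap_angle(z - cur)))))
    z <- sol$solutions[k, ]
    # snap to the current conformation when the root is the current one
    if (max(abs(wrap_angle(z - cur))) < 1e-6) z <- cur
    return(list(status = "ok", angles = z, y = numeric(0), z = z,
                s = sol$count, branch = k))
  }
  yidx <- i:(i + m - 1)
  y <- prior$sample(yidx, cur[seq_len(m)])
  dep1 <- i + m          # first dependent joint (global index)
  # frame after the last independent joint
  T_in <- anchor_start
  for (j in seq_len(m)) {
    jj <- i + j - 1
    T_in <- T_in %*% chain$rel[, , jj] %*% tf_new(rot_axis_angle(chain$axes[, jj], y[j]))
  }
  if (chain$planar) {
    sol <- solve_planar(tf_to_planar(T_in), tf_to_planar(anchor_end),
                        chain$lengths[dep1:(i + b - 1)])
  } else {
    sub <- chain_slice(chain, dep1, i + b - 1)
    args <- c(list(sub, T_in, anchor_end, hints = rbind(cur[(m + 1):b])), ik)
    sol <- do.call(solve_spatial_6, args)
  }
  if (sol$count == 0) return(list(status = "ik_failure", y = y))
  k <- if (pick == "random") sample.int(sol$count, 1) else
    which.min(apply(sol$solutions, 1, function(z) max(abs(wrap_angle(z - cur[(m + 1):b])))))
  z <- sol$solutions[k, ]
  list(status = "ok", angles = c(y, z), y = y, z = z, s = sol$count, branch = k)
}

# Root enumeration for blocks with b <= 6 (spatial) or b <= 3 (planar):
# solve the full closure system over all b block angles by multi-start
# Gauss-Newton in the b unknowns (the system is square or overdetermined).
solve_small_block <- function(chain, i, b, T_start, T_goal, cur, ik = list()) {
  idx <- i:(i + b - 1)
  rel <- chain$rel[, , idx, drop = FALSE]
  axes <- chain$axes[, idx, drop = FALSE]
  resfun <- function(z) {
    fr <- fk_subchain(rel, axes, T_start, z)
    Te <- fr[, , b + 1]
    if (chain$planar) {
      c(Te[1:2, 4] - T_goal[1:2, 4],
        wrap_angle(atan2(Te[2, 1], Te[1, 1]) - atan2(T_goal[2, 1], T_goal[1, 1])))
    } else {
      frame_error(Te, T_goal)
    }
  }
  roots <- list()
  add_root <- function(z) {
    for (r in roots) if (max(abs(wrap_angle(z - r))) < 1e-4) return(FALSE)
    roots[[length(roots) + 1]] <<- z
    TRUE
  }
  n_seeds <- ik$small_seeds %||% 8L
  seeds <- rbind(cur, matrix(stats::runif((n_seeds - 1) * b, -pi, pi), n_seeds - 1, b))
  for (k in seq_len(nrow(seeds))) {
    z <- gauss_newton_generic(resfun, seeds[k, ], tol = 1e-10)
    if (!is.null(z)) add_root(wrap_angle(z))
  }
  k <- length(roots)
  list(solutions = if (k) do.call(rbind, roots) else matrix(0, 0, b), count = k)
}

# Gauss-Newton with finite-difference Jacobian for small generic systems.
gauss_newton_generic <- function(resfun, z0, tol = 1e-10, max_iter = 60) {
  z <- z0
  C <- resfun(z)
  nc <- sqrt(sum(C^2))
  lambda <- 0
  for (it in seq_len(max_iter)) {
    if (nc < tol) return(z)
    J <- fd_jacobian(resfun, z)
    step <- tryCatch(-solve(crossprod(J) + lambda * diag(length(z)), crossprod(J, C)),
                     error = function(e) NULL)
    if (is.null(step)) { lambda <- max(lambda * 10, 1e-6); next }
    improved <- FALSE
    t_ls <- 1
    for (ls in 1:8) {
      z_new <- z + t_ls * as.numeric(step)
      C_new <- resfun(z_new)
      nc_new <- sqrt(sum(C_new^2))
      if (is.finite(nc_new) && nc_new < nc * (1 - 1e-4 * t_ls)) {
        z <- z_new; C <- C_new; nc <- nc_new; lambda <- lambda / 4
        improved <- TRUE
        break
      }
      t_ls <- t_ls / 2
    }
    if (!improved) {
      lambda <- if (lambda == 0) 1e-6 else lambda * 10
      if (lambda > 1e6) return(NULL)
    }
  }
  if (nc < tol) z else NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a
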