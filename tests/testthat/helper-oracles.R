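# Shared generators and independent oracles used across the test files.

# random proper rotation
rand_rotation <- function() {
  A <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(A) < 0) A[, 1] <- -A[, 1]
  A
}

# random rigid 4x4 transform
rand_tf <- function(scale = 1) tf_new(rand_rotation(), rnorm(3, sd = scale))

# random spatial chain with n revolute joints
rand_chain <- function(n, closed = FALSE, q_close = NULL) {
  axes <- matrix(rnorm(3 * n), 3)
  axes <- sweep(axes, 2, sqrt(colSums(axes^2)), "/")
  rel <- array(0, dim = c(4, 4, n))
  for (j in seq_len(n)) rel[, , j] <- rand_tf()
  end <- NULL
  if (closed) {
    ch0 <- new_chain(axes, rel)
    qc <- if (is.null(q_close)) runif(n, -pi, pi) else q_close
    end <- forward_kinematics(ch0, qc)[, , n + 1]
    attr(end, "q_close") <- qc
  }
  new_chain(axes, rel, end_constraint = end)
}

# brute-force forward kinematics: plain 4x4 homogeneous products
fk_oracle <- function(chain, q, base = chain$base) {
  T <- base
  out <- array(0, dim = c(4, 4, chain$n_joints + 1))
  out[, , 1] <- T
  for (j in seq_len(chain$n_joints)) {
    a <- chain$axes[, j]
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    R <- diag(3) + sin(q[j]) * K + (1 - cos(q[j])) * K %*% K
    Rt <- diag(4); Rt[1:3, 1:3] <- R
    T <- T %*% chain$rel[, , j] %*% Rt
    out[, , j + 1] <- T
  }
  out
}

# dense grid search + local refinement for planar 3-angle closure
planar_ik_oracle <- function(T_in, T_goal, L, n_grid = 90) {
  resid <- function(z) {
    p <- fk_planar(L, z, T_in)
    e <- p[, 4] - T_goal
    e[3] <- wrap_angle(e[3])
    e
  }
  # 2-D scan over (z1, z2); z3 is fixed by the orientation constraint
  th_loc <- wrap_angle(T_goal[3] - T_in[3])
  z1s <- seq(-pi, pi, length.out = n_grid + 1)[-1]
  best <- list()
  for (z1 in z1s) {
    for (z2 in z1s) {
      z3 <- th_loc - z1 - z2
      e <- resid(c(z1, z2, z3))
      if (sum(e[1:2]^2) < 0.05) best[[length(best) + 1]] <- c(z1, z2, z3)
    }
  }
  # refine candidates with Newton and deduplicate
  out <- list()
  for (z0 in best) {
    z <- z0
    for (it in 1:60) {
      e <- resid(z)
      if (sqrt(sum(e^2)) < 1e-12) break
      J <- matrix(0, 3, 3)
      for (j in 1:3) {
        ee <- numeric(3); ee[j] <- 1e-7
        J[, j] <- (resid(z + ee) - resid(z - ee)) / 2e-7
      }
      z <- z - tryCatch(solve(J, e), error = function(c) e * 0)
    }
    if (sqrt(sum(resid(z)^2)) < 1e-10) {
      z <- wrap_angle(z)
      dup <- FALSE
      for (r in out) if (max(abs(wrap_angle(z - r))) < 1e-6) dup <- TRUE
      if (!dup) out[[length(out) + 1]] <- z
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(0, 0, 3)
}

# central-difference Jacobian
fd_jac <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    e <- numeric(length(x)); e[j] <- eps
    J[, j] <- (f(x + e) - f(x - e)) / (2 * eps)
  }
  J
}

# angle-series embedding for distribution comparisons
embed_angles <- function(Q) cbind(cos(Q), sin(Q))

# pick, per anchor of a planar tree, the IK branch nearest a reference
# dependent-angle assignment (continuation used by finite-difference charts)
nearest_picks <- function(tree, q, z_ref) {
  picks <- integer(length(tree$anchors))
  names(z_ref) <- tree$z_idx
  qq <- q
  for (ai in seq_along(tree$anchors)) {
    leaf <- as.integer(names(tree$anchors)[ai])
    z3 <- tree$dep[[as.character(leaf)]]
    fk <- tree_fk(tree, qq)
    e1 <- z3[1]; p <- tree$parent[e1]
    T_in <- if (p == 0) tree$base else c(fk$node[, p], fk$theta_out[p])
    sol <- solve_planar(T_in, tree$anchors[[as.character(leaf)]], tree$lengths[z3])
    d <- apply(sol$solutions, 1, function(z)
      max(abs(wrap_angle(z - z_ref[as.character(z3)]))))
    picks[ai] <- which.min(d)
    qq[z3] <- sol$solutions[picks[ai], ]
  }
  picks
}

# CDF of a wrapped Gaussian mixture on [-pi, pi); angles in radians, mixture
# parameters in degrees.  Wrap-safe reference for chi-angle KS tests.
wrapped_mixture_cdf <- function(x, w, means_deg, sds_deg) {
  xd <- x * 180 / pi
  total <- 0
  for (k in seq_along(w)) {
    for (j in -2:2) {
      total <- total + w[k] * (pnorm(xd + 360 * j, means_deg[k], sds_deg[k]) -
                               pnorm(-180 + 360 * j, means_deg[k], sds_deg[k]))
    }
  }
  total
}
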