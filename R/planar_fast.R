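# Specialized planar runner.
#
# Planar runs (mixing studies, stationarity checks) take 1e5..1e6 block
# moves, so the generic block machinery is re-implemented here on flat
# (x, y, theta) pose arrays with closed-form 2x2/1x1 determinants.  The
# random stream and the arithmetic follow sample_block_mh exactly; a test
# asserts that both paths produce identical trajectories from the same seed.

# Compile a factor graph into flat per-variable parameter tables.  Returns
# NULL when a factor type (or duplicated domain) is not representable, in
# which case the generic path is used.
planar_compile <- function(chain, fg, cfg) {
  n <- chain$n_joints
  ang_mean <- ang_par <- rep(NA_real_, n)
  ang_type <- integer(n)                 # 0 none, 1 gauss, 2 von Mises
  pos_mu <- matrix(NA_real_, 2, n + 1)
  pos_sd <- rep(NA_real_, n + 1)
  for (f in fg$factors) {
    if (f$type == "angle_gauss") {
      j <- f$params$idx
      if (ang_type[j] != 0) return(NULL)
      ang_type[j] <- 1L; ang_mean[j] <- f$params$mean; ang_par[j] <- f$params$sd
    } else if (f$type == "angle_vm") {
      j <- f$params$idx
      if (ang_type[j] != 0) return(NULL)
      ang_type[j] <- 2L; ang_mean[j] <- f$params$mean; ang_par[j] <- f$params$kappa
    } else if (f$type == "pos_gauss") {
      j <- f$params$frame_idx
      if (!is.na(pos_sd[j + 1])) return(NULL)
      if (length(f$params$centre) < 2) return(NULL)
      pos_mu[, j + 1] <- f$params$centre[1:2]; pos_sd[j + 1] <- f$params$sd
    } else {
      return(NULL)
    }
  }
  list(ang_type = ang_type, ang_mean = ang_mean, ang_par = ang_par,
       pos_mu = pos_mu, pos_sd = pos_sd,
       any_angle = any(ang_type > 0), any_pos = any(!is.na(pos_sd)))
}

# log score contribution of angles idx and frames fr (0-based) given flat tables
planar_block_logscore <- function(fast, q, poses, idx, fr) {
  v <- 0
  if (fast$any_angle) {
    for (j in idx) {
      t <- fast$ang_type[j]
      if (t == 1L) {
        v <- v - wrap_angle(q[j] - fast$ang_mean[j])^2 / (2 * fast$ang_par[j]^2)
      } else if (t == 2L) {
        v <- v + fast$ang_par[j] * cos(q[j] - fast$ang_mean[j])
      }
    }
  }
  if (fast$any_pos) {
    for (j in fr) {
      sd <- fast$pos_sd[j + 1]
      if (!is.na(sd)) {
        dx <- poses[1, j + 1] - fast$pos_mu[1, j + 1]
        dy <- poses[2, j + 1] - fast$pos_mu[2, j + 1]
        v <- v - (dx * dx + dy * dy) / (2 * sd * sd)
      }
    }
  }
  v
}

# chart metric log-determinant for a planar block from the local pose matrix
# P (3 x (b+1): T_{i-1} .. T_{i+b-1}).  Returns NULL at singular charts.
planar_logdetG <- function(P, m, cfg) {
  b <- ncol(P) - 1L
  pe <- P[1:2, b + 1L]
  # closure Jacobian columns (block joints 1..b, centre = origin of T_{i+k-1})
  Cx <- -(pe[2] - P[2, 2:(b + 1)])
  Cy <- pe[1] - P[1, 2:(b + 1)]
  Cz <- rbind(Cx[(m + 1):b], Cy[(m + 1):b], 1)
  rc <- rcond(Cz)
  if (!is.finite(rc) || rc < cfg$rcond_min) return(NULL)
  Cym <- rbind(Cx[seq_len(m)], Cy[seq_len(m)], 1)
  dzdy <- -solve(Cz, Cym)
  G <- cfg$w_angle * (diag(m) + crossprod(dzdy))
  if (cfg$w_frame_pos != 0 || cfg$w_frame_rot != 0) {
    for (k in seq_len(b - 1L)) {         # frames T_i .. T_{i+b-2}
      pk <- P[1:2, k + 1L]
      v <- matrix(0, 2, m)
      for (col in seq_len(m)) {
        if (col < k) {
          cj <- P[1:2, col + 1L]
          v[, col] <- c(-(pk[2] - cj[2]), pk[1] - cj[1])
        }
        for (nn in 1:3) {
          jz <- m + nn
          if (jz < k && dzdy[nn, col] != 0) {
            cj <- P[1:2, jz + 1L]
            v[, col] <- v[, col] + dzdy[nn, col] * c(-(pk[2] - cj[2]), pk[1] - cj[1])
          }
        }
      }
      if (cfg$w_frame_pos != 0) G <- G + cfg$w_frame_pos * crossprod(v)
      if (cfg$w_frame_rot != 0) {
        a <- numeric(m)
        for (col in seq_len(m)) {
          a[col] <- (col <= k) + sum(dzdy[, col] * ((m + 1:3) <= k))
        }
        G <- G + cfg$w_frame_rot * outer(a, a)
      }
    }
  }
  if (m == 1L) {
    if (G[1, 1] <= 0) return(NULL)
    log(G[1, 1])
  } else if (m == 2L) {
    d <- G[1, 1] * G[2, 2] - G[1, 2] * G[2, 1]
    if (d <= 0) return(NULL)
    log(d)
  } else {
    log_det_psd(G)
  }
}

# One closure-block MH move on the flat planar representation.  Mirrors
# sample_block_mh including its use of the random stream.
planar_block_step <- function(q, poses, i, b, chain, fast, prior, cfg, end2d) {
  n <- chain$n_joints
  L <- chain$lengths
  m <- b - 3L
  yidx <- i:(i + m - 1L)
  y <- prior$sample(yidx, q[yidx])
  # independent forward kinematics; P collects T_{i-1} .. T_{i+b-1}
  P <- matrix(0, 3, b + 1L)
  P[, 1] <- poses[, i]
  px <- P[1, 1]; py <- P[2, 1]; th <- P[3, 1]
  for (j in seq_len(m)) {
    ll <- L[i + j - 1L]
    px <- px + ll * cos(th); py <- py + ll * sin(th); th <- th + y[j]
    P[, j + 1L] <- c(px, py, th)
  }
  anchor_e <- if (i + b - 1L == n && !is.null(end2d)) end2d else poses[, i + b]
  sol <- solve_planar(c(px, py, th), anchor_e, L[(i + m):(i + b - 1L)])
  if (sol$count == 0) return(list(accepted = FALSE, reason = "ik_failure"))
  k <- sample.int(sol$count, 1)
  z <- sol$solutions[k, ]
  for (j in 1:3) {
    ll <- L[i + m + j - 1L]
    px <- px + ll * cos(th); py <- py + ll * sin(th); th <- th + z[j]
    P[, m + j + 1L] <- c(px, py, th)
  }
  # terminal column is the anchor (closure holds to solver tolerance)
  P[, b + 1L] <- anchor_e
  ld_fwd <- planar_logdetG(P, m, cfg)
  if (is.null(ld_fwd)) return(list(accepted = FALSE, reason = "singular"))
  Pcur <- poses[, i:(i + b), drop = FALSE]
  ld_rev <- planar_logdetG(Pcur, m, cfg)
  if (is.null(ld_rev)) return(list(accepted = FALSE, reason = "singular"))
  s_rev <- solve_planar(poses[, i + m], anchor_e, L[(i + m):(i + b - 1L)])$count
  s_rev <- max(s_rev, 1L)
  log_qf <- log_Q(prior$logdens(y, yidx, q[yidx]), sol$count, ld_fwd, cfg)
  log_qr <- log_Q(prior$logdens(q[yidx], yidx, y), s_rev, ld_rev, cfg)
  q_new <- q
  q_new[i:(i + b - 1L)] <- c(y, z)
  d_score <- 0
  if (fast$any_angle || fast$any_pos) {
    poses_new <- poses
    poses_new[, (i + 1L):(i + b - 1L)] <- P[, 2:b]
    idx <- i:(i + b - 1L); fr <- i:(i + b - 2L)
    d_score <- planar_block_logscore(fast, q_new, poses_new, idx, fr) -
      planar_block_logscore(fast, q, poses, idx, fr)
  }
  log_alpha <- min(0, d_score + log_qr - log_qf)
  u <- stats::runif(1)
  if (!(is.finite(log_alpha) && log(u) < log_alpha)) {
    return(list(accepted = FALSE, reason = "rejected"))
  }
  list(accepted = TRUE, reason = "none", q = q_new, block_poses = P[, 2:b, drop = FALSE])
}

# free terminal block: Gaussian angle perturbation, no closure
planar_free_step <- function(q, poses, i, b, chain, fast, cfg) {
  n <- chain$n_joints
  L <- chain$lengths
  q_new <- q
  q_new[i:(i + b - 1L)] <- q_new[i:(i + b - 1L)] + stats::rnorm(b, 0, cfg$sigma_free)
  poses_new <- poses
  px <- poses[1, i]; py <- poses[2, i]; th <- poses[3, i]
  for (j in i:n) {
    px <- px + L[j] * cos(th); py <- py + L[j] * sin(th); th <- th + q_new[j]
    poses_new[, j + 1L] <- c(px, py, th)
  }
  idx <- i:(i + b - 1L); fr <- i:n
  d_score <- planar_block_logscore(fast, q_new, poses_new, idx, fr) -
    planar_block_logscore(fast, q, poses, idx, fr)
  log_alpha <- min(0, d_score)
  u <- stats::runif(1)
  if (!(is.finite(log_alpha) && log(u) < log_alpha)) {
    return(list(accepted = FALSE, reason = "rejected"))
  }
  list(accepted = TRUE, reason = "none", q = q_new, poses = poses_new)
}

planar_run <- function(chain, state, fg, cfg, prior, fast, progress = 0) {
  n <- chain$n_joints
  b <- cfg$b
  poses <- rbind(state$frames[1, 4, ], state$frames[2, 4, ],
                 atan2(state$frames[2, 1, ], state$frames[1, 1, ]))
  q <- state$angles
  end2d <- if (!is.null(chain$end_constraint)) tf_to_planar(chain$end_constraint)
  if (!is.null(end2d)) poses[, n + 1L] <- end2d
  plan <- block_plan(chain, cfg)
  nb <- nrow(plan)
  out <- matrix(0, cfg$n_samples + 1L, n)
  out[1, ] <- q
  n_acc <- n_tot <- 0L
  reasons <- c(ik_failure = 0L, singular = 0L, clash = 0L, rejected = 0L)
  for (sweep in seq_len(cfg$n_samples)) {
    ord <- switch(cfg$sweep, forward = seq_len(nb), backward = rev(seq_len(nb)),
                  random = sample.int(nb))
    for (kb in ord) {
      i <- plan$i[kb]
      if (plan$type[kb] == "free") {
        st <- planar_free_step(q, poses, i, b, chain, fast, cfg)
        if (st$accepted) { q <- st$q; poses <- st$poses }
      } else {
        st <- planar_block_step(q, poses, i, b, chain, fast, prior, cfg, end2d)
        if (st$accepted) {
          q <- st$q
          poses[, (i + 1L):(i + b - 1L)] <- st$block_poses
        }
      }
      n_tot <- n_tot + 1L
      if (st$accepted) n_acc <- n_acc + 1L else reasons[st$reason] <- reasons[st$reason] + 1L
    }
    out[sweep + 1L, ] <- q
    if (progress > 0 && sweep %% progress == 0) {
      message(sprintf("sweep %d/%d accept %.3f", sweep, cfg$n_samples, n_acc / n_tot))
    }
  }
  # rebuild the final expanded state through the generic path
  final <- new_state(chain, q)
  new_ensemble(chain, out, cfg, n_acc, n_tot, reasons, final)
}
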