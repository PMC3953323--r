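# The outer sampling loop.
#
# One Gibbs sweep visits overlapping blocks of consecutive angles along the
# chain (stride one residue for backbones, one angle for planar chains).
# Each block move proposes a closed candidate with sample_block, computes the
# proposal densities of the forward and reverse moves from the prior value,
# the IK solution counts and the chart metric tensors at both points, and
# accepts with the Metropolis-Hastings probability
#   alpha = min(1, Phi_B(x') Q_B(x | xC) / (Phi_B(x) Q_B(x' | xC))).
# Clash factors are evaluated only after a provisional acceptance (they cost
# far more than the other factors and can only veto), which leaves the
# accept/reject semantics unchanged.

#' Sampler configuration
#'
#' @param b block size in angles: 8 for backbones (4 residues), 4 for planar
#'   chains.  Closed-chain mixing needs `b >= 7` spatial / `b >= 4` planar.
#' @param n_samples number of Gibbs sweeps (one recorded sample per sweep).
#' @param skip thinning stride for the quasi-independent subsequence.
#' @param seed RNG seed; fully determines the run.
#' @param sweep block visiting order.
#' @param temperature temperature used by energy-based factors.
#' @param bfactor_scale confidence scale applied to B-factor priors.
#' @param sigma_free standard deviation (radians) of the Gaussian angle
#'   perturbation used for free-endpoint terminal blocks (default 1 degree).
#' @param w_angle,w_frame_pos,w_frame_rot diagonal weights of the chart
#'   metric (angle rows, frame-origin rows, frame-orientation rows).
#' @param rcond_min reciprocal-condition guard for the implicit chart
#'   Jacobian; steps at worse-conditioned states are rejected.
#' @param defer_clash evaluate clash factors only after provisional
#'   acceptance.
#' @param drop_metric,drop_solution_count diagnostic switches that omit the
#'   `sqrt(det G)` or `1/s` term from the proposal density.  They break the
#'   unbiasedness guarantee and exist to demonstrate it.
#' @param ik effort controls passed to [solve_spatial_6()].
#' @param allow_small permit non-mixing block sizes (diagnostics only).
#' @param debug re-verify the frame-consistency invariant after every sweep.
#' @param log_file optional path for a JSON-lines per-step log (block index,
#'   acceptance probability, reason code); forces the generic code path.
#' @export
sampler_config <- function(b = 8L, n_samples = 100L, skip = 1L, seed = 1L,
                           sweep = c("forward", "backward", "random"),
                           temperature = 1, bfactor_scale = 1,
                           sigma_free = pi / 180,
                           w_angle = 1, w_frame_pos = 1, w_frame_rot = 0,
                           rcond_min = 1e-10, defer_clash = TRUE,
                           drop_metric = FALSE, drop_solution_count = FALSE,
                           ik = list(batch = 16L, settle = 2L, max_seeds = 96L),
                           allow_small = FALSE, debug = FALSE, log_file = NULL) {
  sweep <- match.arg(sweep)
  stopifnot(b >= 2, n_samples >= 0, skip >= 1, temperature > 0,
            bfactor_scale > 0, sigma_free >= 0)
  as.list(environment())
}

# Enumerate the blocks of one sweep.  Backbone chains stride by residue (2
# angles); planar chains stride by angle.  Free-endpoint chains sample their
# terminal block with standard MC instead of closure.
block_plan <- function(chain, cfg) {
  n <- chain$n_joints
  b <- cfg$b
  stride <- if (is.null(chain$meta$angle_kind)) 1L else 2L
  if (b > n) stop("block size exceeds chain length")
  starts <- seq(1L, n - b + 1L, by = stride)
  closed <- !is.null(chain$end_constraint)
  types <- rep("closure", length(starts))
  if (!closed) types[length(types)] <- "free"
  data.frame(i = starts, b = b, type = types, stringsAsFactors = FALSE)
}

mh_step <- function(accepted, reason = "none", alpha = NA_real_,
                    s_fwd = NA_integer_, s_rev = NA_integer_,
                    logdetG_fwd = NA_real_, logdetG_rev = NA_real_) {
  list(accepted = accepted, reason = reason, alpha = alpha,
       s_fwd = s_fwd, s_rev = s_rev,
       logdetG_fwd = logdetG_fwd, logdetG_rev = logdetG_rev)
}

# evaluation context of a state
state_ctx <- function(chain, q, frames, atoms = NULL) {
  list(q = q, frames = frames, atoms = atoms, chain = chain)
}

block_vars <- function(chain, i, b, terminal_free = FALSE) {
  n <- chain$n_joints
  fr_hi <- if (terminal_free) n else i + b - 2L
  frames <- i:fr_hi
  at <- chain$meta$atom_owners
  atoms <- if (!is.null(at)) which(at$owner %in% frames) else integer(0)
  list(angles = i:(i + b - 1L), frames = frames, atoms = atoms)
}

# log proposal density of the block sampler at one point of the manifold
log_Q <- function(log_p_y, s, logdetG, cfg) {
  v <- log_p_y
  if (!cfg$drop_solution_count) v <- v - log(s)
  if (!cfg$drop_metric) v <- v - 0.5 * logdetG
  v
}

# chart metric log-determinant at a state (frames must satisfy closure)
block_logdetG <- function(chain, frames, i, b, cfg) {
  cj <- constraint_jacobians(chain, frames, i, b)
  icj <- implicit_chart_jacobian(cj$Cy, cj$Cz, cfg$rcond_min)
  if (icj$singular) return(NULL)
  ch <- chart_jacobian(chain, frames, i, b, icj$dzdy,
                       cfg$w_angle, cfg$w_frame_pos, cfg$w_frame_rot)
  G <- metric_tensor(ch$J, ch$w)
  log_det_psd(G)
}

clash_log_score <- function(fg, ctx, vars) {
  ids <- factors_touching(fg, vars$angles, vars$frames, vars$atoms)
  total <- 0
  for (k in ids) {
    f <- fg$factors[[k]]
    if (f$type != "clash") next
    v <- f$logf(ctx)
    if (!is.finite(v) && v < 0) return(-Inf)
    total <- total + v
  }
  total
}

#' One Metropolis-Hastings block move
#'
#' Proposes a closed candidate for the block starting at angle `i` and
#' accepts or rejects it; IK failure and chart singularity count as
#' rejections (the reverse proposal density at the retained state is always
#' well defined, so detailed balance is preserved).
#'
#' @param chain,state chain and current state.
#' @param i first angle of the block.
#' @param fg a `slik_factor_graph`.
#' @param prior independent-angle proposal prior.
#' @param cfg a [sampler_config()].
#' @return list with `state` (possibly updated) and `step` (acceptance
#'   record: `accepted`, `reason`, `alpha`, solution counts and chart
#'   log-determinants of both move directions).
#' @export
sample_block_mh <- function(chain, state, i, fg, prior = uniform_angle_prior(),
                            cfg = sampler_config()) {
  b <- cfg$b
  n <- chain$n_joints
  m_dep <- if (chain$planar) 3L else 6L
  m <- b - m_dep
  if (m < 1 && !cfg$allow_small) stop("non-mixing block size; see allow_small")
  anchor_end <- if (i + b - 1L == n && !is.null(chain$end_constraint)) {
    chain$end_constraint
  } else {
    state$frames[, , i + b]
  }
  cand <- sample_block(chain, state, i, b, prior = prior,
                       allow_small = cfg$allow_small, ik = cfg$ik)
  if (cand$status != "ok") {
    return(list(state = state, step = mh_step(FALSE, "ik_failure")))
  }
  if (b <= m_dep && identical(cand$angles, state$angles[i:(i + b - 1L)])) {
    # over-determined block whose only root is the current conformation:
    # the move is the identity, accepted with probability one
    return(list(state = state, step = mh_step(TRUE, "none", 1, cand$s, cand$s)))
  }
  # candidate frames: recompute the block's interior, keep the anchor exact
  frames_new <- state$frames
  T <- state$frames[, , i]
  for (k in seq_len(b - 1L)) {
    j <- i + k - 1L
    T <- T %*% chain$rel[, , j] %*% tf_new(rot_axis_angle(chain$axes[, j], cand$angles[k]))
    frames_new[, , j + 1L] <- T
  }
  q_new <- state$angles
  q_new[i:(i + b - 1L)] <- cand$angles

  if (m >= 1) {
    ld_fwd <- block_logdetG(chain, frames_new, i, b, cfg)
    if (is.null(ld_fwd)) return(list(state = state, step = mh_step(FALSE, "singular")))
    ld_rev <- block_logdetG(chain, state$frames, i, b, cfg)
    if (is.null(ld_rev)) return(list(state = state, step = mh_step(FALSE, "singular")))
    # reverse-move solution count at the current independent angles
    cur <- state$angles[i:(i + b - 1L)]
    if (chain$planar) {
      s_rev <- solve_planar(tf_to_planar(state$frames[, , i + m]),
                            tf_to_planar(anchor_end),
                            chain$lengths[(i + m):(i + b - 1L)])$count
    } else {
      sub <- chain_slice(chain, i + m, i + b - 1L)
      args <- c(list(sub, state$frames[, , i + m], anchor_end,
                     hints = rbind(cur[(m + 1):b])), cfg$ik)
      s_rev <- do.call(solve_spatial_6, args)$count
    }
    s_rev <- max(s_rev, 1L)
    yidx <- i:(i + m - 1L)
    y_cur <- cur[seq_len(m)]
    log_qf <- log_Q(prior$logdens(cand$y, yidx, y_cur), cand$s, ld_fwd, cfg)
    log_qr <- log_Q(prior$logdens(y_cur, yidx, cand$y), s_rev, ld_rev, cfg)
  } else {
    ld_fwd <- ld_rev <- NA_real_
    s_rev <- cand$s
    log_qf <- log_qr <- 0
  }

  vars <- block_vars(chain, i, b)
  atoms_new <- if (!is.null(state$atoms)) backbone_to_atoms(chain, frames_new)
  ctx_new <- state_ctx(chain, q_new, frames_new, atoms_new)
  ctx_cur <- state_ctx(chain, state$angles, state$frames, state$atoms)
  skip <- if (cfg$defer_clash) "clash" else character(0)
  d_score <- block_score(fg, ctx_new, vars$angles, vars$frames, vars$atoms, skip_types = skip) -
    block_score(fg, ctx_cur, vars$angles, vars$frames, vars$atoms, skip_types = skip)
  if (!cfg$defer_clash) {
    d_score <- d_score + clash_log_score(fg, ctx_new, vars)
  }
  log_alpha <- min(0, d_score + log_qr - log_qf)
  u <- stats::runif(1)
  acc <- is.finite(log_alpha) && log(u) < log_alpha
  if (acc && cfg$defer_clash && clash_log_score(fg, ctx_new, vars) == -Inf) {
    return(list(state = state,
                step = mh_step(FALSE, "clash", exp(log_alpha), cand$s, s_rev, ld_fwd, ld_rev)))
  }
  if (!acc) {
    return(list(state = state,
                step = mh_step(FALSE, "rejected", exp(log_alpha), cand$s, s_rev, ld_fwd, ld_rev)))
  }
  state$angles <- q_new
  state$frames <- frames_new
  state$atoms <- atoms_new
  list(state = state,
       step = mh_step(TRUE, "none", exp(log_alpha), cand$s, s_rev, ld_fwd, ld_rev))
}

#' Standard MC move for a terminal free-endpoint block
#'
#' Gaussian perturbation of the block's angles (symmetric proposal, so the
#' acceptance probability is just the score ratio); no closure constraint and
#' no metric correction are involved.
#' @inheritParams sample_block_mh
#' @export
sample_free_endpoint_block <- function(chain, state, i, fg, cfg = sampler_config()) {
  b <- cfg$b
  n <- chain$n_joints
  if (!is.null(chain$end_constraint) && i + b - 1L == n) {
    stop("block touches a constrained end; use sample_block_mh")
  }
  q_new <- state$angles
  q_new[i:(i + b - 1L)] <- q_new[i:(i + b - 1L)] + stats::rnorm(b, 0, cfg$sigma_free)
  frames_new <- state$frames
  T <- state$frames[, , i]
  for (j in i:n) {
    T <- T %*% chain$rel[, , j] %*% tf_new(rot_axis_angle(chain$axes[, j], q_new[j]))
    frames_new[, , j + 1L] <- T
  }
  vars <- block_vars(chain, i, b, terminal_free = TRUE)
  atoms_new <- if (!is.null(state$atoms)) backbone_to_atoms(chain, frames_new)
  ctx_new <- state_ctx(chain, q_new, frames_new, atoms_new)
  ctx_cur <- state_ctx(chain, state$angles, state$frames, state$atoms)
  skip <- if (cfg$defer_clash) "clash" else character(0)
  d_score <- block_score(fg, ctx_new, vars$angles, vars$frames, vars$atoms, skip_types = skip) -
    block_score(fg, ctx_cur, vars$angles, vars$frames, vars$atoms, skip_types = skip)
  if (!cfg$defer_clash) d_score <- d_score + clash_log_score(fg, ctx_new, vars)
  log_alpha <- min(0, d_score)
  u <- stats::runif(1)
  acc <- is.finite(log_alpha) && log(u) < log_alpha
  if (acc && cfg$defer_clash && clash_log_score(fg, ctx_new, vars) == -Inf) {
    return(list(state = state, step = mh_step(FALSE, "clash", exp(log_alpha))))
  }
  if (!acc) {
    return(list(state = state, step = mh_step(FALSE, "rejected", exp(log_alpha))))
  }
  state$angles <- q_new
  state$frames <- frames_new
  state$atoms <- atoms_new
  list(state = state, step = mh_step(TRUE, "none", exp(log_alpha)))
}

#' One Gibbs sweep over all blocks
#'
#' Visits the overlapping blocks in the configured order (the order has no
#' effect on the stationary distribution) and applies one MH move to each.
#' @inheritParams sample_block_mh
#' @return list with `state` and `steps` (one record per block).
#' @export
gibbs_sweep <- function(chain, state, fg, prior = uniform_angle_prior(),
                        cfg = sampler_config()) {
  plan <- block_plan(chain, cfg)
  ord <- switch(cfg$sweep,
                forward = seq_len(nrow(plan)),
                backward = rev(seq_len(nrow(plan))),
                random = sample.int(nrow(plan)))
  steps <- vector("list", nrow(plan))
  for (k in ord) {
    res <- if (plan$type[k] == "free") {
      sample_free_endpoint_block(chain, state, plan$i[k], fg, cfg)
    } else {
      sample_block_mh(chain, state, plan$i[k], fg, prior, cfg)
    }
    state <- res$state
    steps[[k]] <- c(block = plan$i[k], res$step)
  }
  list(state = state, steps = steps)
}

#' Run the sampler
#'
#' Generates `n_samples` sweeps from the initial state (which must satisfy
#' closure) and records the angle trajectory, acceptance statistics and the
#' thinned quasi-independent subsequence.  Fully deterministic given
#' `cfg$seed`.
#'
#' @inheritParams sample_block_mh
#' @param progress print a line every `progress` sweeps (0: silent).
#' @return object of class `slik_ensemble`: `angles` (samples x N matrix,
#'   first row the initial state), `thinned_idx`, acceptance statistics,
#'   `final_state`, and the run configuration.
#' @export
run_sampler <- function(chain, state, fg, cfg = sampler_config(),
                        prior = uniform_angle_prior(), progress = 0) {
  if (!is.null(cfg$seed) && !is.na(cfg$seed)) set.seed(cfg$seed)
  if (chain$planar && is.null(cfg$log_file) && !isTRUE(cfg$debug)) {
    fast <- planar_compile(chain, fg, cfg)
    if (!is.null(fast)) {
      return(planar_run(chain, state, fg, cfg, prior, fast, progress))
    }
  }
  log_con <- if (!is.null(cfg$log_file)) file(cfg$log_file, "w")
  if (!is.null(log_con)) on.exit(close(log_con))
  n <- chain$n_joints
  out <- matrix(0, cfg$n_samples + 1L, n)
  out[1, ] <- state$angles
  n_acc <- n_tot <- 0L
  reasons <- c(ik_failure = 0L, singular = 0L, clash = 0L, rejected = 0L)
  for (k in seq_len(cfg$n_samples)) {
    sw <- gibbs_sweep(chain, state, fg, prior, cfg)
    state <- sw$state
    out[k + 1L, ] <- state$angles
    for (st in sw$steps) {
      n_tot <- n_tot + 1L
      if (st$accepted) n_acc <- n_acc + 1L
      else reasons[st$reason] <- reasons[st$reason] + 1L
      if (!is.null(log_con)) {
        writeLines(jsonlite::toJSON(
          list(sweep = k, block = st$block, accepted = st$accepted,
               alpha = st$alpha, reason = st$reason),
          auto_unbox = TRUE, digits = NA, null = "null", na = "null"), log_con)
      }
    }
    if (isTRUE(cfg$debug)) validate_state(chain, state)
    if (progress > 0 && k %% progress == 0) {
      message(sprintf("sweep %d/%d accept %.3f", k, cfg$n_samples, n_acc / n_tot))
    }
  }
  new_ensemble(chain, out, cfg, n_acc, n_tot, reasons, state)
}

new_ensemble <- function(chain, angles, cfg, n_acc, n_tot, reasons, final_state) {
  structure(list(angles = angles, chain = chain, config = cfg,
                 acceptance_rate = if (n_tot) n_acc / n_tot else NA_real_,
                 n_steps = n_tot, reasons = reasons,
                 thinned_idx = seq(1L, nrow(angles), by = cfg$skip),
                 final_state = final_state),
            class = "slik_ensemble")
}

#' @export
print.slik_ensemble <- function(x, ...) {
  cat(sprintf("<slik_ensemble> %d samples x %d angles; acceptance %.3f (%d block moves)\n",
              nrow(x$angles), ncol(x$angles), x$acceptance_rate, x$n_steps))
  if (any(x$reasons > 0)) {
    cat("  rejections:", paste(names(x$reasons), x$reasons, collapse = ", "), "\n")
  }
  cat(sprintf("  thinned (skip %d): %d samples\n", x$config$skip, length(x$thinned_idx)))
  invisible(x)
}

#' Whole-chain Metropolis-Hastings baseline
#'
#' The classical sampler that perturbs every angle at once with an isotropic
#' Gaussian (default 1 degree standard deviation) and accepts on the full
#' score ratio.  Only applicable to chains without a closure constraint (the
#' closed-loop acceptance probability would be zero); used as the scaling
#' comparison baseline.
#' @inheritParams run_sampler
#' @export
run_baseline_mh <- function(chain, state, fg, cfg = sampler_config()) {
  if (!is.null(chain$end_constraint)) {
    stop("whole-chain MH cannot satisfy a closure constraint")
  }
  if (!is.null(cfg$seed) && !is.na(cfg$seed)) set.seed(cfg$seed)
  n <- chain$n_joints
  out <- matrix(0, cfg$n_samples + 1L, n)
  out[1, ] <- state$angles
  n_acc <- 0L
  ctx_cur <- state_ctx(chain, state$angles, state$frames, state$atoms)
  score_cur <- full_score(fg, ctx_cur)
  for (k in seq_len(cfg$n_samples)) {
    q_new <- state$angles + stats::rnorm(n, 0, cfg$sigma_free)
    frames_new <- forward_kinematics(chain, q_new)
    atoms_new <- if (!is.null(state$atoms)) backbone_to_atoms(chain, frames_new)
    ctx_new <- state_ctx(chain, q_new, frames_new, atoms_new)
    score_new <- full_score(fg, ctx_new)
    if (is.finite(score_new) && log(stats::runif(1)) < score_new - score_cur) {
      state$angles <- q_new; state$frames <- frames_new; state$atoms <- atoms_new
      score_cur <- score_new
      n_acc <- n_acc + 1L
    }
    out[k + 1L, ] <- state$angles
  }
  new_ensemble(chain, out, cfg, n_acc, cfg$n_samples,
               c(ik_failure = 0L, singular = 0L, clash = 0L,
                 rejected = cfg$n_samples - n_acc), state)
}
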