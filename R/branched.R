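# Planar branched structures with multiple closure constraints.
#
# A tree of links rooted at a fixed base, with some leaves anchored to fixed
# poses (each anchored path is a closed ring).  The whole structure is
# sampled as one block: independent angles are drawn from a prior, then each
# anchored branch is closed in topological order with the planar three-angle
# solver (its last three angles are the dependent subchain).  The proposal
# density keeps the form Q = P(y) / (s sqrt(det G)), with s the product of
# the per-branch solution counts and G the metric tensor of the joint chart
# through the sparse multi-constraint implicit Jacobian.  Pose propagation
# follows the linear-chain convention (translate along the incoming
# direction, then rotate), so a tree without branches is exactly a linear
# planar chain.

#' Construct a planar tree structure
#'
#' @param parent integer vector: for each edge its parent edge (0 = root).
#'   Edges must be listed in topological order (parent before child).
#' @param lengths link lengths.
#' @param base root pose `c(x, y, theta)`.
#' @param anchors named list: edge id (as character) -> fixed pose
#'   `c(x, y, theta)` for the distal node of that edge.  Each anchored path
#'   must end in at least 3 edges not shared with another anchored path's
#'   dependent set.
#' @export
planar_tree <- function(parent, lengths, base = c(0, 0, 0), anchors = list()) {
  E <- length(parent)
  stopifnot(length(lengths) == E, all(lengths > 0), all(parent < seq_len(E)))
  path_of <- function(e) {
    p <- integer(0)
    while (e != 0) { p <- c(e, p); e <- parent[e] }
    p
  }
  paths <- lapply(seq_len(E), path_of)
  a_ids <- as.integer(names(anchors))
  # dependent split: last 3 edges of each anchored path, claimed once
  claimed <- integer(0)
  dep <- list()
  for (e in a_ids) {
    pa <- paths[[e]]
    if (length(pa) < 3) stop("anchored path to edge ", e, " has fewer than 3 joints")
    z3 <- utils::tail(pa, 3)
    if (any(z3 %in% claimed)) stop("dependent subchains of anchors overlap")
    claimed <- c(claimed, z3)
    dep[[as.character(e)]] <- z3
  }
  y_idx <- setdiff(seq_len(E), claimed)
  structure(list(E = E, parent = as.integer(parent), lengths = lengths,
                 base = base, anchors = anchors, paths = paths,
                 dep = dep, y_idx = y_idx, z_idx = claimed),
            class = "slik_planar_tree")
}

#' @export
print.slik_planar_tree <- function(x, ...) {
  cat(sprintf("<slik_planar_tree> %d links, %d anchors, manifold dim %d\n",
              x$E, length(x$anchors), length(x$y_idx)))
  invisible(x)
}

#' Forward kinematics on a planar tree
#'
#' @param tree a [planar_tree()].
#' @param q edge angles (radians).
#' @return list with `node` (2 x E distal node positions), `theta_in`,
#'   `theta_out` per edge.
#' @export
tree_fk <- function(tree, q) {
  E <- tree$E
  node <- matrix(0, 2, E)
  th_in <- th_out <- numeric(E)
  for (e in seq_len(E)) {
    p <- tree$parent[e]
    if (p == 0) {
      th <- tree$base[3]; px <- tree$base[1]; py <- tree$base[2]
    } else {
      th <- th_out[p]; px <- node[1, p]; py <- node[2, p]
    }
    th_in[e] <- th
    node[1, e] <- px + tree$lengths[e] * cos(th)
    node[2, e] <- py + tree$lengths[e] * sin(th)
    th_out[e] <- th + q[e]
  }
  list(node = node, theta_in = th_in, theta_out = th_out)
}

#' Closure residuals of a planar tree state
#'
#' One `(dx, dy, dtheta)` triple per anchor; all zero on the solution
#' manifold.
#' @inheritParams tree_fk
#' @export
tree_closure_error <- function(tree, q) {
  fk <- tree_fk(tree, q)
  out <- numeric(0)
  for (e in names(tree$anchors)) {
    k <- as.integer(e)
    a <- tree$anchors[[e]]
    out <- c(out, fk$node[1, k] - a[1], fk$node[2, k] - a[2],
             wrap_angle(fk$theta_out[k] - a[3]))
  }
  out
}

# stacked closure-constraint Jacobian (3 rows per anchor, columns = edges)
tree_constraint_jacobian <- function(tree, fk) {
  nA <- length(tree$anchors)
  J <- matrix(0, 3 * nA, tree$E)
  for (ai in seq_len(nA)) {
    leaf <- as.integer(names(tree$anchors)[ai])
    pl <- fk$node[, leaf]
    rows <- (ai - 1) * 3 + 1:3
    for (e in tree$paths[[leaf]]) {
      ce <- fk$node[, e]                 # joint centre: distal node of edge e
      if (e != leaf) {
        J[rows[1], e] <- -(pl[2] - ce[2])
        J[rows[2], e] <- pl[1] - ce[1]
      }
      J[rows[3], e] <- 1
    }
  }
  J
}

# chart metric log-determinant of the whole-tree block; returns NULL at
# singular states.  Also returns dzdy for reuse.
tree_logdetG <- function(tree, fk, cfg) {
  m <- length(tree$y_idx)
  JC <- tree_constraint_jacobian(tree, fk)
  Cz <- JC[, tree$z_idx, drop = FALSE]
  rc <- rcond(Cz)
  if (!is.finite(rc) || rc < cfg$rcond_min) return(NULL)
  dzdy <- -solve(Cz, JC[, tree$y_idx, drop = FALSE])
  # total derivative of any edge angle w.r.t. y (identity over y, dzdy over z)
  dq_dy <- matrix(0, tree$E, m)
  dq_dy[tree$y_idx, ] <- diag(m)
  dq_dy[tree$z_idx, ] <- dzdy
  G <- cfg$w_angle * crossprod(dq_dy)
  anchored <- as.integer(names(tree$anchors))
  for (k in seq_len(tree$E)) {
    if (k %in% anchored) next            # anchored node poses are fixed
    pk <- fk$node[, k]
    path_k <- tree$paths[[k]]
    v <- matrix(0, 2, m)
    a <- numeric(m)
    for (e in path_k) {
      ce <- fk$node[, e]
      de <- if (e != k) c(-(pk[2] - ce[2]), pk[1] - ce[1]) else c(0, 0)
      v <- v + outer(de, dq_dy[e, ])
      a <- a + dq_dy[e, ]
    }
    if (cfg$w_frame_pos != 0) G <- G + cfg$w_frame_pos * crossprod(v)
    if (cfg$w_frame_rot != 0) G <- G + cfg$w_frame_rot * outer(a, a)
  }
  ld <- log_det_psd(G)
  if (is.null(ld)) return(NULL)
  list(logdet = ld, dzdy = dzdy)
}

# close all anchored branches given the independent angles; q_partial must
# hold values for y_idx.  Returns q, per-branch counts and the branch picks
# (random or forced).  NULL on any branch failure.
tree_close <- function(tree, q, picks = NULL) {
  counts <- integer(length(tree$anchors))
  used <- integer(length(tree$anchors))
  for (ai in seq_along(tree$anchors)) {
    leaf <- as.integer(names(tree$anchors)[ai])
    z3 <- tree$dep[[as.character(leaf)]]
    # pose entering the first dependent edge, from the partial FK
    fk <- tree_fk(tree, q)               # dependent angles beyond are junk but unused:
    e1 <- z3[1]
    p <- tree$parent[e1]
    T_in <- if (p == 0) tree$base else c(fk$node[, p], fk$theta_out[p])
    sol <- solve_planar(T_in, tree$anchors[[as.character(leaf)]],
                        tree$lengths[z3])
    if (sol$count == 0) return(NULL)
    counts[ai] <- sol$count
    k <- if (is.null(picks)) sample.int(sol$count, 1) else picks[ai]
    if (k > sol$count) return(NULL)
    used[ai] <- k
    q[z3] <- sol$solutions[k, ]
  }
  list(q = q, counts = counts, picks = used)
}

#' One MH move on a planar branched block
#'
#' Samples the independent angles from the prior, closes every anchored
#' branch in topological order, and accepts with the metric-corrected MH
#' probability; `s` is the product of the branch solution counts.  Branch IK
#' failure counts as a rejection.
#'
#' @param tree a [planar_tree()].
#' @param q current angles (must satisfy all closures).
#' @param log_score function(q, fk) returning the log target score.
#' @param prior independent-angle proposal prior.
#' @param cfg a [sampler_config()].
#' @return list with `q` (possibly updated) and `step`.
#' @export
sample_branched_block_2d <- function(tree, q, log_score, prior = uniform_angle_prior(),
                                     cfg = sampler_config(b = 4L)) {
  q_new <- q
  q_new[tree$y_idx] <- prior$sample(tree$y_idx, q[tree$y_idx])
  cl <- tree_close(tree, q_new)
  if (is.null(cl)) return(list(q = q, step = mh_step(FALSE, "ik_failure")))
  q_new <- cl$q
  fk_new <- tree_fk(tree, q_new)
  g_new <- tree_logdetG(tree, fk_new, cfg)
  if (is.null(g_new)) return(list(q = q, step = mh_step(FALSE, "singular")))
  fk_cur <- tree_fk(tree, q)
  g_cur <- tree_logdetG(tree, fk_cur, cfg)
  if (is.null(g_cur)) return(list(q = q, step = mh_step(FALSE, "singular")))
  # reverse solution counts at the current independent angles
  s_rev <- 1L
  for (ai in seq_along(tree$anchors)) {
    leaf <- as.integer(names(tree$anchors)[ai])
    z3 <- tree$dep[[as.character(leaf)]]
    e1 <- z3[1]
    p <- tree$parent[e1]
    T_in <- if (p == 0) tree$base else c(fk_cur$node[, p], fk_cur$theta_out[p])
    s_rev <- s_rev * max(1L, solve_planar(T_in, tree$anchors[[as.character(leaf)]],
                                          tree$lengths[z3])$count)
  }
  s_fwd <- prod(cl$counts)
  log_qf <- log_Q(prior$logdens(q_new[tree$y_idx], tree$y_idx, q[tree$y_idx]),
                  s_fwd, g_new$logdet, cfg)
  log_qr <- log_Q(prior$logdens(q[tree$y_idx], tree$y_idx, q_new[tree$y_idx]),
                  s_rev, g_cur$logdet, cfg)
  d_score <- log_score(q_new, fk_new) - log_score(q, fk_cur)
  log_alpha <- min(0, d_score + log_qr - log_qf)
  u <- stats::runif(1)
  if (!(is.finite(log_alpha) && log(u) < log_alpha)) {
    return(list(q = q, step = mh_step(FALSE, "rejected", exp(log_alpha), s_fwd, s_rev,
                                      g_new$logdet, g_cur$logdet)))
  }
  list(q = q_new, step = mh_step(TRUE, "none", exp(log_alpha), s_fwd, s_rev,
                                 g_new$logdet, g_cur$logdet))
}

#' Run the branched-block sampler
#'
#' Repeats [sample_branched_block_2d()] (the whole structure is one block,
#' which covers all state variables) and records the trajectory.
#' @inheritParams sample_branched_block_2d
#' @param n_samples number of moves.
#' @export
run_tree_sampler <- function(tree, q0, log_score, cfg = sampler_config(b = 4L),
                             prior = uniform_angle_prior()) {
  if (!is.null(cfg$seed) && !is.na(cfg$seed)) set.seed(cfg$seed)
  err <- tree_closure_error(tree, q0)
  if (max(abs(err)) > 1e-6) stop("initial tree state violates closure")
  out <- matrix(0, cfg$n_samples + 1L, tree$E)
  out[1, ] <- q0
  q <- q0
  n_acc <- 0L
  reasons <- c(ik_failure = 0L, singular = 0L, clash = 0L, rejected = 0L)
  for (k in seq_len(cfg$n_samples)) {
    res <- sample_branched_block_2d(tree, q, log_score, prior, cfg)
    q <- res$q
    if (res$step$accepted) n_acc <- n_acc + 1L
    else reasons[res$step$reason] <- reasons[res$step$reason] + 1L
    out[k + 1L, ] <- q
  }
  structure(list(angles = out, tree = tree, config = cfg,
                 acceptance_rate = n_acc / max(1L, cfg$n_samples),
                 n_steps = cfg$n_samples, reasons = reasons,
                 thinned_idx = seq(1L, cfg$n_samples + 1L, by = cfg$skip)),
            class = "slik_ensemble")
}
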