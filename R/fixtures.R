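# Synthetic fixtures: every input the pipeline consumes can be generated
# deterministically, so all functionality is testable without downloads.
# The planar fixtures emulate the benchmark systems used throughout mixing
# and stationarity studies (anchored 20-link chains with uniform or smooth
# priors, free chains with heterogeneous position priors, three-anchor
# branched rings); the mini-protein stands in for real PDB loops.

#' Anchored or free planar chain fixture
#'
#' Builds a planar chain of `n_links` equal links.  Closed chains are
#' anchored at both endpoints `anchor_dist` apart and initialised on a
#' circular arc (all bend angles equal), which is a valid closed clash-free
#' conformation; free chains start straight.
#'
#' @param n_links number of links.
#' @param length link length.
#' @param anchor_dist distance between the anchors (closed chains); must be
#'   below the total chain length.
#' @param closed anchor the far endpoint.
#' @param angle_prior optional list(mean, sd) (radians) putting a wrapped
#'   Gaussian score factor on every joint angle.
#' @param position_prior optional list(centres = 2 x (n+1) matrix, sd)
#'   putting Gaussian score factors on frame origins (NA columns skipped).
#' @return list with `chain`, `state` and `fg` (factor graph; empty when no
#'   priors are requested).
#' @export
make_planar_chain <- function(n_links = 20L, length = 1, anchor_dist = 10,
                              closed = TRUE, angle_prior = NULL,
                              position_prior = NULL) {
  stopifnot(n_links >= 4)
  L <- rep(length, n_links)
  if (closed) {
    if (anchor_dist >= sum(L)) {
      stop("anchors further apart (", anchor_dist, ") than the chain can reach (",
           sum(L), ")")
    }
    if (anchor_dist <= 0) stop("anchor distance must be positive")
    # inscribe the chain on a circular arc: equal bend angle beta at every
    # joint gives chord length L sin(n beta / 2) / sin(beta / 2)
    chord <- function(beta) length * sin(n_links * beta / 2) / sin(beta / 2)
    beta <- stats::uniroot(function(b) chord(b) - anchor_dist,
                           c(1e-9, 2 * pi / n_links - 1e-9), tol = 1e-14)$root
    th0 <- -(n_links - 1) * beta / 2
    q0 <- rep(beta, n_links)
    base <- c(0, 0, th0)
    poses <- fk_planar(L, q0, base)
    chain <- planar_chain(L, base = base, end = poses[, n_links + 1])
  } else {
    base <- c(0, 0, 0)
    q0 <- rep(0, n_links)
    chain <- planar_chain(L, base = base)
  }
  state <- new_state(chain, q0)
  facs <- list()
  if (!is.null(angle_prior)) {
    for (j in seq_len(n_links)) {
      facs[[length(facs) + 1]] <- angle_gauss_factor(j, angle_prior$mean, angle_prior$sd)
    }
  }
  if (!is.null(position_prior)) {
    for (j in 0:n_links) {
      mu <- position_prior$centres[, j + 1]
      if (any(is.na(mu))) next
      facs[[length(facs) + 1]] <- pos_gauss_factor(j, mu, position_prior$sd)
    }
  }
  list(chain = chain, state = state, fg = factor_graph(facs))
}

#' Synthetic mini-protein PDB fixture
#'
#' Writes an ideal-geometry poly-alanine structure with a designated loop
#' region, synthetic B-factors and (optionally) a helical or custom
#' conformation, as a valid single-chain PDB file.  This synthetic structure
#' stands in for real ion-binding-protein loops in all desk-scale tests.
#'
#' @param n_res total residues.
#' @param loop_start,loop_end loop region (needs one flanking residue on
#'   each side at least).
#' @param conformation `"helix"` (phi -57, psi -47), `"extended"`, or a list
#'   with `phi`, `psi` vectors (radians, length `n_res`).
#' @param bfactor constant or per-residue B-factor value(s).
#' @param file output path (default: a tempfile).
#' @param resid residue type written for every residue.
#' @return list with `path`, `loop_spec` and the coordinate list `bb`.
#' @export
make_mini_protein <- function(n_res = 12L, loop_start = 3L, loop_end = n_res - 2L,
                              conformation = "helix", bfactor = 20,
                              file = tempfile(fileext = ".pdb"),
                              resid = "ALA") {
  stopifnot(n_res >= 4, loop_start >= 2, loop_end <= n_res - 1, loop_start <= loop_end)
  d2r <- pi / 180
  if (identical(conformation, "helix")) {
    phi <- rep(-57 * d2r, n_res); psi <- rep(-47 * d2r, n_res)
  } else if (identical(conformation, "extended")) {
    phi <- rep(-139 * d2r, n_res); psi <- rep(135 * d2r, n_res)
  } else {
    phi <- conformation$phi; psi <- conformation$psi
    stopifnot(length(phi) == n_res, length(psi) == n_res)
  }
  bb <- build_backbone(phi, psi)
  b <- rep_len(bfactor, n_res)[bb$resno]
  bio3d::write.pdb(file = file, xyz = as.numeric(t(bb$xyz)),
                   resno = bb$resno, resid = rep(resid, length(bb$resno)),
                   eleno = seq_along(bb$resno), elety = bb$elety,
                   chain = rep("A", length(bb$resno)), o = rep(1, length(bb$resno)),
                   b = b)
  bb$b <- b
  list(path = file, loop_spec = list(chain = "A", start = loop_start, end = loop_end),
       bb = bb)
}

#' Two-basin toy Ramachandran grid
#'
#' A smooth mixture of two wrapped Gaussian basins (helical and extended
#' regions), normalised so that the values integrate to 1 over the torus
#' (sum times cell area in square radians).
#'
#' @param n_bins grid resolution per axis.
#' @param floor_frac small uniform floor so no cell has zero probability
#'   (set 0 to create hard-zero cells).
#' @export
make_toy_rama_grid <- function(n_bins = 36L, floor_frac = 0.02) {
  centres <- seq(-180, 180 - 360 / n_bins, by = 360 / n_bins) + 180 / n_bins
  wg <- function(x, mu, sd) {
    d <- (x - mu + 180) %% 360 - 180
    exp(-d^2 / (2 * sd^2))
  }
  v <- outer(centres, centres, function(phi, psi) {
    0.6 * wg(phi, -60, 25) * wg(psi, -45, 25) +
      0.4 * wg(phi, -120, 30) * wg(psi, 135, 30)
  })
  v <- (1 - floor_frac) * v / sum(v) + floor_frac / length(v)
  cell_area <- (2 * pi / n_bins)^2
  new_rama_grid(v / cell_area)
}

#' Toy backbone-dependent rotamer table
#'
#' A small Gaussian-mixture rotamer library for arginine (4 chi angles) with
#' one (phi, psi) bin covering the whole plane and three components at the
#' classical gauche+/trans/gauche- chi1 positions.
#' @param residue residue type to label.
#' @export
make_toy_rotamer_table <- function(residue = "ARG") {
  tab <- data.frame(
    residue = residue, phi_lo = -180, psi_lo = -180, bin_width = 360,
    weight = c(0.5, 0.3, 0.2),
    chi1_mean = c(-65, 180, 65), chi1_sd = c(10, 12, 10),
    chi2_mean = c(180, 180, -175), chi2_sd = c(12, 14, 12),
    chi3_mean = c(-65, 180, 65), chi3_sd = c(12, 14, 12),
    chi4_mean = c(-85, 180, 85), chi4_sd = c(15, 16, 15))
  new_rotamer_library(tab)
}

#' Three-anchor planar tree fixture
#'
#' A Y-shaped planar structure: a main chain between two anchored ends with
#' a branch to a third anchor, initialised at a valid closed conformation
#' found from a feasible construction.  Emulates a multiply-closed ring
#' structure constrained at three ends.
#'
#' @param n_main links in the main chain, `>= 7`.
#' @param n_branch links in the branch, `>= 3`.
#' @param branch_at main-chain link the branch hangs off.
#' @export
make_planar_tree <- function(n_main = 8L, n_branch = 4L, branch_at = 4L) {
  stopifnot(n_main >= 7, n_branch >= 3, branch_at >= 1, branch_at <= n_main - 3)
  parent <- c(0L, seq_len(n_main - 1L), branch_at, n_main + seq_len(n_branch - 1L))
  lengths <- rep(1, n_main + n_branch)
  base <- c(0, 0, 0)
  # initial conformation: well-bent subchains (keeping the dependent elbows
  # away from their stretched reach boundaries so nearby closures exist)
  q0 <- c(0.35, rep(c(0.8, -0.9), length.out = n_main - 1L),
          1.4, rep(c(0.9, -1.0), length.out = n_branch - 1L))
  tree0 <- planar_tree(parent, lengths, base, anchors = list())
  fk0 <- tree_fk(tree0, q0)
  anchors <- list()
  anchors[[as.character(n_main)]] <- c(fk0$node[, n_main], fk0$theta_out[n_main])
  leaf <- n_main + n_branch
  anchors[[as.character(leaf)]] <- c(fk0$node[, leaf], fk0$theta_out[leaf])
  tree <- planar_tree(parent, lengths, base, anchors = anchors)
  list(tree = tree, q0 = q0)
}
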