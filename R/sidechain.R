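# Side-chain sampling from backbone-dependent rotamer distributions.
#
# Side-chain torsions chi are drawn directly from the rotamer prior: the
# (phi, psi) plane of each residue type is binned, each bin holds a Gaussian
# mixture over the chi angles, and sampling picks a component by weight and
# draws from its Gaussian.  Because the proposal equals the prior factor, the
# combined backbone + side-chain move accepts with exactly the backbone
# acceptance probability when the side-chains are clash-free, and zero
# otherwise; B-factor restraints are not applied to side-chain atoms.

#' Rotamer library
#'
#' @param table data frame with columns `residue`, `phi_lo`, `psi_lo`,
#'   `bin_width` (degrees), `weight`, then `chi<i>_mean` / `chi<i>_sd`
#'   (degrees, NA beyond the residue's chi count).  One row per mixture
#'   component per bin; weights must sum to 1 within each bin.
#' @export
new_rotamer_library <- function(table) {
  need <- c("residue", "phi_lo", "psi_lo", "bin_width", "weight")
  stopifnot(all(need %in% names(table)))
  chk <- stats::aggregate(table$weight,
                          by = list(table$residue, table$phi_lo, table$psi_lo),
                          FUN = sum)
  if (any(abs(chk$x - 1) > 1e-6)) stop("rotamer component weights must sum to 1 per bin")
  structure(list(table = table), class = "slik_rotamer_library")
}

# mixture components of the bin containing (phi, psi) for a residue type
rotamer_bin <- function(lib, residue, phi, psi) {
  t <- lib$table
  phi_d <- wrap_angle(phi) * 180 / pi
  psi_d <- wrap_angle(psi) * 180 / pi
  rows <- t$residue == residue &
    phi_d >= t$phi_lo & phi_d < t$phi_lo + t$bin_width &
    psi_d >= t$psi_lo & psi_d < t$psi_lo + t$bin_width
  out <- t[rows, , drop = FALSE]
  if (nrow(out) == 0) stop("no rotamer bin for ", residue, " at the given (phi, psi)")
  out
}

#' Sample side-chain torsions from the rotamer prior
#'
#' @param lib a [new_rotamer_library()].
#' @param residue residue type (e.g. `"ARG"`).
#' @param phi,psi backbone dihedrals (radians).
#' @return list with `chi` (radians, wrapped) and `component`.
#' @export
sample_rotamer_chi <- function(lib, residue, phi, psi) {
  comp <- rotamer_bin(lib, residue, phi, psi)
  k <- sample.int(nrow(comp), 1, prob = comp$weight)
  means <- as.numeric(comp[k, grep("^chi[0-9]+_mean$", names(comp))])
  sds <- as.numeric(comp[k, grep("^chi[0-9]+_sd$", names(comp))])
  keep <- !is.na(means)
  chi <- stats::rnorm(sum(keep), means[keep], sds[keep]) * pi / 180
  list(chi = wrap_angle(chi), component = k)
}

#' Density of the rotamer prior at given torsions
#' @inheritParams sample_rotamer_chi
#' @param chi torsions (radians).
#' @export
rotamer_chi_density <- function(lib, residue, phi, psi, chi) {
  comp <- rotamer_bin(lib, residue, phi, psi)
  means <- as.matrix(comp[, grep("^chi[0-9]+_mean$", names(comp)), drop = FALSE])
  sds <- as.matrix(comp[, grep("^chi[0-9]+_sd$", names(comp)), drop = FALSE])
  total <- 0
  for (k in seq_len(nrow(comp))) {
    keep <- !is.na(means[k, ])
    d <- prod(stats::dnorm(chi * 180 / pi, means[k, keep], sds[k, keep]))
    total <- total + comp$weight[k] * d
  }
  total
}

# Internal-coordinate side-chain templates: atom, reference atoms, bond
# length (A), bond angle (deg), and which chi (0 = fixed improper) sets the
# torsion.  Enough geometry for clash checking.
sidechain_templates <- function() {
  list(
    ALA = data.frame(atom = "CB", ref = I(list(c("C", "N", "CA"))),
                     len = 1.53, ang = 110.5, tors = 122.5, chi = 0L),
    ARG = data.frame(
      atom = c("CB", "CG", "CD", "NE", "CZ"),
      ref = I(list(c("C", "N", "CA"), c("N", "CA", "CB"), c("CA", "CB", "CG"),
                   c("CB", "CG", "CD"), c("CG", "CD", "NE"))),
      len = c(1.53, 1.52, 1.52, 1.46, 1.33),
      ang = c(110.5, 114.1, 111.3, 112.0, 124.2),
      tors = c(122.5, NA, NA, NA, NA),
      chi = c(0L, 1L, 2L, 3L, 4L))
  )
}

#' Build side-chain atoms for one residue
#'
#' @param residue residue type with a template (`"ALA"`, `"ARG"`).
#' @param N,CA,C backbone positions.
#' @param chi torsions (radians), one per rotatable chi of the type.
#' @return matrix of atom positions with atom names as rownames.
#' @export
build_sidechain_atoms <- function(residue, N, CA, C, chi = numeric(0)) {
  tpl <- sidechain_templates()[[residue]]
  if (is.null(tpl)) stop("no side-chain template for ", residue)
  placed <- list(N = N, CA = CA, C = C)
  out <- matrix(0, nrow(tpl), 3, dimnames = list(tpl$atom, NULL))
  for (k in seq_len(nrow(tpl))) {
    refs <- tpl$ref[[k]]
    tors <- if (tpl$chi[k] == 0L) tpl$tors[k] * pi / 180 else chi[tpl$chi[k]]
    p <- nerf_place(placed[[refs[1]]], placed[[refs[2]]], placed[[refs[3]]],
                    tpl$len[k], tpl$ang[k] * pi / 180, tors)
    placed[[tpl$atom[k]]] <- p
    out[k, ] <- p
  }
  out
}

#' Number of rotatable chi angles of a residue type
#' @param residue residue type.
#' @export
n_chi <- function(residue) {
  tpl <- sidechain_templates()[[residue]]
  if (is.null(tpl)) 0L else max(tpl$chi)
}

#' Sample side-chains for the residues of a block
#'
#' Draws each residue's chi from its backbone-dependent rotamer distribution,
#' builds the side-chain atoms, and rejects the whole set if any side-chain
#' atom clashes with the environment, the loop backbone, or another freshly
#' built side-chain (bonded neighbours excluded by a distance-1/2 rule on
#' the construction graph).
#'
#' @param chain loop chain with an atom table.
#' @param state current backbone state.
#' @param residues residue numbers to dress (default: all loop residues).
#' @param restypes named character vector: residue number -> type.
#' @param lib rotamer library.
#' @param env_grid clash grid over environment atoms (may be empty).
#' @param overlap clash overlap fraction.
#' @return list with `status` (`"ok"` or `"clash"`), `chi` (named list) and
#'   `atoms` (stacked side-chain positions).
#' @export
sample_sidechains <- function(chain, state, residues = NULL, restypes, lib,
                              env_grid = NULL, overlap = 0.75) {
  at <- chain$meta$atom_owners
  if (is.null(residues)) residues <- chain$meta$residues
  radii <- vdw_radii()
  chi_out <- list()
  sc_pos <- NULL
  sc_rad <- numeric(0)
  sc_res <- integer(0)
  dih <- state$angles
  for (r in residues) {
    rtype <- restypes[[as.character(r)]]
    if (is.null(rtype) || n_chi(rtype) == 0) next
    i <- 2L * match(r, chain$meta$residues) - 1L
    draw <- sample_rotamer_chi(lib, rtype, dih[i], dih[i + 1L])
    getp <- function(el) state$atoms[which(at$resno == r & at$elety == el), ]
    pos <- build_sidechain_atoms(rtype, getp("N"), getp("CA"), getp("C"), draw$chi)
    chi_out[[as.character(r)]] <- draw$chi
    sc_pos <- rbind(sc_pos, pos)
    sc_rad <- c(sc_rad, radii[element_of(rownames(pos))])
    sc_res <- c(sc_res, rep(r, nrow(pos)))
  }
  if (is.null(sc_pos)) return(list(status = "ok", chi = chi_out, atoms = NULL))
  # skip CB/CG vs own-backbone pairs (within two bonds of CA) and
  # neighbouring side-chain atoms along the same construction chain
  bb_rad <- radii[element_of(at$elety)]
  clash <- 0
  for (k in seq_len(nrow(sc_pos))) {
    nm <- rownames(sc_pos)[k]
    # vs environment
    if (!is.null(env_grid) && nrow(env_grid$positions)) {
      cand <- grid_neighbors(env_grid, sc_pos[k, ])
      for (j in cand) {
        lim <- overlap * (sc_rad[k] + env_grid$radii[j])
        if (sum((sc_pos[k, ] - env_grid$positions[j, ])^2) < lim^2) clash <- 1
      }
    }
    # vs loop backbone (own residue's N, CA, C excluded for CB; CA for CG)
    for (j in seq_len(nrow(at))) {
      if (at$resno[j] == sc_res[k] &&
          ((nm == "CB" && at$elety[j] %in% c("N", "CA", "C")) ||
           (nm == "CG" && at$elety[j] %in% c("CA", "CB")))) next
      lim <- overlap * (sc_rad[k] + bb_rad[j])
      if (sum((sc_pos[k, ] - state$atoms[j, ])^2) < lim^2) clash <- 1
    }
    # vs other side-chain atoms (adjacent atoms in the same residue excluded)
    if (k > 1) for (j in 1:(k - 1)) {
      if (sc_res[j] == sc_res[k] && abs(k - j) <= 2) next
      lim <- overlap * (sc_rad[k] + sc_rad[j])
      if (sum((sc_pos[k, ] - sc_pos[j, ])^2) < lim^2) clash <- 1
    }
    if (clash) break
  }
  if (clash) return(list(status = "clash", chi = chi_out, atoms = sc_pos))
  list(status = "ok", chi = chi_out, atoms = sc_pos)
}

#' Combined backbone + side-chain block move
#'
#' Runs the backbone block move; on acceptance, draws side-chains for the
#' block's residues from the rotamer prior and vetoes the whole move if they
#' clash.  In a clash-free environment the combined acceptance probability
#' therefore equals the backbone acceptance probability exactly.
#'
#' @inheritParams sample_block_mh
#' @inheritParams sample_sidechains
#' @return list with `state`, `step` (the backbone record, with
#'   `reason = "clash"` when vetoed by side-chains) and `chi`.
#' @export
sample_block_with_sidechains <- function(chain, state, i, fg, restypes, lib,
                                         prior = uniform_angle_prior(),
                                         cfg = sampler_config(),
                                         env_grid = NULL, overlap = 0.75) {
  bb <- sample_block_mh(chain, state, i, fg, prior, cfg)
  if (!bb$step$accepted) return(c(bb, list(chi = NULL)))
  res_lo <- chain$meta$angle_res[i]
  res_hi <- chain$meta$angle_res[min(i + cfg$b - 1L, chain$n_joints)]
  sc <- sample_sidechains(chain, bb$state, residues = res_lo:res_hi,
                          restypes = restypes, lib = lib,
                          env_grid = env_grid, overlap = overlap)
  if (sc$status == "clash") {
    step <- bb$step
    step$accepted <- FALSE
    step$reason <- "clash"
    return(list(state = state, step = step, chi = NULL))
  }
  list(state = bb$state, step = bb$step, chi = sc$chi)
}
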