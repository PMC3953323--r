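# Protein backbone kinematics.
#
# A loop of L residues is modelled as a chain of 2L revolute joints, the
# backbone dihedrals phi_1, psi_1, ..., phi_L, psi_L.  Bond lengths, bond
# angles and the omega torsion (180 degrees) are fixed; when a loop is
# extracted from a structure its native covalent geometry is kept exactly, so
# forward kinematics at the native dihedrals reproduces the native
# coordinates.  Each joint's frame sits on its rotatable bond (origin at the
# distal atom, z along the bond), and every backbone atom is rigidly owned by
# one frame, which keeps the factor graph sparse.

#' Ideal backbone geometry
#'
#' Bond lengths (Angstrom) and angles (degrees) used when building synthetic
#' backbones; all values can be overridden.  The omega dihedral is fixed at
#' 180 degrees (trans).
#' @param ... named overrides, e.g. `len_n_ca = 1.47`.
#' @export
ideal_backbone_geometry <- function(...) {
  g <- list(len_n_ca = 1.458, len_ca_c = 1.525, len_c_n = 1.329,
            len_c_o = 1.231,
            ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.5, omega = 180)
  over <- list(...)
  stopifnot(all(names(over) %in% names(g)))
  g[names(over)] <- over
  with(g, {
    if (any(c(len_n_ca, len_ca_c, len_c_n, len_c_o) <= 0)) stop("bond lengths must be positive")
    angs <- c(ang_n_ca_c, ang_ca_c_n, ang_c_n_ca, ang_ca_c_o)
    if (any(angs <= 0 | angs >= 180)) stop("bond angles must lie in (0, 180) degrees")
  })
  g
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three placed atoms `a, b, c`, returns the position `d` with bond
#' length `|cd| = len`, bond angle `b-c-d = theta` and dihedral
#' `(a, b, c, d) = chi`.
#' @param a,b,c length-3 positions.
#' @param len bond length (Angstrom).
#' @param theta bond angle (radians).
#' @param chi dihedral (radians).
#' @export
nerf_place <- function(a, b, c, len, theta, chi) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("collinear reference atoms in internal-coordinate placement")
  n <- n / nn
  m <- cross3(n, bc)
  d2 <- len * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  as.numeric(c + cbind(bc, m, n) %*% d2)
}

#' Build an ideal-geometry backbone from dihedrals
#'
#' Places N, CA, C, O atoms for `n_res` residues with the given `(phi, psi)`
#' dihedrals (radians) and trans peptide bonds.  `phi[1]` has no preceding
#' carbonyl and is ignored (the first residue is placed in a canonical
#' orientation).
#'
#' @param phi,psi dihedral vectors of length `n_res`, radians.
#' @param geom geometry list from [ideal_backbone_geometry()].
#' @return list with `xyz` (4*n_res x 3 matrix), `elety`, `resno` vectors.
#' @export
build_backbone <- function(phi, psi, geom = ideal_backbone_geometry()) {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res, n_res >= 1)
  d2r <- pi / 180
  N <- CA <- C <- O <- matrix(0, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(geom$len_n_ca, 0, 0)
  th <- geom$ang_n_ca_c * d2r
  C[1, ] <- CA[1, ] + geom$len_ca_c * c(-cos(th), sin(th), 0)
  for (r in seq_len(n_res)) {
    if (r < n_res) {
      N[r + 1, ] <- nerf_place(N[r, ], CA[r, ], C[r, ],
                               geom$len_c_n, geom$ang_ca_c_n * d2r, psi[r])
      CA[r + 1, ] <- nerf_place(CA[r, ], C[r, ], N[r + 1, ],
                                geom$len_n_ca, geom$ang_c_n_ca * d2r, geom$omega * d2r)
      C[r + 1, ] <- nerf_place(C[r, ], N[r + 1, ], CA[r + 1, ],
                               geom$len_ca_c, geom$ang_n_ca_c * d2r, phi[r + 1])
    }
    O[r, ] <- nerf_place(N[r, ], CA[r, ], C[r, ],
                         geom$len_c_o, geom$ang_ca_c_o * d2r, psi[r] + pi)
  }
  xyz <- matrix(0, 4 * n_res, 3)
  elety <- character(4 * n_res)
  resno <- integer(4 * n_res)
  for (r in seq_len(n_res)) {
    k <- (r - 1) * 4
    xyz[k + 1, ] <- N[r, ]; xyz[k + 2, ] <- CA[r, ]
    xyz[k + 3, ] <- C[r, ]; xyz[k + 4, ] <- O[r, ]
    elety[k + 1:4] <- c("N", "CA", "C", "O")
    resno[k + 1:4] <- r
  }
  list(xyz = xyz, elety = elety, resno = resno)
}

#' Measure backbone dihedrals from coordinates
#'
#' @param bb list as returned by [build_backbone()], or any list with `xyz`,
#'   `elety`, `resno` covering backbone atoms.
#' @return matrix with columns `phi`, `psi` (radians); `phi[1]` and
#'   `psi[last]` are `NA` (undefined without flanking residues).
#' @export
measure_backbone_dihedrals <- function(bb) {
  res <- sort(unique(bb$resno))
  get <- function(r, at) {
    k <- which(bb$resno == r & bb$elety == at)
    if (length(k) != 1) stop("missing backbone atom ", at, " in residue ", r)
    bb$xyz[k, ]
  }
  out <- matrix(NA_real_, length(res), 2, dimnames = list(res, c("phi", "psi")))
  for (i in seq_along(res)) {
    r <- res[i]
    if (i > 1) {
      out[i, 1] <- dihedral(get(res[i - 1], "C"), get(r, "N"), get(r, "CA"), get(r, "C"))
    }
    if (i < length(res)) {
      out[i, 2] <- dihedral(get(r, "N"), get(r, "CA"), get(r, "C"), get(res[i + 1], "N"))
    }
  }
  out
}

# Torsion of atom d about the bond frame F (see bond_frame): polar angle of
# d - origin in the frame's xy plane.  Matches dihedral(p, a, b, d).
frame_torsion <- function(F, d) {
  v <- d - F[1:3, 4]
  atan2(sum(v * F[1:3, 2]), sum(v * F[1:3, 1]))
}

#' Build the kinematic chain of a backbone loop
#'
#' Constructs the 2L-joint chain (phi/psi per residue) of loop residues
#' `start..end` from explicit backbone coordinates, keeping the native
#' covalent geometry.  Flanking atoms `C(start-1)` and `N(end+1)` must be
#' present: they define the fixed base frame and the closure goal frame.
#'
#' @param bb coordinate list (`xyz`, `elety`, `resno`, optional `b`
#'   B-factors) covering residues `start-1 .. end+1` at least.
#' @param start,end first and last loop residue numbers (inclusive).
#' @return list with `chain` (a `slik_chain` whose `meta` holds the atom
#'   table) and `state` (the native `slik_state`).
#' @export
backbone_loop_chain <- function(bb, start, end) {
  res <- start:end
  L <- length(res)
  stopifnot(L >= 1)
  get <- function(r, at) {
    k <- which(bb$resno == r & bb$elety == at)
    if (length(k) != 1) stop("residue ", r, " lacks backbone atom ", at)
    bb$xyz[k, ]
  }
  getb <- function(r, at) {
    k <- which(bb$resno == r & bb$elety == at)
    if (!is.null(bb$b) && length(k) == 1) bb$b[k] else NA_real_
  }
  n <- 2L * L
  pre <- vector("list", n)      # pre-torsion bond frames
  qn <- numeric(n)              # native dihedrals
  for (i in seq_len(L)) {
    r <- res[i]
    p_prev <- get(r - 1, "C")
    pre[[2 * i - 1]] <- bond_frame(p_prev, get(r, "N"), get(r, "CA"))
    qn[2 * i - 1] <- frame_torsion(pre[[2 * i - 1]], get(r, "C"))
    pre[[2 * i]] <- bond_frame(get(r, "N"), get(r, "CA"), get(r, "C"))
    qn[2 * i] <- frame_torsion(pre[[2 * i]], get(r + 1, "N"))
  }
  base <- pre[[1]]
  Tn <- vector("list", n)       # native joint frames
  rel <- array(0, dim = c(4, 4, n))
  prev <- base
  for (j in seq_len(n)) {
    Tn[[j]] <- pre[[j]] %*% tf_rot_z(qn[j])    # torsion acts about +z of the bond frame
    rel[, , j] <- tf_inverse(prev) %*% pre[[j]]
    prev <- Tn[[j]]
  }
  end_constraint <- Tn[[n]]
  # atom ownership: owner 0 is the fixed base frame
  atom_rows <- list()
  add_atom <- function(r, at, owner) {
    p <- get(r, at)
    To <- if (owner == 0) base else Tn[[owner]]
    loc <- as.numeric(tf_inverse(To) %*% c(p, 1))[1:3]
    atom_rows[[length(atom_rows) + 1]] <<- data.frame(
      resno = r, elety = at, owner = owner,
      lx = loc[1], ly = loc[2], lz = loc[3], b = getb(r, at),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(L)) {
    r <- res[i]
    add_atom(r, "N", if (i == 1) 0L else 2L * (i - 1))
    add_atom(r, "CA", 2L * i - 1L)
    add_atom(r, "C", 2L * i)
    if (any(bb$resno == r & bb$elety == "O")) add_atom(r, "O", 2L * i)
  }
  atoms <- do.call(rbind, atom_rows)
  axes <- matrix(rep(c(0, 0, 1), n), 3, n)   # torsion acts about +z of each bond frame
  chain <- new_chain(axes, rel, base = base, end_constraint = end_constraint,
                     meta = list(atom_owners = atoms, residues = res,
                                 angle_res = rep(res, each = 2),
                                 angle_kind = rep(c("phi", "psi"), L)))
  state <- new_state(chain, qn)
  list(chain = chain, state = state)
}

#' Backbone atom positions from frames
#'
#' Maps each owned atom through its owner frame; bond lengths and angles are
#' preserved exactly because ownership is rigid.
#' @param chain a loop chain from [backbone_loop_chain()].
#' @param frames 4 x 4 x (N+1) frame array.
#' @return numeric matrix (atoms x 3), rows aligned with
#'   `chain$meta$atom_owners`.
#' @export
backbone_to_atoms <- function(chain, frames) {
  at <- chain$meta$atom_owners
  if (is.null(at)) stop("chain carries no atom table")
  out <- matrix(0, nrow(at), 3)
  for (k in seq_len(nrow(at))) {
    To <- frames[, , at$owner[k] + 1]
    out[k, ] <- To[1:3, 1:3] %*% c(at$lx[k], at$ly[k], at$lz[k]) + To[1:3, 4]
  }
  out
}
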