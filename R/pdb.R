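# PDB input/output (via bio3d) and assembly of the protein factor graph.

#' Chemical element of a PDB atom name
#' @param elety atom name vector (e.g. `"CA"`, `"OD1"`).
#' @export
element_of <- function(elety) {
  first <- substr(gsub("[0-9']", "", toupper(elety)), 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, "C")
}

#' Load a loop from a PDB file
#'
#' Reads the structure, extracts the backbone of loop residues
#' `start..end` on the given chain plus the flanking residues that define
#' the anchors, and builds the kinematic loop chain anchored so that the
#' flanking frames act as the closure constraints.  B-factors are retained
#' per atom.  Alternate locations are resolved to the highest-occupancy
#' conformer; insertion codes in the loop range are rejected.
#'
#' @param pdb_path path to a PDB file.
#' @param loop_spec list with `chain`, `start`, `end` (author residue
#'   numbering, inclusive).
#' @return list with `chain` (the kinematic chain), `state` (native state),
#'   `pdb` (the bio3d object), `env` (fixed atoms: `xyz`, `elety`, `resno`),
#'   `moving_pdb_rows` (row indices of loop atoms in the pdb), `restypes`,
#'   and clash bookkeeping (`env_exclusions`, `self_exclusions`).
#' @export
load_state_from_pdb <- function(pdb_path, loop_spec) {
  stopifnot(all(c("chain", "start", "end") %in% names(loop_spec)))
  start <- loop_spec$start; end <- loop_spec$end
  stopifnot(start <= end)
  pdb <- bio3d::read.pdb(pdb_path)
  a <- pdb$atom
  a$row <- seq_len(nrow(a))
  a <- a[a$chain == loop_spec$chain & a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0) stop("chain ", loop_spec$chain, " not found in ", pdb_path)
  rng <- range(a$resno)
  if (start - 1 < rng[1] || end + 1 > rng[2]) {
    stop("loop ", start, "..", end, " (plus flanking residues) outside chain ",
         loop_spec$chain, " range ", rng[1], "..", rng[2])
  }
  sel <- a[a$resno >= start - 1 & a$resno <= end + 1, , drop = FALSE]
  if (any(nzchar(sel$insert) & !is.na(sel$insert))) {
    stop("insertion codes in the loop range are not supported")
  }
  # altLoc: keep the highest-occupancy conformer of each atom
  key <- paste(sel$resno, sel$elety)
  keep <- unlist(lapply(split(seq_len(nrow(sel)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    idx[which.max(sel$o[idx])]
  }))
  sel <- sel[sort(keep), , drop = FALSE]
  for (r in start:end) {
    for (at in c("N", "CA", "C")) {
      if (!any(sel$resno == r & sel$elety == at)) {
        stop("residue ", r, " is missing backbone atom ", at)
      }
    }
  }
  if (!any(sel$resno == start - 1 & sel$elety == "C")) {
    stop("flanking residue ", start - 1, " is missing atom C (needed for the anchor)")
  }
  if (!any(sel$resno == end + 1 & sel$elety == "N")) {
    stop("flanking residue ", end + 1, " is missing atom N (needed for the anchor)")
  }
  bb <- list(xyz = as.matrix(sel[, c("x", "y", "z")]), elety = sel$elety,
             resno = sel$resno, b = sel$b)
  lc <- backbone_loop_chain(bb, start, end)
  at <- lc$chain$meta$atom_owners
  moving_rows <- vapply(seq_len(nrow(at)), function(k) {
    sel$row[which(sel$resno == at$resno[k] & sel$elety == at$elety[k])]
  }, 0L)
  env_mask <- !(a$resno >= start & a$resno <= end &
                a$elety %in% c("N", "CA", "C", "O"))
  env <- a[env_mask, , drop = FALSE]
  env_bb <- list(xyz = as.matrix(env[, c("x", "y", "z")]), elety = env$elety,
                 resno = env$resno, row = env$row)
  restypes <- vapply(start:end, function(r) sel$resid[which(sel$resno == r)][1], "")
  names(restypes) <- start:end
  list(chain = lc$chain, state = lc$state, pdb = pdb,
       loop_spec = loop_spec, env = env_bb,
       moving_pdb_rows = moving_rows, restypes = restypes,
       exclusions = loop_clash_exclusions(at, env_bb, start, end))
}

# bonded (1-2 and 1-3) pair exclusions for clash checking: pairs among the
# moving loop atoms, and pairs between moving atoms and the flanking
# environment atoms across the two anchor bonds.
loop_clash_exclusions <- function(at, env, start, end) {
  n <- nrow(at)
  # bond list among moving atoms (indices into the atom table)
  idx <- function(r, el) {
    k <- which(at$resno == r & at$elety == el)
    if (length(k)) k else NA_integer_
  }
  bonds <- list()
  for (r in unique(at$resno)) {
    bonds <- c(bonds, list(c(idx(r, "N"), idx(r, "CA")), c(idx(r, "CA"), idx(r, "C")),
                           c(idx(r, "C"), idx(r, "O")), c(idx(r, "C"), idx(r + 1, "N"))))
  }
  B <- do.call(rbind, bonds)
  B <- B[stats::complete.cases(B), , drop = FALSE]
  adj <- lapply(seq_len(n), function(k) {
    unique(c(B[B[, 1] == k, 2], B[B[, 2] == k, 1]))
  })
  pairs <- list()
  for (k in seq_len(n)) {
    n1 <- adj[[k]]
    n2 <- unique(unlist(adj[n1]))
    for (j in unique(c(n1, n2))) if (j > k) pairs[[length(pairs) + 1]] <- c(k, j)
  }
  self <- if (length(pairs)) do.call(rbind, pairs) else matrix(0L, 0, 2)
  # across the anchors: moving atoms within two bonds of the fixed C(start-1)
  # and N(end+1)
  env_idx <- function(r, el) which(env$resno == r & env$elety == el)
  ep <- list()
  add_env <- function(mi, ei) {
    if (length(mi) == 1 && !is.na(mi) && length(ei) == 1) {
      ep[[length(ep) + 1]] <<- c(mi, ei)
    }
  }
  add_env(idx(start, "N"), env_idx(start - 1, "C"))     # 1-2
  add_env(idx(start, "CA"), env_idx(start - 1, "C"))    # 1-3
  add_env(idx(start, "N"), env_idx(start - 1, "CA"))    # 1-3
  add_env(idx(start, "N"), env_idx(start - 1, "O"))     # 1-3
  add_env(idx(end, "C"), env_idx(end + 1, "N"))         # 1-2
  add_env(idx(end, "C"), env_idx(end + 1, "CA"))        # 1-3
  add_env(idx(end, "CA"), env_idx(end + 1, "N"))        # 1-3
  add_env(idx(end, "O"), env_idx(end + 1, "N"))         # 1-3
  envp <- if (length(ep)) do.call(rbind, ep) else matrix(0L, 0, 2)
  list(self = self, env = envp)
}

#' Assemble the factor graph of a loaded protein loop
#'
#' Builds Ramachandran factors per loop residue, B-factor positional
#' restraints per moving backbone atom (centred at the native positions),
#' and a deferred steric-clash factor against the fixed environment.
#'
#' @param loaded result of [load_state_from_pdb()].
#' @param rama a `slik_rama_grid` (one grid for all residues) or a named
#'   list by residue number; `NULL` to omit.
#' @param priors character subset of `c("rama", "bfactor", "clash")`.
#' @param bfactor_scale confidence scale `c` of the B-factor Gaussians.
#' @param overlap clash overlap fraction.
#' @param radii named element radii.
#' @export
protein_factor_graph <- function(loaded, rama = NULL,
                                 priors = c("rama", "bfactor", "clash"),
                                 bfactor_scale = 1, overlap = 0.75,
                                 radii = vdw_radii()) {
  chain <- loaded$chain
  at <- chain$meta$atom_owners
  facs <- list()
  if ("rama" %in% priors && !is.null(rama)) {
    res <- chain$meta$residues
    for (i in seq_along(res)) {
      g <- if (inherits(rama, "slik_rama_grid")) rama else rama[[as.character(res[i])]]
      if (is.null(g)) next
      facs[[length(facs) + 1]] <- rama_prior_factor(g, 2L * i - 1L, 2L * i)
    }
  }
  if ("bfactor" %in% priors) {
    native <- backbone_to_atoms(chain, loaded$state$frames)
    for (k in seq_len(nrow(at))) {
      B <- at$b[k]
      if (is.na(B) || B <= 0) next
      facs[[length(facs) + 1]] <- bfactor_prior_factor(k, native[k, ], B, bfactor_scale)
    }
  }
  if ("clash" %in% priors) {
    env_r <- radii[element_of(loaded$env$elety)]
    grid <- clash_grid(loaded$env$xyz, env_r)
    mov_r <- radii[element_of(at$elety)]
    excl <- loaded$exclusions
    facs[[length(facs) + 1]] <- new_factor(
      "clash",
      function(ctx) {
        log(clash_factor(grid, ctx$atoms, mov_r, overlap = overlap,
                         self_exclusions = excl$self, env_exclusions = excl$env))
      },
      atoms = seq_len(nrow(at)),
      params = list(grid = grid, radii = mov_r, overlap = overlap))
  }
  factor_graph(facs)
}

#' Write a conformation ensemble as a multi-MODEL PDB
#'
#' Each sample becomes one MODEL holding the full structure with the loop
#' atoms replaced by that sample's coordinates.
#'
#' @param file output path.
#' @param loaded result of [load_state_from_pdb()].
#' @param ensemble a `slik_ensemble` over the loaded chain, or a list of
#'   angle vectors.
#' @param thin write only the thinned subsequence of the ensemble.
#' @return the file path, invisibly.
#' @export
write_ensemble_pdb <- function(file, loaded, ensemble, thin = FALSE) {
  rows <- if (inherits(ensemble, "slik_ensemble")) {
    idx <- if (thin) ensemble$thinned_idx else seq_len(nrow(ensemble$angles))
    lapply(idx, function(k) ensemble$angles[k, ])
  } else {
    ensemble
  }
  pdb <- loaded$pdb
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(rows)) {
    st <- new_state(loaded$chain, rows[[k]])
    xyz <- pdb$xyz
    for (j in seq_along(loaded$moving_pdb_rows)) {
      r <- loaded$moving_pdb_rows[j]
      xyz[(3 * r - 2):(3 * r)] <- st$atoms[j, ]
    }
    tmp <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(pdb, file = tmp, xyz = xyz, end = FALSE)
    lines <- readLines(tmp)
    unlink(tmp)
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
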