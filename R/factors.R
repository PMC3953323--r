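# Sparse factored scores.
#
# The target score is a product of non-negative local factors over small
# variable subsets (angles, frames, atom positions):
#   Phi(x) = prod_i phi_i(S_i).
# Because each variable appears in a bounded number of factors, the change in
# Phi when one block moves is the change in the factors touching that block,
# so block-restricted scores cost O(1) per move.  All evaluation is in log
# space; hard-constraint violations give -Inf.

#' Create a factor
#'
#' @param type factor type string (used by fast evaluation paths); one of
#'   `"rama"`, `"bfactor"`, `"clash"`, `"angle_gauss"`, `"angle_vm"`,
#'   `"pos_gauss"`, `"custom"`.
#' @param logf function(ctx) returning the log factor value; `ctx` has
#'   elements `q` (angles), `frames`, `atoms`, `chain`.
#' @param angles,frames,atoms integer ids of the variables in the factor's
#'   domain (frames are 0-based like `T_j`).
#' @param params named list of type-specific parameters.
#' @export
new_factor <- function(type, logf, angles = integer(0), frames = integer(0),
                       atoms = integer(0), params = list()) {
  structure(list(type = type, logf = logf, angles = as.integer(angles),
                 frames = as.integer(frames), atoms = as.integer(atoms),
                 params = params),
            class = "slik_factor")
}

#' Assemble a factor graph
#'
#' @param factors list of [new_factor()] objects.
#' @return object of class `slik_factor_graph` with an inverse index from
#'   variables to factors.
#' @export
factor_graph <- function(factors) {
  stopifnot(all(vapply(factors, inherits, TRUE, "slik_factor")))
  idx <- list(angles = list(), frames = list(), atoms = list())
  for (k in seq_along(factors)) {
    f <- factors[[k]]
    for (a in f$angles) {
      key <- as.character(a)
      idx$angles[[key]] <- c(idx$angles[[key]], k)
    }
    for (a in f$frames) {
      key <- as.character(a)
      idx$frames[[key]] <- c(idx$frames[[key]], k)
    }
    for (a in f$atoms) {
      key <- as.character(a)
      idx$atoms[[key]] <- c(idx$atoms[[key]], k)
    }
  }
  structure(list(factors = factors, index = idx), class = "slik_factor_graph")
}

#' @export
print.slik_factor_graph <- function(x, ...) {
  cat(sprintf("<slik_factor_graph> %d factors (%s)\n", length(x$factors),
              paste(names(table(vapply(x$factors, `[[`, "", "type"))), collapse = ", ")))
  invisible(x)
}

# ids of factors whose domain intersects the given variable sets
factors_touching <- function(fg, angles = integer(0), frames = integer(0),
                             atoms = integer(0)) {
  ids <- integer(0)
  for (a in angles) ids <- c(ids, fg$index$angles[[as.character(a)]])
  for (a in frames) ids <- c(ids, fg$index$frames[[as.character(a)]])
  for (a in atoms) ids <- c(ids, fg$index$atoms[[as.character(a)]])
  sort(unique(ids))
}

#' Block-restricted log score
#'
#' Log of the product of exactly those factors whose domain intersects the
#' block's variables.  For a block covering every variable this equals the
#' full log score.  Ratios of block scores between two states differing only
#' inside the block equal the ratios of the full scores, which is what the
#' acceptance probability needs.
#'
#' @param fg a `slik_factor_graph`.
#' @param ctx evaluation context: list with `q`, `frames`, `atoms`, `chain`.
#' @param angles,frames,atoms variable ids of the block.
#' @param skip_types factor types to leave out (the sampler defers clash
#'   factors until after the provisional acceptance decision).
#' @return log score (`-Inf` when a hard constraint is violated).
#' @export
block_score <- function(fg, ctx, angles = integer(0), frames = integer(0),
                        atoms = integer(0), skip_types = character(0)) {
  ids <- factors_touching(fg, angles, frames, atoms)
  total <- 0
  for (k in ids) {
    f <- fg$factors[[k]]
    if (f$type %in% skip_types) next
    v <- f$logf(ctx)
    if (!is.finite(v) && v < 0) return(-Inf)
    total <- total + v
  }
  total
}

#' Full log score of a state
#' @inheritParams block_score
#' @export
full_score <- function(fg, ctx, skip_types = character(0)) {
  total <- 0
  for (f in fg$factors) {
    if (f$type %in% skip_types) next
    v <- f$logf(ctx)
    if (!is.finite(v) && v < 0) return(-Inf)
    total <- total + v
  }
  total
}

#' Convert an energy to a score
#'
#' Gibbs measure: `Phi = exp(-E / T)`.
#' @param E energy.
#' @param T temperature, positive, same units.
#' @export
energy_to_score <- function(E, T) {
  stopifnot(T > 0)
  exp(-E / T)
}

#' Discretized Ramachandran probability grid
#'
#' A piecewise-constant density over `[-180, 180)^2` in (phi, psi), stored as
#' a matrix with phi bins as rows (first row starts at -180 degrees).
#'
#' @param values non-negative matrix (n_phi x n_psi).
#' @param interpolate use bilinear interpolation instead of the cellwise
#'   lookup (off by default; the tabulated libraries are binned).
#' @export
new_rama_grid <- function(values, interpolate = FALSE) {
  values <- as.matrix(values)
  stopifnot(all(values >= 0), nrow(values) >= 1, ncol(values) >= 1)
  structure(list(values = values, n_phi = nrow(values), n_psi = ncol(values),
                 interpolate = interpolate),
            class = "slik_rama_grid")
}

#' Ramachandran factor lookup
#'
#' Value of the grid cell containing `(phi, psi)`; angles outside
#' `[-180, 180)` are wrapped in.
#' @param grid a `slik_rama_grid`.
#' @param phi,psi angles in radians (vectors allowed).
#' @export
ramachandran_factor <- function(grid, phi, psi) {
  u <- (wrap_angle(phi) + pi) / (2 * pi)   # in [0, 1)
  v <- (wrap_angle(psi) + pi) / (2 * pi)
  if (!grid$interpolate) {
    i <- pmin(grid$n_phi, 1L + floor(u * grid$n_phi))
    j <- pmin(grid$n_psi, 1L + floor(v * grid$n_psi))
    return(grid$values[cbind(i, j)])
  }
  # bilinear on cell centres, periodic
  bil <- function(uu, vv) {
    fi <- uu * grid$n_phi - 0.5; fj <- vv * grid$n_psi - 0.5
    i0 <- floor(fi); j0 <- floor(fj)
    di <- fi - i0; dj <- fj - j0
    ii <- function(i) 1L + ((i %% grid$n_phi + grid$n_phi) %% grid$n_phi)
    jj <- function(j) 1L + ((j %% grid$n_psi + grid$n_psi) %% grid$n_psi)
    grid$values[ii(i0), jj(j0)] * (1 - di) * (1 - dj) +
      grid$values[ii(i0 + 1), jj(j0)] * di * (1 - dj) +
      grid$values[ii(i0), jj(j0 + 1)] * (1 - di) * dj +
      grid$values[ii(i0 + 1), jj(j0 + 1)] * di * dj
  }
  mapply(bil, u, v)
}

#' B-factor positional prior
#'
#' Gaussian restraint of an atom to its reference position, with variance set
#' by the crystallographic B-factor:
#' `phi_BF(p) = 1/(c sqrt(2 pi B)) exp(-|p - mu|^2 / (2 B c^2))`.
#' The scale `c` expresses confidence in the deposited B-factors (larger `c`
#' means weaker restraints).  The normalisation constant is one-dimensional
#' while the displacement is three-dimensional; as a density this is only
#' defined up to that constant, which cancels in all acceptance ratios.
#'
#' @param p atom position (length 3, Angstrom).
#' @param mu reference position.
#' @param B B-factor (Angstrom squared), positive.
#' @param c confidence scale, positive.
#' @param log return the log value.
#' @export
bfactor_factor <- function(p, mu, B, c = 1, log = FALSE) {
  if (any(B <= 0)) stop("B-factor must be positive")
  if (any(c <= 0)) stop("B-factor scale must be positive")
  lv <- -log(c) - 0.5 * log(2 * pi * B) - sum((p - mu)^2) / (2 * B * c^2)
  if (log) lv else exp(lv)
}

# --- convenience factor constructors -------------------------------------

#' Built-in factor constructors
#'
#' `rama_prior_factor`: Ramachandran prior on one residue's (phi, psi).
#' `bfactor_prior_factor`: B-factor Gaussian on one atom.
#' `angle_gauss_factor`: wrapped Gaussian prior on one joint angle.
#' `angle_vm_factor`: von Mises prior (unnormalized) on one joint angle.
#' `pos_gauss_factor`: isotropic Gaussian prior on one frame origin.
#'
#' @param grid a `slik_rama_grid`.
#' @param phi_idx,psi_idx angle ids of the residue's phi and psi.
#' @name builtin_factors
#' @export
rama_prior_factor <- function(grid, phi_idx, psi_idx) {
  force(grid); force(phi_idx); force(psi_idx)
  new_factor("rama",
             function(ctx) log(ramachandran_factor(grid, ctx$q[phi_idx], ctx$q[psi_idx])),
             angles = c(phi_idx, psi_idx),
             params = list(grid = grid, phi_idx = phi_idx, psi_idx = psi_idx))
}

#' @rdname builtin_factors
#' @param atom_idx row of the atom in the state's atom matrix.
#' @param mu,B,c see [bfactor_factor()].
#' @export
bfactor_prior_factor <- function(atom_idx, mu, B, c = 1) {
  force(atom_idx); force(mu); force(B); force(c)
  new_factor("bfactor",
             function(ctx) bfactor_factor(ctx$atoms[atom_idx, ], mu, B, c, log = TRUE),
             atoms = atom_idx,
             params = list(atom_idx = atom_idx, mu = mu, B = B, c = c))
}

#' @rdname builtin_factors
#' @param idx joint angle id.
#' @param mean,sd Gaussian parameters (radians).
#' @export
angle_gauss_factor <- function(idx, mean, sd) {
  force(idx); force(mean); force(sd)
  new_factor("angle_gauss",
             function(ctx) -wrap_angle(ctx$q[idx] - mean)^2 / (2 * sd^2),
             angles = idx, params = list(idx = idx, mean = mean, sd = sd))
}

#' @rdname builtin_factors
#' @param kappa von Mises concentration.
#' @export
angle_vm_factor <- function(idx, mean, kappa) {
  force(idx); force(mean); force(kappa)
  new_factor("angle_vm",
             function(ctx) kappa * cos(ctx$q[idx] - mean),
             angles = idx, params = list(idx = idx, mean = mean, kappa = kappa))
}

#' @rdname builtin_factors
#' @param frame_idx frame id (0-based, `T_j`).
#' @param centre prior mean of the frame origin (length 2 for planar chains).
#' @export
pos_gauss_factor <- function(frame_idx, centre, sd) {
  force(frame_idx); force(centre); force(sd)
  nd <- length(centre)
  new_factor("pos_gauss",
             function(ctx) {
               p <- ctx$frames[seq_len(nd), 4, frame_idx + 1]
               -sum((p - centre)^2) / (2 * sd^2)
             },
             frames = frame_idx,
             params = list(frame_idx = frame_idx, centre = centre, sd = sd))
}
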