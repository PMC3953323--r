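# Steric clash detection with a spatial hash grid.
#
# The clash factor is binary: 0 if any non-excluded atom pair overlaps
# (distance below the overlap fraction times the sum of van der Waals radii),
# 1 otherwise.  Checking all pairs is quadratic, so fixed environment atoms
# are hashed into a cubic grid whose cell edge is at least the largest pair
# radius sum: a query then only inspects the 27 neighbouring cells, and the
# grid answer is identical to the exhaustive check.

#' Default van der Waals radii (Angstrom) by element
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

#' Build a clash grid over fixed atoms
#'
#' @param positions n x 3 matrix of environment atom positions.
#' @param radii per-atom radii (recycled).
#' @param cell cell edge; defaults to twice the largest radius (the largest
#'   possible pair radius sum), never smaller.
#' @export
clash_grid <- function(positions, radii, cell = NULL) {
  positions <- as.matrix(positions)
  radii <- rep_len(radii, nrow(positions))
  r_max <- if (length(radii)) max(radii) else 1
  if (is.null(cell)) cell <- 2 * r_max
  cell <- max(cell, 2 * r_max)
  ht <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(positions)) {
    keys <- apply(floor(t(positions) / cell), 2, paste, collapse = " ")
    for (k in seq_along(keys)) {
      ht[[keys[k]]] <- c(ht[[keys[k]]], k)
    }
  }
  structure(list(ht = ht, cell = cell, positions = positions, radii = radii,
                 r_max = r_max),
            class = "slik_clash_grid")
}

# candidate environment atoms near p (superset of all atoms within r_max+query radius)
grid_neighbors <- function(grid, p) {
  base <- floor(p / grid$cell)
  out <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    key <- paste(base + c(dx, dy, dz), collapse = " ")
    hit <- grid$ht[[key]]
    if (!is.null(hit)) out <- c(out, hit)
  }
  out
}

#' Binary clash factor
#'
#' Checks the moving atoms against the grid's environment atoms and against
#' each other.  Pairs listed in `exclusions` (bonded 1-2 and 1-3 pairs) are
#' skipped.
#'
#' @param grid a [clash_grid()] over the fixed environment (may hold zero
#'   atoms).
#' @param positions m x 3 matrix of moving atom positions.
#' @param radii moving atom radii (recycled).
#' @param overlap overlap tolerance fraction applied to the radius sum
#'   (default 0.75; a pair clashes when closer than
#'   `overlap * (r_i + r_j)`).
#' @param self_exclusions 2-column matrix of index pairs among the moving
#'   atoms to skip.
#' @param env_exclusions 2-column matrix of (moving index, environment index)
#'   pairs to skip.
#' @return 1 if clash-free, 0 otherwise.
#' @export
clash_factor <- function(grid, positions, radii, overlap = 0.75,
                         self_exclusions = NULL, env_exclusions = NULL) {
  positions <- as.matrix(positions)
  m <- nrow(positions)
  radii <- rep_len(radii, m)
  skip_self <- pair_key_set(self_exclusions)
  skip_env <- pair_key_set(env_exclusions, ordered = TRUE)
  # moving vs environment
  if (nrow(grid$positions)) {
    for (k in seq_len(m)) {
      cand <- grid_neighbors(grid, positions[k, ])
      for (j in cand) {
        if (!is.null(skip_env) && pair_in(skip_env, k, j, ordered = TRUE)) next
        lim <- overlap * (radii[k] + grid$radii[j])
        if (sum((positions[k, ] - grid$positions[j, ])^2) < lim^2) return(0)
      }
    }
  }
  # moving vs moving
  if (m > 1) {
    for (k in 1:(m - 1)) for (j in (k + 1):m) {
      if (!is.null(skip_self) && pair_in(skip_self, k, j)) next
      lim <- overlap * (radii[k] + radii[j])
      if (sum((positions[k, ] - positions[j, ])^2) < lim^2) return(0)
    }
  }
  1
}

pair_key_set <- function(pairs, ordered = FALSE) {
  if (is.null(pairs) || nrow(pairs) == 0) return(NULL)
  a <- pairs[, 1]; b <- pairs[, 2]
  if (!ordered) {
    lo <- pmin(a, b); hi <- pmax(a, b); a <- lo; b <- hi
  }
  e <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(a)) e[[paste(a[k], b[k])]] <- TRUE
  e
}

pair_in <- function(set, i, j, ordered = FALSE) {
  if (!ordered && i > j) { tmp <- i; i <- j; j <- tmp }
  !is.null(set[[paste(i, j)]])
}

# Exhaustive all-pairs clash check; reference implementation used to verify
# the grid path.
clash_factor_naive <- function(env_positions, env_radii, positions, radii,
                               overlap = 0.75, self_exclusions = NULL,
                               env_exclusions = NULL) {
  positions <- as.matrix(positions)
  m <- nrow(positions)
  radii <- rep_len(radii, m)
  skip_self <- pair_key_set(self_exclusions)
  skip_env <- pair_key_set(env_exclusions, ordered = TRUE)
  if (!is.null(env_positions) && nrow(env_positions)) {
    env_radii <- rep_len(env_radii, nrow(env_positions))
    for (k in seq_len(m)) for (j in seq_len(nrow(env_positions))) {
      if (!is.null(skip_env) && pair_in(skip_env, k, j, ordered = TRUE)) next
      lim <- overlap * (radii[k] + env_radii[j])
      if (sum((positions[k, ] - env_positions[j, ])^2) < lim^2) return(0)
    }
  }
  if (m > 1) {
    for (k in 1:(m - 1)) for (j in (k + 1):m) {
      if (!is.null(skip_self) && pair_in(skip_self, k, j)) next
      lim <- overlap * (radii[k] + radii[j])
      if (sum((positions[k, ] - positions[j, ])^2) < lim^2) return(0)
    }
  }
  1
}
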