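# Proposal priors for the independent angles of a block.
#
# The block proposal draws the independent angles y from a prior density
# P(y); because P(y) enters the proposal density Q explicitly, any choice
# with full support leaves the stationary distribution unchanged -- it only
# affects mixing speed.  Uniform is the default; protein runs can draw each
# phi/psi from its Ramachandran marginal.

# A proposal prior is a list with two functions:
#   sample(idx, ref)          draw one angle per index; `ref` holds the
#                             current values of those angles, so random-walk
#                             kernels are expressible
#   logdens(values, idx, ref) summed log proposal density; for the forward
#                             move `ref` is the current state, for the
#                             reverse move it is the candidate
# Priors that ignore `ref` are ordinary independence samplers.

#' Uniform proposal prior over angles
#'
#' @return a prior object (see the commentary in this file): `sample(idx,
#'   ref)` draws uniformly on `[-pi, pi)`, `logdens` is constant.
#' @export
uniform_angle_prior <- function() {
  list(sample = function(idx, ref = NULL) stats::runif(length(idx), -pi, pi),
       logdens = function(values, idx, ref = NULL) 0)
}

#' Degenerate (Dirac) proposal prior
#'
#' Always proposes the stored angles; useful to verify identity behaviour of
#' the block sampler.
#' @param values named by angle index, or a full angle vector.
#' @export
dirac_angle_prior <- function(values) {
  list(sample = function(idx, ref = NULL) values[idx],
       logdens = function(v, idx, ref = NULL) 0)
}

#' Von Mises proposal prior
#'
#' Density proportional to `exp(kappa * cos(theta - mean))`, sampled with the
#' Best-Fisher rejection algorithm.
#' @param mean,kappa circular mean (radians) and concentration.
#' @export
vonmises_angle_prior <- function(mean = 0, kappa = 1) {
  list(sample = function(idx, ref = NULL) wrap_angle(mean + rvonmises(length(idx), kappa)),
       logdens = function(values, idx, ref = NULL) sum(kappa * cos(values - mean)))
}

#' Local (random-walk) proposal prior
#'
#' Wrapped-Gaussian steps around the current angles.  The proposal density is
#' conditioned on the move's starting point, which the acceptance ratio
#' accounts for by evaluating the reverse density at the candidate.  Backbone
#' blocks have narrow closure workspaces, so small local steps keep the
#' closure success rate usable; combine with a global component via
#' [rama_local_mixture_prior()] to retain basin hopping.
#' @param sd step standard deviation (radians).
#' @export
local_angle_prior <- function(sd = 5 * pi / 180) {
  list(sample = function(idx, ref) wrap_angle(ref + stats::rnorm(length(idx), 0, sd)),
       logdens = function(values, idx, ref) {
         sum(-wrap_angle(values - ref)^2 / (2 * sd^2)) -
           length(idx) * log(sd * sqrt(2 * pi))
       })
}

# Best & Fisher (1979) von Mises sampler, centred at 0.
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (k in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[k] <- sign(u[3] - 0.5) * acos(max(-1, min(1, f)))
        break
      }
    }
  }
  out
}

#' Proposal prior drawing each angle from a per-angle binned density
#'
#' Used to propose protein phi/psi from the marginals of per-residue
#' Ramachandran grids.  Bins cover `[-pi, pi)` uniformly.
#'
#' @param tables named list (by angle index as character) of non-negative
#'   bin-weight vectors; indices without a table fall back to uniform.
#' @export
binned_angle_prior <- function(tables) {
  dens <- lapply(tables, function(w) {
    w <- w / sum(w)
    n <- length(w)
    list(p = w, d = w * n / (2 * pi), cum = cumsum(w), n = n)
  })
  sample1 <- function(id) {
    t <- dens[[id]]
    if (is.null(t)) return(stats::runif(1, -pi, pi))
    k <- findInterval(stats::runif(1), t$cum) + 1L
    k <- min(k, t$n)
    -pi + (k - 1 + stats::runif(1)) * 2 * pi / t$n
  }
  dens1 <- function(v, id) {
    t <- dens[[id]]
    if (is.null(t)) return(1 / (2 * pi))
    k <- min(t$n, 1L + floor((wrap_angle(v) + pi) / (2 * pi) * t$n))
    t$d[k]
  }
  list(sample = function(idx, ref = NULL) vapply(as.character(idx), sample1, 0),
       logdens = function(values, idx, ref = NULL) {
         sum(log(mapply(dens1, values, as.character(idx))))
       },
       dens1 = dens1)
}

#' Ramachandran-marginal proposal prior for a backbone loop chain
#'
#' Builds a [binned_angle_prior()] whose table for each phi (psi) angle is
#' the phi (psi) marginal of that residue's Ramachandran grid.
#' @param chain a loop chain from [backbone_loop_chain()].
#' @param grids either a single `slik_rama_grid` used for all residues or a
#'   named list by residue number.
#' @export
rama_marginal_prior <- function(chain, grids) {
  kind <- chain$meta$angle_kind
  res <- chain$meta$angle_res
  tabs <- list()
  for (j in seq_along(kind)) {
    g <- if (inherits(grids, "slik_rama_grid")) grids else grids[[as.character(res[j])]]
    if (is.null(g)) next
    tabs[[as.character(j)]] <- if (kind[j] == "phi") rowSums(g$values) else colSums(g$values)
  }
  binned_angle_prior(tabs)
}

#' Mixture of Ramachandran-marginal and local proposals
#'
#' With probability `w_local` each independent angle takes a small
#' wrapped-Gaussian step from its current value, otherwise it is redrawn
#' globally from its Ramachandran marginal.  The mixture density (needed in
#' the acceptance ratio) is evaluated per angle.  This keeps the closure
#' success rate of backbone blocks usable while still allowing basin
#' changes.
#'
#' @inheritParams rama_marginal_prior
#' @param sd local step standard deviation (radians).
#' @param w_local mixture weight of the local component.
#' @export
rama_local_mixture_prior <- function(chain, grids, sd = 5 * pi / 180,
                                     w_local = 0.7) {
  stopifnot(w_local > 0, w_local < 1)
  glob <- rama_marginal_prior(chain, grids)
  nc <- 1 / (sd * sqrt(2 * pi))
  list(sample = function(idx, ref) {
    loc <- stats::runif(length(idx)) < w_local
    out <- numeric(length(idx))
    if (any(loc)) out[loc] <- wrap_angle(ref[loc] + stats::rnorm(sum(loc), 0, sd))
    if (any(!loc)) out[!loc] <- glob$sample(idx[!loc])
    out
  },
  logdens = function(values, idx, ref) {
    d_loc <- nc * exp(-wrap_angle(values - ref)^2 / (2 * sd^2))
    d_glob <- mapply(glob$dens1, values, as.character(idx))
    sum(log(w_local * d_loc + (1 - w_local) * d_glob))
  })
}
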