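# Plain-text formats for prior tables and planar chain descriptions.

#' Read / write a Ramachandran grid
#'
#' Tab-separated columns `phi_lo`, `psi_lo`, `value` (degrees, density per
#' square radian), one row per cell, preceded by a comment header line
#' `# bin_width: <degrees>`.
#' @param path file path.
#' @export
read_rama_grid <- function(path) {
  hdr <- readLines(path, n = 1)
  bw <- as.numeric(sub("^#\\s*bin_width:\\s*", "", hdr))
  if (!is.finite(bw) || bw <= 0) stop("missing '# bin_width:' header in ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  n_phi <- as.integer(round(360 / bw))
  lo <- seq(-180, 180 - bw, by = bw)
  v <- matrix(0, n_phi, n_phi)
  i <- match(d$phi_lo, lo); j <- match(d$psi_lo, lo)
  if (any(is.na(i)) || any(is.na(j))) stop("grid cells do not tile [-180,180) at the stated bin width")
  v[cbind(i, j)] <- d$value
  new_rama_grid(v)
}

#' @rdname read_rama_grid
#' @param grid a `slik_rama_grid`.
#' @export
write_rama_grid <- function(grid, path) {
  bw <- 360 / grid$n_phi
  lo <- seq(-180, 180 - bw, by = bw)
  d <- expand.grid(phi_lo = lo, psi_lo = lo)
  d$value <- grid$values[cbind(match(d$phi_lo, lo), match(d$psi_lo, lo))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width: %g", bw), con)
  utils::write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a rotamer library table
#'
#' Tab-separated with columns `residue`, `phi_lo`, `psi_lo`, `bin_width`,
#' `weight`, `chi<i>_mean`, `chi<i>_sd` (angles in degrees).  This is also
#' the target layout for converting published backbone-dependent rotamer
#' libraries: one row per (residue, bin, rotamer), with the rotamer's
#' probability as `weight` and its chi means/sigmas in the chi columns.
#' @param path file path.
#' @export
read_rotamer_library <- function(path) {
  new_rotamer_library(utils::read.table(path, header = TRUE, sep = "\t",
                                        stringsAsFactors = FALSE))
}

#' @rdname read_rotamer_library
#' @param lib a `slik_rotamer_library`.
#' @export
write_rotamer_library <- function(lib, path) {
  utils::write.table(lib$table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an element radii table
#'
#' Tab-separated columns `element`, `radius` (Angstrom).
#' @param path file path.
#' @export
read_radii <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(d$radius, d$element)
}

#' @rdname read_radii
#' @param radii named numeric vector.
#' @export
write_radii <- function(radii, path) {
  utils::write.table(data.frame(element = names(radii), radius = radii),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a planar chain description
#'
#' YAML with keys `link_lengths`, `base_frame` (x, y, theta in degrees),
#' optional `end_frame`, and optional `priors` (`angle_gauss`:
#' mean/sd degrees; `position_gauss`: list of frame/centre/sd).
#' @param path file path.
#' @return list with `chain`, `state` (straight or arc initialisation) and
#'   `fg`.
#' @export
read_planar_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$link_lengths), !is.null(cfg$base_frame))
  d2r <- pi / 180
  base <- as.numeric(cfg$base_frame); base[3] <- base[3] * d2r
  end <- if (!is.null(cfg$end_frame)) {
    e <- as.numeric(cfg$end_frame); e[3] <- e[3] * d2r; e
  }
  chain <- planar_chain(as.numeric(cfg$link_lengths), base = base, end = end)
  facs <- list()
  if (!is.null(cfg$priors$angle_gauss)) {
    p <- cfg$priors$angle_gauss
    for (j in seq_len(chain$n_joints)) {
      facs[[length(facs) + 1]] <- angle_gauss_factor(j, p$mean * d2r, p$sd * d2r)
    }
  }
  if (!is.null(cfg$priors$position_gauss)) {
    for (p in cfg$priors$position_gauss) {
      facs[[length(facs) + 1]] <- pos_gauss_factor(p$frame, as.numeric(p$centre), p$sd)
    }
  }
  state <- if (is.null(end)) new_state(chain, rep(0, chain$n_joints)) else {
    init_closed_planar_state(chain)
  }
  list(chain = chain, state = state, fg = factor_graph(facs))
}

# find a valid closed conformation of a planar chain by damped Gauss-Newton
# from a gentle arc
init_closed_planar_state <- function(chain, tries = 25L) {
  n <- chain$n_joints
  end <- tf_to_planar(chain$end_constraint)
  base <- tf_to_planar(chain$base)
  resfun <- function(q) planar_closure_error(fk_planar(chain$lengths, q, base), end)
  for (t in seq_len(tries)) {
    q0 <- if (t == 1) rep(0.1, n) else stats::runif(n, -pi / 2, pi / 2)
    q <- gauss_newton_generic(resfun, q0, tol = 1e-11)
    if (!is.null(q)) return(new_state(chain, wrap_angle(q)))
  }
  stop("could not find a closed initial conformation")
}

#' @rdname read_planar_config
#' @param chain a planar `slik_chain`.
#' @param fg optional factor graph of recognised planar factor types.
#' @export
write_planar_config <- function(chain, path, fg = NULL) {
  r2d <- 180 / pi
  base <- tf_to_planar(chain$base)
  out <- list(link_lengths = as.numeric(chain$lengths),
              base_frame = c(base[1], base[2], base[3] * r2d))
  if (!is.null(chain$end_constraint)) {
    e <- tf_to_planar(chain$end_constraint)
    out$end_frame <- c(e[1], e[2], e[3] * r2d)
  }
  if (!is.null(fg)) {
    pr <- list()
    for (f in fg$factors) {
      if (f$type == "angle_gauss" && is.null(pr$angle_gauss)) {
        pr$angle_gauss <- list(mean = f$params$mean * r2d, sd = f$params$sd * r2d)
      } else if (f$type == "pos_gauss") {
        pr$position_gauss <- c(pr$position_gauss,
                               list(list(frame = f$params$frame_idx,
                                         centre = as.numeric(f$params$centre),
                                         sd = f$params$sd)))
      }
    }
    if (length(pr)) out$priors <- pr
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
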