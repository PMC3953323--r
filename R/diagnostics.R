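# Mixing assessment and ensemble summaries.

#' Autocorrelation of a (possibly circular) series
#'
#' Standard normalized autocovariance.  For angle series the circular
#' variant embeds the series as the sine of the deviation from the circular
#' mean, which is wrap-safe; lag 0 is exactly 1.  A constant series has no
#' scale, so its autocorrelation is defined as 0 beyond lag 0 (with a
#' warning).
#'
#' @param x numeric series (radians when `circular`).
#' @param max_lag largest lag; must be below `length(x)`.
#' @param circular treat as angles.
#' @return numeric vector of autocorrelations at lags `0..max_lag`.
#' @export
autocorrelation <- function(x, max_lag = min(100L, length(x) - 1L),
                            circular = FALSE) {
  stopifnot(length(x) > max_lag)
  if (circular) {
    mu <- circular_mean(x)
    x <- sin(wrap_angle(x - mu))
  }
  if (stats::sd(x) == 0) {
    warning("constant series: autocorrelation set to 0 beyond lag 0")
    return(c(1, rep(0, max_lag)))
  }
  out <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
  out[1] <- 1
  out
}

#' Circular mean of angles
#' @param x angles in radians.
#' @export
circular_mean <- function(x) atan2(mean(sin(x)), mean(cos(x)))

#' Mixing report for an angle trajectory
#'
#' Computes per-angle circular autocorrelation curves and recommends the
#' smallest skip (thinning stride) at which the mean absolute autocorrelation
#' over all angle series falls below the quasi-independence threshold.
#'
#' @param angles samples x n matrix of angles (radians), or a
#'   `slik_ensemble`.
#' @param threshold quasi-independence threshold (default 0.2).
#' @param max_lag largest lag examined.
#' @return object of class `slik_mixing_report`: `acf` ((max_lag+1) x n
#'   matrix), `skip` (recommended stride; `NA` if never below threshold),
#'   `threshold`, and the ensemble acceptance rate when available.
#' @export
mixing_report <- function(angles, threshold = 0.2,
                          max_lag = NULL) {
  acc <- NA_real_
  if (inherits(angles, "slik_ensemble")) {
    acc <- angles$acceptance_rate
    angles <- angles$angles
  }
  if (is.null(max_lag)) max_lag <- min(200L, nrow(angles) %/% 3L)
  A <- vapply(seq_len(ncol(angles)),
              function(j) suppressWarnings(
                autocorrelation(angles[, j], max_lag, circular = TRUE)),
              numeric(max_lag + 1L))
  crit <- rowMeans(abs(A))
  below <- which(crit[-1] < threshold)
  skip <- if (length(below)) below[1] else NA_integer_
  structure(list(acf = A, mean_abs = crit, skip = skip, threshold = threshold,
                 acceptance_rate = acc),
            class = "slik_mixing_report")
}

#' @export
print.slik_mixing_report <- function(x, ...) {
  cat(sprintf("<slik_mixing_report> %d series, threshold %.2f, recommended skip %s\n",
              ncol(x$acf), x$threshold,
              if (is.na(x$skip)) "not reached" else x$skip))
  invisible(x)
}

#' Root-mean-square deviation between coordinate sets
#'
#' Computed in the common fixed frame by default (loop anchors are shared, so
#' no superposition is involved); optionally Kabsch-superposed for free
#' chains.
#'
#' @param a,b n x 3 coordinate matrices with matched rows.
#' @param select optional row indices.
#' @param superpose least-squares superpose `b` onto `a` first.
#' @return RMSD in the coordinate units (Angstrom).
#' @export
rmsd <- function(a, b, select = NULL, superpose = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  if (!is.null(select)) { a <- a[select, , drop = FALSE]; b <- b[select, , drop = FALSE] }
  if (superpose) b <- kabsch_superpose(b, a)
  sqrt(mean(rowSums((a - b)^2)))
}

# least-squares superposition of P onto Q (returns transformed P)
kabsch_superpose <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P0 %*% t(R), 2, cq, "+")
}

#' Per-angle circular statistics of an ensemble
#'
#' Circular mean and mean absolute circular deviation for each angle series,
#' plus the pooled average deviation.  The deviation reference is either each
#' series' own circular mean or a supplied reference conformation (e.g. the
#' native structure).
#'
#' @param angles samples x n matrix (radians) or a `slik_ensemble`.
#' @param reference `"mean"`, or a length-n numeric vector of reference
#'   angles (radians).
#' @param degrees report in degrees.
#' @return list with `mean`, `deviation` (per angle) and `average_deviation`
#'   (pooled).
#' @export
dihedral_statistics <- function(angles, reference = "mean", degrees = TRUE) {
  if (inherits(angles, "slik_ensemble")) angles <- angles$angles
  n <- ncol(angles)
  mu <- apply(angles, 2, circular_mean)
  ref <- if (identical(reference, "mean")) mu else {
    stopifnot(length(reference) == n)
    reference
  }
  dev <- vapply(seq_len(n),
                function(j) mean(abs(wrap_angle(angles[, j] - ref[j]))), 0)
  k <- if (degrees) 180 / pi else 1
  list(mean = mu * k, deviation = dev * k, average_deviation = mean(dev) * k)
}

#' Two-sample energy-distance test
#'
#' Permutation test of the hypothesis that two multivariate samples come
#' from the same distribution, based on the energy statistic
#' `2 E|X-Y| - E|X-X'| - E|Y-Y'|`.  Used to compare sampler output against a
#' reference (e.g. rejection-sampling) ensemble.
#'
#' @param x,y matrices with observations in rows.
#' @param n_perm number of label permutations.
#' @return list with `statistic` and `p.value`
#'   (`(1 + #{perm >= obs}) / (n_perm + 1)`).
#' @export
energy_distance_test <- function(x, y, n_perm = 199L) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x); m <- nrow(y)
  D <- as.matrix(stats::dist(rbind(x, y)))
  estat <- function(ia) {
    ib <- setdiff(seq_len(n + m), ia)
    2 * mean(D[ia, ib]) - mean(D[ia, ia]) - mean(D[ib, ib])
  }
  obs <- estat(seq_len(n))
  cnt <- 0L
  for (k in seq_len(n_perm)) {
    if (estat(sample.int(n + m, n)) >= obs) cnt <- cnt + 1L
  }
  list(statistic = obs * n * m / (n + m), p.value = (1 + cnt) / (n_perm + 1))
}
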