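# Factors, factor graphs and clash detection.

test_that("Ramachandran lookup is a piecewise-constant cell lookup", {
  g_unif <- new_rama_grid(matrix(1 / (2 * pi)^2, 36, 36))
  set.seed(21)
  phis <- runif(50, -10, 10); psis <- runif(50, -10, 10)
  expect_true(all(ramachandran_factor(g_unif, phis, psis) == 1 / (2 * pi)^2))

  v <- matrix(runif(36 * 36), 36, 36)
  g <- new_rama_grid(v)
  # naive double-loop oracle over bin edges in degrees
  naive <- function(phi, psi) {
    pd <- (phi * 180 / pi + 180) %% 360 - 180
    sd <- (psi * 180 / pi + 180) %% 360 - 180
    for (i in 1:36) for (j in 1:36) {
      if (pd >= -180 + (i - 1) * 10 && pd < -180 + i * 10 &&
          sd >= -180 + (j - 1) * 10 && sd < -180 + j * 10) return(v[i, j])
    }
    NA
  }
  for (k in 1:100) {
    phi <- runif(1, -4 * pi, 4 * pi); psi <- runif(1, -4 * pi, 4 * pi)
    expect_identical(ramachandran_factor(g, phi, psi), naive(phi, psi))
  }
  # a zero-probability cell scores 0, which forces rejection downstream
  v0 <- v; v0[5, 7] <- 0
  g0 <- new_rama_grid(v0)
  phi0 <- (-180 + 4.5 * 10) * pi / 180
  psi0 <- (-180 + 6.5 * 10) * pi / 180
  expect_identical(ramachandran_factor(g0, phi0, psi0), 0)
})

test_that("the B-factor factor equals its closed form", {
  expect_equal(bfactor_factor(c(0, 0, 0), c(0, 0, 0), B = 1, c = 1),
               1 / sqrt(2 * pi), tolerance = 1e-12)
  # at displacement c*sqrt(B) the value is exp(-1/2) of the peak
  p <- c(sqrt(2.5) * 1.3, 0, 0)
  expect_equal(bfactor_factor(p, c(0, 0, 0), B = 2.5, c = 1.3) /
                 bfactor_factor(c(0, 0, 0), c(0, 0, 0), B = 2.5, c = 1.3),
               exp(-0.5), tolerance = 1e-12)
  # scaling B by 10 widens the positional spread by sqrt(10): equal relative
  # height at sqrt(10)-scaled displacement
  d1 <- bfactor_factor(c(1, 0, 0), rep(0, 3), B = 1) / bfactor_factor(rep(0, 3), rep(0, 3), B = 1)
  d2 <- bfactor_factor(c(sqrt(10), 0, 0), rep(0, 3), B = 10) / bfactor_factor(rep(0, 3), rep(0, 3), B = 10)
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_error(bfactor_factor(p, p, B = -1), "positive")
})

test_that("energy-to-score conversion is the Gibbs measure", {
  expect_identical(energy_to_score(0, 1), 1)
  expect_equal(energy_to_score(2.2, 2.2), exp(-1), tolerance = 1e-14)
  E <- sort(runif(10, -5, 5))
  s <- energy_to_score(E, 0.7)
  expect_true(all(diff(s) < 0))
  expect_error(energy_to_score(1, 0), "T > 0")
})

test_that("grid-hashed clash detection matches the all-pairs oracle", {
  set.seed(22)
  for (rep in 1:50) {
    n_env <- 300; n_mov <- 12
    env <- matrix(runif(3 * n_env, 0, 12), ncol = 3)
    mov <- matrix(runif(3 * n_mov, 0, 12), ncol = 3)
    r_env <- runif(n_env, 0.8, 1.6)
    r_mov <- runif(n_mov, 0.8, 1.6)
    excl <- cbind(sample.int(n_mov, 3), sample.int(n_env, 3))
    grid <- clash_grid(env, r_env)
    expect_identical(
      clash_factor(grid, mov, r_mov, overlap = 0.75, env_exclusions = excl),
      clash_factor_naive(env, r_env, mov, r_mov, overlap = 0.75,
                         env_exclusions = excl))
  }
})

test_that("clash factor is binary with the documented overlap rule", {
  g <- clash_grid(matrix(numeric(0), 0, 3), numeric(0))
  two <- rbind(c(0, 0, 0), c(3.5, 0, 0))
  expect_identical(clash_factor(g, two, c(1.7, 1.7)), 1)
  expect_identical(clash_factor(g, rbind(c(0, 0, 0), c(0, 0, 0)), c(1.7, 1.7)), 0)
  # bonded pairs are excluded
  expect_identical(clash_factor(g, rbind(c(0, 0, 0), c(0, 0, 0)), c(1.7, 1.7),
                                self_exclusions = rbind(c(1L, 2L))), 1)
  # boundary: distance just below overlap * radius sum clashes
  d <- 0.75 * (1.7 + 1.7)
  expect_identical(clash_factor(g, rbind(c(0, 0, 0), c(d - 1e-9, 0, 0)), 1.7), 0)
  expect_identical(clash_factor(g, rbind(c(0, 0, 0), c(d + 1e-9, 0, 0)), 1.7), 1)
})

test_that("block scores multiply exactly the factors touching the block", {
  set.seed(23)
  n <- 8
  facs <- c(lapply(1:n, function(j) angle_gauss_factor(j, 0.1 * j, 0.5)),
            lapply(0:n, function(j) pos_gauss_factor(j, c(j, 0), 1.5)))
  fg <- factor_graph(facs)
  fx <- make_planar_chain(n, anchor_dist = 4)
  st <- fx$state
  ctx <- list(q = st$angles, frames = st$frames, atoms = NULL, chain = fx$chain)
  # a block touching no factor domains scores 1 (log 0)
  expect_identical(block_score(fg, ctx, integer(0), integer(0), integer(0)), 0)
  # the full-chain block equals the naive full product
  naive <- sum(vapply(facs, function(f) f$logf(ctx), 0))
  expect_equal(block_score(fg, ctx, 1:n, 0:n), naive, tolerance = 1e-12)
  expect_equal(full_score(fg, ctx), naive, tolerance = 1e-12)
  # block-score ratios equal full-score ratios when only block variables move
  i <- 3; b <- 4
  q2 <- st$angles
  q2[i:(i + b - 1)] <- q2[i:(i + b - 1)] + 0.1
  st2 <- new_state(fx$chain, q2)
  ctx2 <- list(q = st2$angles, frames = st2$frames, atoms = NULL, chain = fx$chain)
  va <- i:(i + b - 1); vf <- i:(i + b - 2)
  # frames beyond the block moved too (no closure enforced here), so compare
  # on a state where only block-interior frames differ
  st3 <- st
  st3$angles <- q2
  st3$frames[, , (i + 1):(i + b - 1)] <- st2$frames[, , (i + 1):(i + b - 1)]
  ctx3 <- list(q = st3$angles, frames = st3$frames, atoms = NULL, chain = fx$chain)
  expect_equal(block_score(fg, ctx3, va, vf) - block_score(fg, ctx, va, vf),
               full_score(fg, ctx3) - full_score(fg, ctx), tolerance = 1e-12)
})

test_that("factor graph index is the exact inverse of factor domains", {
  facs <- list(angle_gauss_factor(2, 0, 1), pos_gauss_factor(3, c(0, 0), 1),
               angle_gauss_factor(5, 0, 1))
  fg <- factor_graph(facs)
  for (k in seq_along(facs)) {
    for (a in facs[[k]]$angles) expect_true(k %in% fg$index$angles[[as.character(a)]])
    for (a in facs[[k]]$frames) expect_true(k %in% fg$index$frames[[as.character(a)]])
  }
  expect_identical(slikmc:::factors_touching(fg, angles = 2L), 1L)
  expect_identical(slikmc:::factors_touching(fg, angles = 4L), integer(0))
})

test_that("bilinear Ramachandran interpolation is exact at centres and bounded", {
  set.seed(24)
  v <- matrix(runif(18 * 18), 18, 18)
  g0 <- new_rama_grid(v)
  g1 <- new_rama_grid(v, interpolate = TRUE)
  bw <- 2 * pi / 18
  centres <- -pi + (seq_len(18) - 0.5) * bw
  for (t in 1:25) {
    i <- sample.int(18, 1); j <- sample.int(18, 1)
    expect_equal(ramachandran_factor(g1, centres[i], centres[j]), v[i, j],
                 tolerance = 1e-12)
  }
  # between centres the value stays within the neighbouring cell range
  for (t in 1:25) {
    phi <- runif(1, -pi, pi); psi <- runif(1, -pi, pi)
    val <- ramachandran_factor(g1, phi, psi)
    expect_gte(val, min(v)); expect_lte(val, max(v))
  }
  # piecewise-constant lookup is unaffected by the flag
  expect_identical(ramachandran_factor(g0, 0.3, -0.5),
                   ramachandran_factor(new_rama_grid(v, FALSE), 0.3, -0.5))
})
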