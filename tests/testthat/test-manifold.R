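# Chart geometry: constraint Jacobians, implicit chart Jacobian, metric
# tensor, proposal density and the change-of-variables utilities.

# planar closure residual of a block as an explicit function of its angles,
# for finite-difference checks
planar_block_residual <- function(chain, state, i, b) {
  anchor_s <- tf_to_planar(state$frames[, , i])
  anchor_e <- if (i + b - 1 == chain$n_joints) tf_to_planar(chain$end_constraint)
              else tf_to_planar(state$frames[, , i + b])
  L <- chain$lengths[i:(i + b - 1)]
  function(qb) {
    p <- fk_planar(L, qb, anchor_s)
    e <- p[, b + 1] - anchor_e
    e[3] <- wrap_angle(e[3])
    e
  }
}

test_that("constraint Jacobians match central differences on random states", {
  set.seed(51)
  # planar blocks
  fx <- make_planar_chain(9, anchor_dist = 4.5)
  st <- fx$state
  for (i in c(1, 3, 6)) {
    b <- 4
    J <- constraint_jacobian_full(fx$chain, st$frames, i, b)
    f <- planar_block_residual(fx$chain, st, i, b)
    Jfd <- fd_jac(f, st$angles[i:(i + b - 1)], eps = 1e-6)
    expect_lt(max(abs(J - Jfd)), 1e-5)
    expect_true(all(J[3, ] == 1))  # planar orientation row is all ones
  }
  # spatial blocks
  for (rep in 1:5) {
    ch <- rand_chain(8, closed = TRUE)
    st <- new_state(ch, attr(ch$end_constraint, "q_close"))
    J <- constraint_jacobian_full(ch, st$frames, 1, 8)
    f <- function(q) {
      fr <- forward_kinematics(ch, q)
      frame_error(fr[, , 9], ch$end_constraint)
    }
    Jfd <- fd_jac(f, st$angles, eps = 1e-6)
    expect_lt(max(abs(J - Jfd)), 1e-5)
  }
  # repeated evaluation is deterministic
  J1 <- constraint_jacobian_full(fx$chain, fx$state$frames, 2, 4)
  expect_identical(J1, constraint_jacobian_full(fx$chain, fx$state$frames, 2, 4))
})

test_that("the implicit chart Jacobian predicts the re-solved IK branch", {
  set.seed(52)
  fx <- make_planar_chain(7, anchor_dist = 3.2)
  st <- fx$state
  i <- 1; b <- 5; m <- 2
  cj <- constraint_jacobians(fx$chain, st$frames, i, b)
  icj <- implicit_chart_jacobian(cj$Cy, cj$Cz)
  expect_false(icj$singular)
  # perturb y, re-solve the same branch, compare dz to the prediction
  L <- fx$chain$lengths
  anchor_s <- tf_to_planar(st$frames[, , i])
  anchor_e <- tf_to_planar(st$frames[, , i + b])
  y0 <- st$angles[i:(i + m - 1)]
  z0 <- st$angles[(i + m):(i + b - 1)]
  solve_branch <- function(y) {
    T_in <- fk_planar(L[i:(i + m - 1)], y, anchor_s)[, m + 1]
    sol <- solve_planar(T_in, anchor_e, L[(i + m):(i + b - 1)])
    d <- apply(sol$solutions, 1, function(z) max(abs(wrap_angle(z - z0))))
    sol$solutions[which.min(d), ]
  }
  eps <- 1e-5
  for (j in 1:m) {
    e <- numeric(m); e[j] <- eps
    dz <- wrap_angle(solve_branch(y0 + e) - solve_branch(y0 - e)) / (2 * eps)
    expect_lt(max(abs(dz - icj$dzdy[, j])), 1e-4)
  }
  # degenerate m = 0 split gives an empty matrix
  cj0 <- constraint_jacobians(fx$chain, st$frames, 2, 3)
  icj0 <- implicit_chart_jacobian(cj0$Cy, cj0$Cz)
  expect_identical(dim(icj0$dzdy), c(3L, 0L))
})

test_that("four-bar coupler sensitivity matches the closed-form derivation", {
  # planar 4-angle block: y = q1, z = (q2, q3, q4).  Closure gives three
  # scalar equations; differentiating the loop equations symbolically:
  #   sum_k L_k exp(i theta_{k-1}) = p_e  with theta_k = theta_0 + q_1 + ... + q_k
  # yields dz/dy by solving the 3x3 linear system below (independent path).
  set.seed(53)
  fx <- make_planar_chain(4, anchor_dist = 2.1)
  st <- fx$state
  cj <- constraint_jacobians(fx$chain, st$frames, 1, 4)
  icj <- implicit_chart_jacobian(cj$Cy, cj$Cz)
  L <- fx$chain$lengths
  th0 <- tf_to_planar(fx$chain$base)[3]
  th <- th0 + cumsum(st$angles)          # theta_1..theta_4
  dirs <- th0 + c(0, th[1:3])            # link directions theta_0..theta_3
  # d p_e / d q_j = i * sum_{k >= j} L_{k+1} exp(i theta_k), j = 1..3 affect links j+1..4
  dp <- function(j) {
    idx <- (j + 1):4
    v <- colSums(cbind(-L[idx] * sin(dirs[idx]), L[idx] * cos(dirs[idx])))
    v
  }
  A <- cbind(c(dp(2), 1), c(dp(3), 1), c(0, 0, 1))   # columns: dq2, dq3, dq4
  rhs <- -c(dp(1), 1)
  dz_closed <- solve(A, rhs)
  expect_lt(max(abs(icj$dzdy[, 1] - dz_closed)), 1e-9)
})

test_that("the chart Jacobian has an identity top block and finite-difference frame rows", {
  set.seed(54)
  fx <- make_planar_chain(6, anchor_dist = 2.8)
  st <- fx$state
  i <- 1; b <- 6; m <- 3
  cj <- constraint_jacobians(fx$chain, st$frames, i, b)
  icj <- implicit_chart_jacobian(cj$Cy, cj$Cz)
  ch <- chart_jacobian(fx$chain, st$frames, i, b, icj$dzdy)
  expect_identical(ch$J[seq_len(m), ], diag(m))
  # frame-origin rows against re-solved perturbed states
  L <- fx$chain$lengths
  base2d <- tf_to_planar(fx$chain$base)
  z0 <- st$angles[(m + 1):b]
  full_map <- function(y) {
    T_in <- fk_planar(L[1:m], y, base2d)[, m + 1]
    sol <- solve_planar(T_in, tf_to_planar(fx$chain$end_constraint), L[(m + 1):b])
    d <- apply(sol$solutions, 1, function(z) max(abs(wrap_angle(z - z0))))
    z <- sol$solutions[which.min(d), ]
    p <- fk_planar(L, c(y, z), base2d)
    as.numeric(p[1:2, 2:b])              # origins of T_1..T_{b-1}
  }
  Jfd <- fd_jac(full_map, st$angles[1:m], eps = 1e-6)
  pos_rows <- ch$J[ch$w == 1, ][-(1:b), , drop = FALSE]  # frame position rows
  # rows interleave (x, y) per frame in both constructions
  expect_lt(max(abs(pos_rows - Jfd)), 1e-4)
  # with zero frame weights G collapses to the angle-space metric
  G0 <- metric_tensor(ch$J, ifelse(ch$w > 0 & seq_along(ch$w) <= b, 1, 0))
  expect_equal(G0, diag(m) + crossprod(icj$dzdy), tolerance = 1e-12)
})

test_that("proposal densities follow Q = P / (s sqrt(det G))", {
  # linear chart f(y) = 2y doubles arc length: Q = P / 2
  G <- matrix(4, 1, 1)
  expect_equal(proposal_density(0.5, 1, G), 0.25, tolerance = 1e-14)
  # isometric chart leaves the density unchanged
  expect_equal(proposal_density(0.37, 1, diag(2)), 0.37, tolerance = 1e-14)
  # s branches divide the density
  expect_equal(proposal_density(0.37, 4, diag(2)), 0.37 / 4, tolerance = 1e-14)
  expect_error(proposal_density(0.5, 1, matrix(0, 1, 1)), "singular")
})

test_that("block proposals are distributed as Q over the solution manifold", {
  # planar 4-angle fixed-endpoint block: 1-D manifold charted by q1 per IK
  # branch.  Bin the proposals by arc length along the manifold (computed
  # with the analytic metric) and compare the bin masses with the integral
  # of Q = P / (s sqrt(det G)) over each arc-length bin.
  set.seed(55)
  fx <- make_planar_chain(4, anchor_dist = 2.1)
  chain <- fx$chain; st <- fx$state
  L <- chain$lengths
  base2d <- tf_to_planar(chain$base); end2d <- tf_to_planar(chain$end_constraint)
  chart_at <- function(y, branch) {
    T_in <- fk_planar(L[1], y, base2d)[, 2]
    sol <- solve_planar(T_in, end2d, L[2:4])
    if (sol$count == 0) return(NULL)
    k <- which(sign(sol$solutions[, 2]) == branch)
    if (!length(k)) return(NULL)
    q <- c(y, sol$solutions[k[1], ])
    stq <- new_state(chain, q)
    cj <- constraint_jacobians(chain, stq$frames, 1, 4)
    icj <- implicit_chart_jacobian(cj$Cy, cj$Cz)
    if (icj$singular) return(NULL)
    ch <- chart_jacobian(chain, stq$frames, 1, 4, icj$dzdy)
    list(sqrtG = sqrt(det(metric_tensor(ch$J, ch$w))), s = sol$count)
  }
  n_grid <- 1200
  ys <- seq(-pi, pi, length.out = n_grid + 1)[-1]
  dy <- 2 * pi / n_grid
  n_draw <- 30000
  got <- matrix(NA_real_, n_draw, 2)     # q1 and branch sign of z2
  for (t in seq_len(n_draw)) {
    cand <- sample_block(chain, st, 1, 4)
    if (cand$status == "ok") got[t, ] <- c(cand$angles[1], sign(cand$angles[3]))
  }
  got <- got[!is.na(got[, 1]), , drop = FALSE]
  for (branch in c(-1, 1)) {
    info <- lapply(ys, chart_at, branch = branch)
    ok <- !vapply(info, is.null, TRUE)
    y_sup <- ys[ok]
    sqrtG <- vapply(info[ok], `[[`, 0, "sqrtG")
    s <- vapply(info[ok], `[[`, 0, "s")
    ell <- cumsum(sqrtG * dy)            # arc length along the branch
    total <- ell[length(ell)]
    brk <- seq(0, total, length.out = 17)
    # expected mass per arc bin: integral of Q dl = sum P(y)/s dy over cells
    cell_mass <- (1 / (2 * pi)) / s * dy
    cell_bin <- findInterval(ell, brk, rightmost.closed = TRUE)
    expected <- tapply(cell_mass, factor(cell_bin, levels = 1:16), sum)
    expected[is.na(expected)] <- 0
    # observed: map each draw's y to its arc coordinate
    draws <- got[got[, 2] == branch, 1]
    dl <- ell[pmax(1, findInterval(draws, y_sup - dy / 2))]
    obs <- table(factor(findInterval(dl, brk, rightmost.closed = TRUE), levels = 1:16))
    keep <- expected > 0
    ch2 <- suppressWarnings(chisq.test(as.numeric(obs[keep]),
                                       p = expected[keep] / sum(expected[keep])))
    expect_gt(ch2$p.value, 0.01)
  }
})

test_that("pushforward densities transform with the Gram determinant", {
  set.seed(56)
  # rigid rotations preserve densities
  R <- rand_rotation()
  g <- function(u) exp(-sum(u^2) / 2) / (2 * pi)^(3 / 2)
  u0 <- rnorm(3)
  expect_equal(density_pushforward(g, function(u) as.numeric(R %*% u), u0),
               g(u0), tolerance = 1e-6)
  # unit-speed circle: uniform density 1/(2pi), line integral 1
  gu <- function(u) 1 / (2 * pi)
  f <- function(u) c(cos(u[1]), sin(u[1]))
  expect_equal(density_pushforward(gu, f, 0.7), 1 / (2 * pi), tolerance = 1e-8)
  # Monte-Carlo surface integral of g_v over f(U) equals the integral of g_u
  f2 <- function(u) c(u[1], u[2], 0.3 * sin(u[1]) * cos(2 * u[2]))
  gu2 <- function(u) dnorm(u[1], 0.2, 0.4) * dnorm(u[2], -0.1, 0.5)
  n_mc <- 20000
  U <- cbind(runif(n_mc, -1.5, 1.5), runif(n_mc, -1.5, 1.5))
  area <- 3 * 3
  vals <- vapply(seq_len(n_mc), function(k) {
    u <- U[k, ]
    J <- fd_jac(f2, u)
    density_pushforward(gu2, f2, u) * parallelotope_volume(J)
  }, 0)
  lhs <- mean(vals) * area               # integral of g_v over the surface
  rhs <- mean(vapply(seq_len(n_mc), function(k) gu2(U[k, ]), 0)) * area
  expect_lt(abs(lhs - rhs), 0.02)
  expect_error(density_pushforward(gu, function(u) c(0, 0), 0.5), "rank")
})

test_that("parallelotope volumes equal Gram determinants", {
  expect_equal(parallelotope_volume(cbind(c(1, 0, 0), c(0, 1, 0))), 1)
  expect_equal(parallelotope_volume(cbind(c(3, 4))), 5)
  set.seed(57)
  for (rep in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    v_cross <- sqrt(sum(slikmc:::cross3(a, b)^2))
    expect_equal(parallelotope_volume(cbind(a, b)), v_cross, tolerance = 1e-10)
  }
  expect_equal(parallelotope_volume(cbind(c(1, 2, 3), c(2, 4, 6))), 0, tolerance = 1e-8)
})

test_that("manifold dimensions follow the angle-count-minus-constraints rule", {
  set.seed(58)
  # spatial: b = 7 -> 1, b = 6 -> 0, b = 8 -> 2
  for (b in 6:8) {
    ch <- rand_chain(b, closed = TRUE)
    st <- new_state(ch, attr(ch$end_constraint, "q_close"))
    expect_identical(as.integer(manifold_dimension(ch, st$frames)),
                     as.integer(b - 6))
  }
  # planar: b = 4 -> 1, b = 3 -> 0
  fx4 <- make_planar_chain(4, anchor_dist = 2.2)
  expect_identical(as.integer(manifold_dimension(fx4$chain, fx4$state$frames)), 1L)
  fx5 <- make_planar_chain(5, anchor_dist = 2.4)
  expect_identical(as.integer(manifold_dimension(fx5$chain, fx5$state$frames, 2, 3)), 0L)
})

test_that("the weighted volume element is invariant to the chart labelling", {
  # the same planar 4-angle block charted by q1 (the implementation's
  # labelling) or by q2 (an alternative labelling, realised here through a
  # finite-difference chart): sqrt(det G) transforms with the chart-change
  # derivative, so Q times the volume element is chart-invariant.
  set.seed(59)
  fx <- make_planar_chain(4, anchor_dist = 2.1)
  chain <- fx$chain; st <- fx$state
  L <- chain$lengths
  base2d <- tf_to_planar(chain$base); end2d <- tf_to_planar(chain$end_constraint)
  cj <- constraint_jacobians(chain, st$frames, 1, 4)
  icj <- implicit_chart_jacobian(cj$Cy, cj$Cz)
  ch <- chart_jacobian(chain, st$frames, 1, 4, icj$dzdy)
  sqrtG1 <- sqrt(det(metric_tensor(ch$J, ch$w)))
  # chart 2: parameter q2; solve (q1, q3, q4) from closure near the current
  # state and assemble the same weighted coordinates (angles + frame origins)
  resfun <- function(v, q2) {
    q <- c(v[1], q2, v[2], v[3])
    p <- fk_planar(L, q, base2d)
    e <- p[, 5] - end2d
    e[3] <- wrap_angle(e[3])
    e
  }
  chart2 <- function(q2) {
    v <- slikmc:::gauss_newton_generic(function(v) resfun(v, q2),
                                       st$angles[c(1, 3, 4)], tol = 1e-12)
    q <- c(v[1], q2, v[2], v[3])
    p <- fk_planar(L, q, base2d)
    c(q, as.numeric(p[1:2, 2:4]))        # angles + origins of T_1..T_3
  }
  J2 <- fd_jac(chart2, st$angles[2], eps = 1e-7)
  sqrtG2 <- parallelotope_volume(J2)
  # chart-change derivative dq2/dq1 from the implementation's chart
  dq2_dq1 <- abs(icj$dzdy[1, 1])
  expect_equal(sqrtG2 * dq2_dq1, sqrtG1, tolerance = 1e-5)
})
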