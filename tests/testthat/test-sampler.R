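# The MH block sampler, Gibbs sweeps, free-endpoint moves and full runs.

test_that("acceptance records satisfy the MH identity and are 1 under uniform score", {
  set.seed(61)
  fx <- make_planar_chain(8, anchor_dist = 4)
  cfg <- sampler_config(b = 4L)
  st <- fx$state
  n_seen <- 0
  for (t in 1:60) {
    res <- sample_block_mh(fx$chain, st, sample(1:5, 1), fx$fg, cfg = cfg)
    s <- res$step
    if (s$reason %in% c("ik_failure", "singular")) next
    n_seen <- n_seen + 1
    # uniform score, uniform prior: alpha = min(1, (s_f sqrt(G_f)) / (s_r sqrt(G_r)))
    expect_equal(s$alpha,
                 min(1, exp(log(s$s_fwd / s$s_rev) +
                              0.5 * (s$logdetG_fwd - s$logdetG_rev))),
                 tolerance = 1e-9)
    expect_gte(s$alpha, 0); expect_lte(s$alpha, 1)
    st <- res$state
  }
  expect_gt(n_seen, 10)
  # free-endpoint blocks with uniform score accept every move
  fxf <- make_planar_chain(8, closed = FALSE)
  for (t in 1:10) {
    res <- sample_free_endpoint_block(fxf$chain, fxf$state, 5, fxf$fg, cfg)
    expect_identical(res$step$alpha, 1)
    expect_true(res$step$accepted)
  }
})

test_that("clashing candidates are rejected with identical semantics in both clash orders", {
  set.seed(62)
  mp <- make_mini_protein(n_res = 10, loop_start = 3, loop_end = 8)
  loaded <- load_state_from_pdb(mp$path, mp$loop_spec)
  grid <- make_toy_rama_grid()
  fg <- protein_factor_graph(loaded, grid, priors = c("rama", "clash"))
  prior <- local_angle_prior(4 * pi / 180)
  run_once <- function(defer, seed) {
    cfg <- sampler_config(b = 8L, n_samples = 8L, seed = seed, defer_clash = defer,
                          ik = list(max_seeds = 48L))
    run_sampler(loaded$chain, loaded$state, fg, cfg, prior)
  }
  e1 <- run_once(TRUE, 5)
  e2 <- run_once(FALSE, 5)
  # deferred clash evaluation changes cost, not outcomes
  expect_identical(e1$angles, e2$angles)
  expect_identical(e1$acceptance_rate, e2$acceptance_rate)
  # an always-clashing factor forces zero acceptance with reason "clash"
  always_clash <- new_factor("clash", function(ctx) -Inf,
                             atoms = seq_len(nrow(loaded$chain$meta$atom_owners)))
  fg_bad <- factor_graph(c(fg$factors[-length(fg$factors)], list(always_clash)))
  cfg <- sampler_config(b = 8L, n_samples = 5L, seed = 9, ik = list(max_seeds = 32L))
  e3 <- run_sampler(loaded$chain, loaded$state, fg_bad, cfg, prior)
  expect_identical(e3$acceptance_rate, 0)
  expect_identical(unname(e3$angles[6, ]), loaded$state$angles)
  expect_gt(e3$reasons[["clash"]], 0)
})

test_that("sweeps visit the documented overlapping blocks", {
  # 7-residue loop -> 4 blocks of 4 residues at stride 1
  set.seed(63)
  bb <- build_backbone(runif(9, -pi, 0), runif(9, -pi, pi))
  lc <- backbone_loop_chain(bb, 2, 8)
  plan <- slikmc:::block_plan(lc$chain, sampler_config(b = 8L))
  expect_identical(plan$i, c(1L, 3L, 5L, 7L))
  expect_identical(unique(plan$type), "closure")
  # 4-residue loop -> exactly one block
  lc4 <- backbone_loop_chain(bb, 3, 6)
  expect_identical(nrow(slikmc:::block_plan(lc4$chain, sampler_config(b = 8L))), 1L)
  # planar 20-link closed chain, b = 4 -> 17 blocks
  fx <- make_planar_chain(20, anchor_dist = 10)
  expect_identical(nrow(slikmc:::block_plan(fx$chain, sampler_config(b = 4L))), 17L)
  # free planar chain: terminal block is sampled without closure
  fxf <- make_planar_chain(10, closed = FALSE)
  planf <- slikmc:::block_plan(fxf$chain, sampler_config(b = 4L))
  expect_identical(planf$type[nrow(planf)], "free")
})

test_that("block ordering does not change the stationary distribution", {
  fx <- make_planar_chain(8, anchor_dist = 3.5,
                          angle_prior = list(mean = 0.3, sd = 0.8))
  run_order <- function(sweep, seed) {
    cfg <- sampler_config(b = 4L, n_samples = 20000L, skip = 100L, seed = seed,
                          sweep = sweep)
    e <- run_sampler(fx$chain, fx$state, fx$fg, cfg)
    e$angles[e$thinned_idx[-(1:10)], ]
  }
  a <- run_order("forward", 3)
  b <- run_order("random", 4)
  et <- energy_distance_test(embed_angles(a[seq(1, nrow(a), 2), ]),
                             embed_angles(b[seq(1, nrow(b), 2), ]), n_perm = 99)
  expect_gt(et$p.value, 0.01)
})

test_that("runs are deterministic given the seed and honour n_samples = 0", {
  fx <- make_planar_chain(12, anchor_dist = 6)
  cfg <- sampler_config(b = 4L, n_samples = 40L, seed = 123L)
  e1 <- run_sampler(fx$chain, fx$state, fx$fg, cfg)
  e2 <- run_sampler(fx$chain, fx$state, fx$fg, cfg)
  expect_identical(e1$angles, e2$angles)
  cfg0 <- sampler_config(b = 4L, n_samples = 0L, seed = 1L)
  e0 <- run_sampler(fx$chain, fx$state, fx$fg, cfg0)
  expect_identical(nrow(e0$angles), 1L)
  expect_identical(unname(e0$angles[1, ]), fx$state$angles)
})

test_that("every emitted planar conformation satisfies closure", {
  fx <- make_planar_chain(10, anchor_dist = 5)
  cfg <- sampler_config(b = 4L, n_samples = 200L, seed = 8L)
  e <- run_sampler(fx$chain, fx$state, fx$fg, cfg)
  end2d <- tf_to_planar(fx$chain$end_constraint)
  for (k in seq(1, 201, by = 20)) {
    p <- fk_planar(fx$chain$lengths, e$angles[k, ], tf_to_planar(fx$chain$base))
    expect_lt(max(abs(slikmc:::planar_closure_error(p, end2d))), 1e-8)
  }
  expect_true(validate_state(fx$chain, e$final_state))
})

test_that("zero perturbation width freezes free-endpoint blocks", {
  fx <- make_planar_chain(6, closed = FALSE)
  cfg <- sampler_config(b = 4L, sigma_free = 0)
  set.seed(64)
  res <- sample_free_endpoint_block(fx$chain, fx$state, 3, fx$fg, cfg)
  expect_identical(res$state$angles, fx$state$angles)
})

test_that("a terminal position prior shapes the free-end distribution", {
  # free 10-link chain, Gaussian prior on the end-frame origin only: the end
  # position explores the prior basin and its spread approaches the prior sd
  n <- 10
  centres <- matrix(NA_real_, 2, n + 1)
  centres[, n + 1] <- c(5, 2)
  fx <- make_planar_chain(n, closed = FALSE,
                          position_prior = list(centres = centres, sd = 0.3))
  cfg <- sampler_config(b = 4L, n_samples = 20000L, seed = 10L, sigma_free = 0.6)
  e <- run_sampler(fx$chain, fx$state, fx$fg, cfg)
  keep <- seq(2001, 20001, by = 10)
  ends <- t(vapply(keep, function(k) {
    p <- fk_planar(fx$chain$lengths, e$angles[k, ], c(0, 0, 0))
    p[1:2, n + 1]
  }, c(0, 0)))
  expect_lt(max(abs(colMeans(ends) - c(5, 2))), 0.1)
  expect_lt(abs(sd(ends[, 1]) / 0.3 - 1), 0.10)
  expect_lt(abs(sd(ends[, 2]) / 0.3 - 1), 0.10)
})

test_that("backbone loop sampling keeps exact closure and positive scores", {
  set.seed(65)
  mp <- make_mini_protein(n_res = 11, loop_start = 3, loop_end = 9)
  loaded <- load_state_from_pdb(mp$path, mp$loop_spec)
  grid <- make_toy_rama_grid()
  fg <- protein_factor_graph(loaded, grid, priors = c("rama", "clash"))
  prior <- local_angle_prior(4 * pi / 180)
  cfg <- sampler_config(b = 8L, n_samples = 12L, seed = 2L,
                        ik = list(max_seeds = 48L))
  e <- run_sampler(loaded$chain, loaded$state, fg, cfg, prior)
  expect_gt(e$acceptance_rate, 0)
  n <- loaded$chain$n_joints
  for (k in seq_len(nrow(e$angles))) {
    fr <- forward_kinematics(loaded$chain, e$angles[k, ])
    expect_lt(max(abs(frame_error(fr[, , n + 1], loaded$chain$end_constraint))), 1e-8)
    ctx <- slikmc:::state_ctx(loaded$chain, e$angles[k, ], fr,
                              backbone_to_atoms(loaded$chain, fr))
    expect_gt(full_score(fg, ctx), -Inf)
  }
  expect_true(validate_state(loaded$chain, e$final_state))
})

test_that("debug validation and the JSON-lines step log work", {
  fx <- make_planar_chain(8, anchor_dist = 4)
  lf <- tempfile(fileext = ".jsonl")
  cfg <- sampler_config(b = 4L, n_samples = 5L, seed = 3L, debug = TRUE,
                        log_file = lf)
  e <- run_sampler(fx$chain, fx$state, fx$fg, cfg)
  lines <- readLines(lf)
  expect_identical(length(lines), 5L * 5L)          # blocks per sweep x sweeps
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("sweep", "block", "accepted", "reason") %in% names(rec)))
  # the log forces the generic path; trajectories still match the fast path
  e2 <- run_sampler(fx$chain, fx$state, fx$fg,
                    sampler_config(b = 4L, n_samples = 5L, seed = 3L))
  expect_equal(e$angles, e2$angles, tolerance = 1e-9)
})
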