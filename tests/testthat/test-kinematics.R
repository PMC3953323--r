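# Chains, forward kinematics, backbone geometry and PDB round-trips.

test_that("forward kinematics handles the straight planar chain and is deterministic", {
  ch <- planar_chain(c(1, 1, 1))
  fr <- forward_kinematics(ch, c(0, 0, 0))
  expect_equal(fr[1:3, 4, 4], c(3, 0, 0))
  q <- c(0.2, -0.4, 1.1)
  expect_identical(forward_kinematics(ch, q), forward_kinematics(ch, q))
  expect_error(forward_kinematics(ch, c(0, 0)), "expected 3 angles")
})

test_that("forward kinematics matches a naive homogeneous-matrix oracle", {
  set.seed(41)
  for (rep in 1:5) {
    ch <- rand_chain(8)
    q <- runif(8, -pi, pi)
    fr <- forward_kinematics(ch, q)
    or <- fk_oracle(ch, q)
    expect_lt(max(abs(fr[1:3, 4, ] - or[1:3, 4, ])), 1e-9)
    expect_lt(max(abs(fr - or)), 1e-9)
  }
})

test_that("all frames stay rigid along random chains", {
  set.seed(42)
  ch <- rand_chain(10)
  fr <- forward_kinematics(ch, runif(10, -pi, pi))
  for (j in 1:11) {
    R <- fr[1:3, 1:3, j]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
  }
})

test_that("the planar fast path is an exact specialization of the 3D path", {
  set.seed(43)
  L <- runif(7, 0.5, 2)
  base <- c(0.3, -1, 0.7)
  ch <- planar_chain(L, base = base)
  q <- runif(7, -pi, pi)
  fr3 <- forward_kinematics(ch, q)
  p2 <- fk_planar(L, q, base)
  expect_lt(max(abs(fr3[1, 4, ] - p2[1, ])), 1e-12)
  expect_lt(max(abs(fr3[2, 4, ] - p2[2, ])), 1e-12)
  th3 <- atan2(fr3[2, 1, ], fr3[1, 1, ])
  expect_lt(max(abs(wrap_angle(th3 - p2[3, ]))), 1e-12)
  expect_lt(max(abs(fr3[3, 4, ])), 1e-12)  # stays in the plane
})

test_that("chain constructors validate axes and rigidity", {
  bad_axes <- matrix(c(0, 0, 2), 3, 1)
  rel <- array(diag(4), dim = c(4, 4, 1))
  expect_error(new_chain(bad_axes, rel), "unit")
  rel_bad <- rel; rel_bad[1, 1, 1] <- 2
  expect_error(new_chain(matrix(c(0, 0, 1), 3, 1), rel_bad), "rigid")
})

test_that("backbone construction and dihedral measurement round-trip", {
  set.seed(44)
  for (rep in 1:4) {
    n <- 6
    phi <- runif(n, -pi, pi)
    psi <- runif(n, -pi, pi)
    bb <- build_backbone(phi, psi)
    dh <- measure_backbone_dihedrals(bb)
    expect_lt(max(abs(wrap_angle(dh[-1, "phi"] - phi[-1]))), 1e-9)
    expect_lt(max(abs(wrap_angle(dh[-n, "psi"] - psi[-n]))), 1e-9)
  }
})

test_that("reconstructed bond lengths equal the configured ideal values", {
  g <- ideal_backbone_geometry()
  bb <- build_backbone(rep(-1, 5), rep(2, 5), g)
  get <- function(r, at) bb$xyz[which(bb$resno == r & bb$elety == at), ]
  for (r in 1:5) {
    expect_equal(sqrt(sum((get(r, "CA") - get(r, "N"))^2)), g$len_n_ca, tolerance = 1e-9)
    expect_equal(sqrt(sum((get(r, "C") - get(r, "CA"))^2)), g$len_ca_c, tolerance = 1e-9)
    if (r < 5) {
      expect_equal(sqrt(sum((get(r + 1, "N") - get(r, "C"))^2)), g$len_c_n, tolerance = 1e-9)
    }
  }
})

test_that("the fully extended strand maximises the end-to-end distance", {
  vals <- seq(-pi, pi, length.out = 25)
  span <- function(a) {
    bb <- build_backbone(rep(a, 8), rep(a, 8))
    ca <- bb$xyz[bb$elety == "CA", ]
    sqrt(sum((ca[8, ] - ca[1, ])^2))
  }
  spans <- vapply(vals, span, 0)
  expect_equal(which.max(spans), which.min(abs(abs(vals) - pi)))
  expect_gt(span(pi), max(spans[abs(vals) < 3]) - 1e-12)
})

test_that("loop chains reproduce native coordinates and satisfy Eq-consistency", {
  set.seed(45)
  phi <- runif(9, -pi, 0); psi <- runif(9, -pi, pi)
  bb <- build_backbone(phi, psi)
  lc <- backbone_loop_chain(bb, 3, 7)
  at <- lc$chain$meta$atom_owners
  pos <- backbone_to_atoms(lc$chain, lc$state$frames)
  for (k in seq_len(nrow(at))) {
    ref <- bb$xyz[which(bb$resno == at$resno[k] & bb$elety == at$elety[k]), ]
    expect_lt(max(abs(pos[k, ] - ref)), 1e-9)
  }
  expect_true(validate_state(lc$chain, lc$state))
  # native angles are the measured dihedrals
  expect_lt(max(abs(wrap_angle(lc$state$angles[seq(1, 9, 2)] - phi[3:7]))), 1e-9)
  expect_lt(max(abs(wrap_angle(lc$state$angles[seq(2, 10, 2)] - psi[3:7]))), 1e-9)
})

test_that("dihedrals measured from regenerated atoms equal the set angles", {
  set.seed(46)
  bb <- build_backbone(runif(8, -pi, pi), runif(8, -pi, pi))
  lc <- backbone_loop_chain(bb, 2, 7)
  q2 <- wrap_angle(lc$state$angles + runif(12, -1, 1))
  st2 <- new_state(lc$chain, q2)
  at <- lc$chain$meta$atom_owners
  bb2 <- bb
  for (k in seq_len(nrow(at))) {
    bb2$xyz[which(bb2$resno == at$resno[k] & bb2$elety == at$elety[k]), ] <- st2$atoms[k, ]
  }
  dh <- measure_backbone_dihedrals(bb2)
  res <- 2:7
  expect_lt(max(abs(wrap_angle(dh[as.character(res), "phi"] - q2[seq(1, 11, 2)]))), 1e-9)
  expect_lt(max(abs(wrap_angle(dh[as.character(res[-6]), "psi"] - q2[seq(2, 10, 2)]))), 1e-9)
})

test_that("PDB loading round-trips coordinates, dihedrals and B-factors", {
  mp <- make_mini_protein(n_res = 10, loop_start = 3, loop_end = 8,
                          conformation = "helix", bfactor = c(15, 25))
  loaded <- load_state_from_pdb(mp$path, mp$loop_spec)
  at <- loaded$chain$meta$atom_owners
  for (k in seq_len(nrow(at))) {
    ref <- mp$bb$xyz[which(mp$bb$resno == at$resno[k] & mp$bb$elety == at$elety[k]), ]
    expect_lt(max(abs(loaded$state$atoms[k, ] - ref)), 1e-3)  # PDB precision
  }
  expect_lt(max(abs(wrap_angle(loaded$state$angles[seq(1, 12, 2)] + 57 * pi / 180))), 2e-3)
  expect_lt(max(abs(wrap_angle(loaded$state$angles[seq(2, 12, 2)] + 47 * pi / 180))), 2e-3)
  expect_true(all(at$b %in% c(15, 25)))
  # writing the loaded ensemble back preserves coordinates at PDB precision
  out <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(out, loaded, list(loaded$state$angles))
  re <- bio3d::read.pdb(out, multi = TRUE)
  expect_lt(max(abs(re$xyz[1, ] - loaded$pdb$xyz[1, ])), 1e-3)
})

test_that("loop specifications outside the chain raise errors", {
  mp <- make_mini_protein(n_res = 8)
  expect_error(load_state_from_pdb(mp$path, list(chain = "A", start = 5, end = 30)),
               "outside")
  expect_error(load_state_from_pdb(mp$path, list(chain = "B", start = 3, end = 6)),
               "not found")
  expect_error(load_state_from_pdb(mp$path, list(chain = "A", start = 1, end = 4)),
               "outside")
})
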