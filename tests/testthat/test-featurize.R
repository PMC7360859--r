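test_that("dihedral reproduces planar references and the independent oracle", {
  expect_equal(dihedral(c(1,0,0), c(0,0,0), c(0,1,0), c(1,1,0)), 0)
  expect_equal(dihedral(c(1,0,0), c(0,0,0), c(0,1,0), c(-1,1,0)), 180)
  ## sign convention frozen by the projection-formula oracle
  expect_equal(oracle_dihedral(c(1,0,0), c(0,0,0), c(0,1,0), c(0,1,1)), -90)
  expect_equal(dihedral(c(1,0,0), c(0,0,0), c(0,1,0), c(0,1,1)), -90)
  set.seed(7)
  for (i in 1:25) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_equal(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("dihedral is rigid-motion invariant and flips sign under reflection", {
  set.seed(8)
  for (i in 1:20) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    a0 <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    rm <- random_rigid_motion()
    q <- apply_rigid(pts, rm)
    expect_equal(dihedral(q[1, ], q[2, ], q[3, ], q[4, ]), a0,
                 tolerance = 1e-9)
    mir <- pts %*% diag(c(-1, 1, 1))
    expect_equal(dihedral(mir[1, ], mir[2, ], mir[3, ], mir[4, ]), -a0,
                 tolerance = 1e-9)
  }
  expect_error(dihedral(c(0,0,0), c(0,0,0), c(0,1,0), c(1,1,0)), "coincide")
  expect_error(dihedral(c(2,0,0), c(1,0,0), c(0,0,0), c(-1,0,0)), "collinear")
})

test_that("psi/phi features embed angles on the unit circle and realize prescribed values", {
  psi <- matrix(c(90, -60, 120), 1)
  traj <- toy_backbone_traj(psi)
  fm <- psi_phi_features(traj, region_selection("CDR3_alpha", "A", c(1, 3)),
                         angles = "psi")
  lab <- attr(fm, "labels")
  expect_equal(length(lab), ncol(fm))
  ## residue 1 psi = 90 -> (sin, cos) = (1, 0)
  i_sin <- grep("A1:psi:sin", lab); i_cos <- grep("A1:psi:cos", lab)
  expect_equal(unname(fm[1, i_sin]), 1, tolerance = 1e-12)
  expect_equal(unname(fm[1, i_cos]), 0, tolerance = 1e-12)
  ## terminal psi (residue 3) is skipped: 2 psi angles -> 4 features
  expect_equal(ncol(fm), 4)
  ## sin^2 + cos^2 = 1 for every pair
  s2 <- fm[, grep(":sin$", lab), drop = FALSE]^2 +
    fm[, grep(":cos$", lab), drop = FALSE]^2
  expect_true(all(abs(s2 - 1) < 1e-9))
})

test_that("a constant trajectory gives zero-variance features", {
  psi <- matrix(rep(c(-60, 120, 40), each = 6), 6)
  traj <- toy_backbone_traj(psi)
  fm <- psi_phi_features(traj, region_selection("CDR3_alpha", "A", c(1, 3)))
  expect_true(all(apply(fm, 2, stats::var) < 1e-20))
})

test_that("decoded angles of HMM frames stay within 3 sigma of the generating state mean", {
  P <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  spec <- hmm_dihedral_spec(P, rbind(rep(-60, 4), rep(120, 4)),
                            emission_sd = 8, n_frames = 2000, seed = 5)
  g <- generate_hmm_trajectory(spec)
  fm <- psi_phi_features(g$trajectory, region_selection("custom", "A", c(1, 4)),
                         angles = "psi")
  ang <- attr(fm, "angle_deg")
  means <- spec$psi_means[g$hidden, seq_len(ncol(ang)), drop = FALSE]
  dev <- abs(tcrmsm::wrap_angle(ang - means))
  expect_gt(mean(dev <= 3 * 8), 0.99)
})

test_that("the collective variable is the stated linear combination", {
  psi <- matrix(c(90, -60, 120, 30), 1)
  traj <- toy_backbone_traj(psi)
  sel <- region_selection("CDR3_alpha", "A", c(1, 4))
  fm <- psi_phi_features(traj, sel, angles = "psi")
  k <- length(grep(":psi:sin$", attr(fm, "labels")))
  expect_equal(collective_variable(fm, rep(0, k), rep(0, k)), 0)
  ## single-angle check: weights pick out sin(90) = 1
  w <- rep(0, k); w[1] <- 1
  expect_equal(collective_variable(fm, w, rep(0, k)), 1, tolerance = 1e-12)
  ## random weights against a hand-rolled sum over 5 frames
  set.seed(11)
  psi5 <- matrix(runif(5 * 4, -170, 170), 5)
  traj5 <- toy_backbone_traj(psi5)
  fm5 <- psi_phi_features(traj5, sel, angles = "psi")
  a <- runif(k); b <- runif(k)
  ang <- attr(fm5, "angle_deg") * pi / 180
  manual <- sapply(seq_len(5), function(f)
    sum(a * sin(ang[f, ])) + sum(b * cos(ang[f, ])))
  expect_equal(collective_variable(fm5, a, b), manual, tolerance = 1e-12)
  expect_error(collective_variable(fm5, c(a, 1), b), "weight length")
})

test_that("center of mass matches weighted means and a loop-accumulation oracle", {
  top <- structure3d(atom_name = rep("CA", 2), resid = 1:2,
                     chain = c("A", "A"), element = c("C", "C"),
                     xyz = rbind(c(-1, 0, 0), c(1, 0, 0)))
  sel <- region_selection("custom", "A", c(1, 2))
  expect_equal(center_of_mass(top, top$xyz, sel), c(0, 0, 0))
  top2 <- structure3d(atom_name = rep("CA", 2), resid = 1:2,
                      chain = c("A", "A"), element = c("C", "C"),
                      xyz = rbind(c(0, 0, 0), c(4, 0, 0)),
                      mass = c(1, 3))
  expect_equal(center_of_mass(top2, top2$xyz, sel), c(3, 0, 0))
  set.seed(12)
  xyz <- matrix(rnorm(30), 10, 3)
  m <- runif(10, 1, 20)
  top3 <- structure3d(atom_name = rep("CA", 10), resid = 1:10,
                      chain = rep("A", 10), element = rep("C", 10),
                      xyz = xyz, mass = m)
  sel10 <- region_selection("custom", "A", c(1, 10))
  acc <- c(0, 0, 0)
  for (i in 1:10) acc <- acc + m[i] * xyz[i, ]
  expect_equal(center_of_mass(top3, xyz, sel10), acc / sum(m),
               tolerance = 1e-12)
  expect_equal(center_of_mass(top3, xyz, sel10, mass_weighted = FALSE),
               colMeans(xyz), tolerance = 1e-12)
})

test_that("interdomain torsion recovers prescribed targets over the angle grid", {
  for (tgt in seq(-150, 150, by = 50)) {
    g <- generate_two_domain_trajectory(
      two_domain_spec(tgt, jitter_sd = 0, n_frames = 2, seed = 3))
    a <- do.call(interdomain_torsion, c(list(g$trajectory), g$selections))
    expect_lt(max(abs(as.numeric(a) - tgt)), 1e-6)
  }
})

test_that("interdomain torsion is rigid-motion invariant and mirror-antisymmetric", {
  g <- generate_two_domain_trajectory(
    two_domain_spec(60, jitter_sd = 0, n_frames = 2, seed = 4))
  a0 <- as.numeric(do.call(interdomain_torsion, c(list(g$trajectory), g$selections)))
  set.seed(13)
  rm <- random_rigid_motion()
  tr <- g$trajectory
  for (f in 1:2) tr$coords[, , f] <- apply_rigid(tr$coords[, , f], rm)
  a1 <- as.numeric(do.call(interdomain_torsion, c(list(tr), g$selections)))
  expect_equal(a1, a0, tolerance = 1e-9)
  mir <- g$trajectory
  for (f in 1:2) mir$coords[, , f] <- mir$coords[, , f] %*% diag(c(-1, 1, 1))
  a2 <- as.numeric(do.call(interdomain_torsion, c(list(mir), g$selections)))
  expect_equal(a2, -a0, tolerance = 1e-9)
})

test_that("overlapping interdomain selections are rejected", {
  g <- generate_two_domain_trajectory(two_domain_spec(60, n_frames = 1))
  sels <- g$selections
  sels$v_alpha <- region_selection("V_alpha", "A", c(1, 108))  # overlaps CDR
  expect_error(do.call(interdomain_torsion, c(list(g$trajectory), sels)),
               "disjoint")
})
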