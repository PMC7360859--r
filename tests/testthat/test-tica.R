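telegraph_features <- function(n, p_stay = 0.95, noise = 0.1, seed = 1) {
  P <- matrix(c(p_stay, 1 - p_stay, 1 - p_stay, p_stay), 2, 2)
  s <- simulate_markov_chain(P, n, seed = seed)
  set.seed(seed + 5000)
  list(x = cbind(ifelse(s == 1, 1, -1) + rnorm(n, sd = noise)), states = s)
}

test_that("the leading tICA eigenvalue matches the telegraph autocorrelation", {
  lag <- 5
  p_stay <- 0.95
  ## closed form: chain autocorrelation (2p-1)^lag attenuated by the
  ## signal-to-total variance ratio 1 / (1 + noise^2) (emission is iid)
  expected <- (2 * p_stay - 1)^lag / (1 + 0.1^2)
  vals <- sapply(1:50, function(seed)
    fit_tica(telegraph_features(4000, p_stay, seed = seed)$x, lag = lag,
             n_components = 1, frame_interval = 1)$eigenvalues[1])
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se + 1e-3)
})

test_that("white noise has no time structure and degenerate features need reg", {
  set.seed(21)
  X <- matrix(rnorm(10000 * 3), ncol = 3)
  tm <- fit_tica(X, lag = 2, n_components = 3, frame_interval = 1)
  expect_true(all(abs(tm$eigenvalues) < 0.1))
  ## duplicated (perfectly collinear) features fit fine with reg > 0
  tf <- telegraph_features(2000, seed = 31)
  Xdup <- cbind(tf$x, tf$x)
  tmd <- fit_tica(Xdup, lag = 5, n_components = 2, reg = 1e-6,
                  frame_interval = 1)
  expect_true(all(is.finite(tmd$components)))
  pr <- predict(tmd, Xdup)
  expect_true(all(is.finite(pr)))
})

test_that("projection is the mean-centered linear map", {
  tf <- telegraph_features(3000, seed = 41)
  tm <- fit_tica(tf$x, lag = 5, n_components = 1, frame_interval = 1)
  expect_equal(as.numeric(predict(tm, matrix(tm$mean, 1))), 0,
               tolerance = 1e-10)
  p1 <- predict(tm, tf$x[1, , drop = FALSE])
  p2 <- predict(tm, tf$x[2, , drop = FALSE])
  diff_direct <- (tf$x[1, ] - tf$x[2, ]) %*% tm$components
  expect_equal(as.numeric(p1 - p2), as.numeric(diff_direct),
               tolerance = 1e-12)
  ## tIC1 sign separates the generating states
  pr <- as.numeric(predict(tm, tf$x))
  side <- pr > 0
  purity <- max(mean(side == (tf$states == 1)),
                mean(side == (tf$states == 2)))
  expect_gt(purity, 0.95)
})

test_that("symmetrized estimation is invariant under time reversal with a real bounded spectrum", {
  tf <- telegraph_features(4000, seed = 51)
  tm <- fit_tica(tf$x, lag = 5, n_components = 1, frame_interval = 1)
  tm_rev <- fit_tica(tf$x[nrow(tf$x):1, , drop = FALSE], lag = 5,
                     n_components = 1, frame_interval = 1)
  expect_equal(tm$eigenvalues, tm_rev$eigenvalues, tolerance = 1e-10)
  expect_true(all(tm$eigenvalues <= 1 & tm$eigenvalues >= -1))
})

test_that("the tICA implied timescale recovers the telegraph relaxation time", {
  p_stay <- 0.98
  t_r <- -1 / log(2 * p_stay - 1)
  lag <- 5
  tf <- telegraph_features(50000, p_stay, seed = 61)
  tm <- fit_tica(tf$x, lag = lag, n_components = 1, frame_interval = 1)
  t_hat <- -lag / log(tm$eigenvalues[1])
  expect_lt(abs(t_hat - t_r) / t_r, 0.2)
})

test_that("lag validation: too-long and non-multiple lags are rejected", {
  tf <- telegraph_features(100, seed = 71)
  expect_error(fit_tica(tf$x, lag = 100, frame_interval = 1), "shorter")
  expect_error(fit_tica(tf$x, lag = 2.5, frame_interval = 1), "multiple")
})

test_that("free-energy surfaces are flat for uniform sampling and symmetric for equal clusters", {
  set.seed(81)
  U <- cbind(runif(64000), runif(64000))
  fes <- free_energy_surface(U, temperature = 300, bins = 4)
  expect_lt(max(abs(fes$values), na.rm = TRUE), 0.15)
  expect_equal(min(fes$values, na.rm = TRUE), 0)
  ## two equal Gaussian clusters -> two minima within 0.1 kcal/mol
  G <- rbind(cbind(rnorm(20000, -3, 0.3), rnorm(20000, 0, 0.3)),
             cbind(rnorm(20000, 3, 0.3), rnorm(20000, 0, 0.3)))
  fes2 <- free_energy_surface(G, bins = 20)
  mids <- (fes2$edges[[1]][-1] + fes2$edges[[1]][-21]) / 2
  f_left <- min(fes2$values[mids < 0, ], na.rm = TRUE)
  f_right <- min(fes2$values[mids > 0, ], na.rm = TRUE)
  expect_lt(abs(f_left - f_right), 0.1)
  ## single point: one occupied bin at F = 0
  fes3 <- free_energy_surface(matrix(c(0.5, 0.5), 1), bins = 4)
  expect_equal(sum(fes3$counts > 0), 1)
  expect_equal(min(fes3$values, na.rm = TRUE), 0)
  expect_true(all(is.na(fes3$values[fes3$counts == 0])))
})

test_that("single structures project to the same point as their in-trajectory frames", {
  P <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  spec <- hmm_dihedral_spec(P, rbind(rep(-60, 4), rep(120, 4)),
                            emission_sd = 8, n_frames = 2000, seed = 91)
  g <- generate_hmm_trajectory(spec)
  sel <- region_selection("custom", "A", c(1, 4))
  fm <- psi_phi_features(g$trajectory, sel)
  tm <- fit_tica(fm, lag = 5, n_components = 2)
  pr <- predict(tm, fm)
  ## frame 10 as a standalone structure
  s <- g$trajectory$topology
  s$xyz <- tcrmsm:::frame_coords(g$trajectory, 10)
  pt <- project_structure(tm, s, sel)
  expect_equal(pt, as.numeric(pr[10, ]), tolerance = 1e-10)
  ## synthetic "crystal" at a state mean falls among that state's frames
  noiseless <- hmm_dihedral_spec(matrix(1), spec$psi_means[1, , drop = FALSE],
                                 emission_sd = 1e-6, n_frames = 1, seed = 1)
  cry <- generate_hmm_trajectory(noiseless)
  sc <- cry$trajectory$topology
  sc$xyz <- tcrmsm:::frame_coords(cry$trajectory, 1)
  pc <- project_structure(tm, sc, sel)
  st1 <- pr[g$hidden == 1, 1]
  expect_gt(pc[1], mean(st1) - 3 * stats::sd(st1))
  expect_lt(pc[1], mean(st1) + 3 * stats::sd(st1))
  ## mismatched loop length -> label/feature mismatch error
  short <- hmm_dihedral_spec(matrix(1), matrix(-60, 1, 3),
                             emission_sd = 1, n_frames = 1, seed = 1)
  gs <- generate_hmm_trajectory(short)
  ss <- gs$trajectory$topology
  ss$xyz <- tcrmsm:::frame_coords(gs$trajectory, 1)
  expect_error(project_structure(tm, ss, region_selection("custom", "A", c(1, 3))),
               "match")
})
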