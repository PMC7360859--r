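test_that("transition counting matches hand enumeration and a brute-force oracle", {
  expect_equal(count_transitions(c(0L, 1L, 0L, 1L), 1),
               matrix(c(0L, 1L, 2L, 0L), 2, 2))
  C2 <- count_transitions(c(0L, 0L, 0L, 0L), 2)
  expect_equal(C2, matrix(2L, 1, 1))
  set.seed(1)
  d <- sample(0:2, 60, replace = TRUE)
  lag <- 3
  C <- count_transitions(d, lag)
  manual <- matrix(0L, 3, 3)
  for (t in seq_len(length(d) - lag))
    manual[d[t] + 1, d[t + lag] + 1] <- manual[d[t] + 1, d[t + lag] + 1] + 1L
  expect_equal(C, manual)
  expect_error(count_transitions(c(0L, 1L), 5), "shorter")
})

test_that("the largest connected set picks the heaviest strongly connected component", {
  C <- matrix(0, 5, 5)
  C[1:3, 1:3] <- 10; C[4:5, 4:5] <- 2
  expect_equal(largest_connected_set(C), 1:3)
  Cfull <- matrix(1, 4, 4)
  expect_equal(largest_connected_set(Cfull), 1:4)
  ## one-way chain 0 -> 1 -> 2: every SCC is a singleton
  Cchain <- matrix(0, 3, 3)
  Cchain[1, 2] <- 5; Cchain[2, 3] <- 5; diag(Cchain) <- c(1, 2, 9)
  expect_length(largest_connected_set(Cchain), 1)
})

test_that("reversible MLE reduces to row normalization for symmetric counts", {
  C <- matrix(c(8, 2, 2, 8), 2, 2)
  m <- estimate_msm(C, lag = 1)
  expect_equal(m$transition_matrix, matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2),
               tolerance = 1e-9)
  expect_equal(m$stationary, c(0.5, 0.5), tolerance = 1e-9)
  set.seed(2)
  S <- matrix(sample(1:20, 16, replace = TRUE), 4, 4)
  S <- S + t(S)
  ms <- estimate_msm(S, lag = 1)
  expect_equal(ms$transition_matrix, S / rowSums(S), tolerance = 1e-8)
})

test_that("estimated models satisfy stochasticity, stationarity and detailed balance", {
  set.seed(3)
  for (rep in 1:5) {
    C <- matrix(rpois(25, 20) + 1L, 5, 5)
    m <- estimate_msm(C, lag = 1)
    T_mat <- m$transition_matrix
    p <- m$stationary
    expect_true(all(abs(rowSums(T_mat) - 1) < 1e-10))
    expect_true(all(abs(p %*% T_mat - p) < 1e-8))
    expect_true(all(abs(T_mat * p - t(T_mat * p)) < 1e-8))
    ## reversible spectrum is real in [-1, 1]
    expect_true(all(m$eigenvalues >= -1 - 1e-12 & m$eigenvalues <= 1 + 1e-12))
  }
})

test_that("the reversible MLE beats a random search over detailed-balance matrices", {
  set.seed(4)
  C <- matrix(rpois(16, 8) + 1L, 4, 4)
  m <- estimate_msm(C, lag = 1)
  loglik <- function(T_mat) sum(C * log(T_mat))
  ll_best <- loglik(m$transition_matrix)
  worse <- 0
  for (i in 1:20000) {
    pi_r <- stats::rgamma(4, 1); pi_r <- pi_r / sum(pi_r)
    X <- matrix(stats::rgamma(16, 1), 4, 4)
    X <- X + t(X)                  # symmetric flux => detailed balance
    T_r <- X / rowSums(X)
    if (loglik(T_r) <= ll_best + 1e-9) worse <- worse + 1
  }
  expect_equal(worse, 20000)
})

test_that("implied timescales follow the closed form and flag degenerate spectra", {
  m <- estimate_msm(matrix(c(9, 1, 1, 9), 2, 2), lag = 1)
  its <- implied_timescales(m, 1)
  expect_equal(its$timescale_ns[1], -1 / log(0.8), tolerance = 1e-9)
  ## identity-like chain: eigenvalue 1 -> infinite timescale marker
  ident <- list(eigenvalues = c(1, 1), lag = 1)
  class(ident) <- "msm_model"
  expect_true(is.infinite(implied_timescales(ident, 1)$timescale_ns[1]))
  neg <- list(eigenvalues = c(1, -0.2), lag = 1)
  class(neg) <- "msm_model"
  expect_true(is.na(implied_timescales(neg, 1)$timescale_ns[1]))
})

test_that("implied timescales plateau once the lag clears the emission decorrelation", {
  P <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2)
  hid <- simulate_markov_chain(P, 50000, seed = 2)
  set.seed(102)
  obs <- ifelse(stats::runif(50000) < 0.02, 3L - hid, hid) - 1L
  its <- sapply(c(10, 15, 20), function(L) {
    m <- estimate_msm(count_transitions(obs, L), lag = L)
    implied_timescales(m, 1)$timescale_ns[1]
  })
  expect_lt(max(its) / min(its) - 1, 0.2)
})

test_that("PCCA+ recovers nearly decomposable blocks with simplex-valid memberships", {
  eps <- 1e-3
  T_block <- matrix(c(0.5 - eps, 0.5 - eps, eps, eps,
                      0.5 - eps, 0.5 - eps, eps, eps,
                      eps, eps, 0.5 - eps, 0.5 - eps,
                      eps, eps, 0.5 - eps, 0.5 - eps), 4, 4, byrow = TRUE)
  C <- round(T_block * 1e5)
  m <- estimate_msm(C, lag = 1)
  mac <- pcca_plus(m, 2)
  expect_true(same_partition(mac$crisp_assignment, c(1, 1, 2, 2)))
  expect_equal(rowSums(mac$memberships), rep(1, 4), tolerance = 1e-10)
  expect_true(all(mac$memberships >= 0 & mac$memberships <= 1))
  expect_equal(sum(mac$macro_stationary), 1, tolerance = 1e-9)
  ## membership simplex constraint on arbitrary reversible models
  set.seed(5)
  Cr <- matrix(rpois(36, 15) + 1L, 6, 6)
  mr <- estimate_msm(Cr, lag = 1)
  macr <- pcca_plus(mr, 3)
  expect_equal(rowSums(macr$memberships), rep(1, 6), tolerance = 1e-10)
  expect_error(pcca_plus(mr, 1), "between 2")
})

test_that("three-state HMM macrostates match the hidden states with high purity", {
  P <- matrix(c(0.96, 0.03, 0.01,
                0.02, 0.96, 0.02,
                0.01, 0.03, 0.96), 3, 3, byrow = TRUE)
  psi_means <- rbind(rep(-60, 5), rep(120, 5), c(-60, 120, -60, 120, -60))
  spec <- hmm_dihedral_spec(P, psi_means, emission_sd = 12,
                            n_frames = 20000, seed = 6)
  g <- generate_hmm_trajectory(spec)
  fm <- psi_phi_features(g$trajectory, region_selection("custom", "A", c(1, 5)))
  tm <- fit_tica(fm, lag = 5, n_components = 2)
  km <- kmeans_microstates(predict(tm, fm), k = 40, seed = 6)
  m <- estimate_msm(count_transitions(km$assignment, 5), lag = 5)
  mac <- pcca_plus(m, 3)
  fr_mac <- frames_to_macrostates(mac, km$assignment)
  purity <- mean(sapply(1:3, function(a) {
    tab <- table(g$hidden[fr_mac == a])
    max(tab) / sum(tab)
  }))
  expect_gt(purity, 0.95)

  ## a k-means center is its own nearest microstate, so a frame sitting on
  ## it inherits that microstate's macrostate
  expect_equal(predict(km, km$centers), 0:(km$n_states - 1))
  f7 <- fm[7, , drop = FALSE]
  expect_equal(assign_to_macrostate(f7, tm, km, mac),
               frames_to_macrostates(mac, predict(km, predict(tm, f7))))

  ## a frame rebuilt at a generator state mean lands in that state's macrostate
  pure <- hmm_dihedral_spec(matrix(1), psi_means[2, , drop = FALSE],
                            emission_sd = 1e-6, n_frames = 1, seed = 1)
  gp <- generate_hmm_trajectory(pure)
  s <- gp$trajectory$topology
  s$xyz <- tcrmsm:::frame_coords(gp$trajectory, 1)
  sel <- region_selection("custom", "A", c(1, 5))
  got <- assign_to_macrostate(s, tm, km, mac, selections = sel)
  want <- as.integer(names(which.max(table(fr_mac[g$hidden == 2]))))
  expect_equal(got, want)

  ## rigid motion does not change the assignment (dihedral features)
  set.seed(7)
  rm <- random_rigid_motion()
  s2 <- s; s2$xyz <- apply_rigid(s$xyz, rm)
  expect_equal(assign_to_macrostate(s2, tm, km, mac, selections = sel), got)
})

test_that("Chapman-Kolmogorov accepts Markovian data and rejects a hidden fast intermediate", {
  P <- matrix(c(0.97, 0.02, 0.01,
                0.02, 0.96, 0.02,
                0.01, 0.03, 0.96), 3, 3, byrow = TRUE)
  d <- simulate_markov_chain(P, 20000, seed = 8) - 1L
  m <- estimate_msm(count_transitions(d, 1), lag = 1)
  mac <- pcca_plus(m, 3)
  ck <- chapman_kolmogorov(d, m, mac, lag_frames = 1, multiples = 1:5,
                           n_boot = 50, seed = 1)
  ## k = 1: predicted equals re-estimated exactly
  k1 <- ck$table[ck$table$multiple == 1, ]
  expect_equal(k1$predicted, k1$estimated, tolerance = 1e-12)
  expect_gte(ck_pass_fraction(ck), 0.9)
  ## lumped chain with disparate exit rates is non-Markovian
  Ph <- matrix(c(0.69, 0.01, 0.30,
                 0.01, 0.988, 0.002,
                 0.05, 0.005, 0.945), 3, 3, byrow = TRUE)
  hid <- simulate_markov_chain(Ph, 20000, seed = 9)
  obs <- ifelse(hid == 3, 1L, 0L)
  m2 <- estimate_msm(count_transitions(obs, 1), lag = 1)
  mac2 <- pcca_plus(m2, 2)
  ck2 <- chapman_kolmogorov(obs, m2, mac2, lag_frames = 1, multiples = 1:5,
                            n_boot = 50, seed = 1)
  expect_true(any(!ck2$table$ok, na.rm = TRUE))
})

test_that("mean first-passage times solve the linear system and match simulation", {
  m <- estimate_msm(matrix(c(9, 1, 1, 9), 2, 2), lag = 1)
  expect_equal(mfpt(m, 1, 2), 10, tolerance = 1e-9)
  expect_equal(mfpt(m, integer(0), 1:2), 0)  # target = all states
  ## kinetic Monte Carlo oracle on a 3-state chain
  set.seed(10)
  C3 <- matrix(rpois(9, 30) + 1L, 3, 3)
  m3 <- estimate_msm(C3, lag = 1)
  chain <- simulate_markov_chain(m3$transition_matrix, 3e5, seed = 11)
  ## empirical first-passage 1 -> 3
  fp <- c()
  t0 <- NA
  for (t in seq_along(chain)) {
    if (is.na(t0) && chain[t] == 1) t0 <- t
    if (!is.na(t0) && chain[t] == 3) { fp <- c(fp, t - t0); t0 <- NA }
  }
  est <- mean(fp); se <- stats::sd(fp) / sqrt(length(fp))
  expect_lt(abs(mfpt(m3, 1, 3) - est), 3 * se + 0.05)
  expect_error(mfpt(m3, 1, 1), "disjoint")
})
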