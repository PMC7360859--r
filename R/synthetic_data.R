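## Synthetic-data generators with known ground truth: hidden-Markov dihedral
## trajectories on an idealized polyalanine-like backbone, rigid two-domain
## assemblies with prescribed four-COM interdomain torsions, and analytic
## double-well potentials. All generators are deterministic per seed.

## Idealized backbone geometry (Angstrom / degrees); side chains omitted.
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.9,
                ang_ca_c_o = 120.5, omega = 180)

## Vectorized NeRF chain extension: place D given A, B, C (F x 3 matrices),
## bond length r, bond angle theta (deg), torsion phi (deg, per frame).
nerf_place <- function(A, B, C, r, theta, phi) {
  th <- deg2rad(theta); ph <- deg2rad(phi)
  bc <- C - B
  bc <- bc / rownorm(bc)
  ab <- B - A
  n <- cross3(ab, bc)
  n <- n / rownorm(n)
  m <- cross3(n, bc)
  d1 <- -r * cos(th)
  d2 <- r * sin(th) * cos(ph)
  d3 <- r * sin(th) * sin(ph)
  C + bc * d1 + m * d2 + n * d3
}

## Build backbone coordinates for F frames of an n_res chain with given
## per-frame phi/psi (F x n_res matrices, degrees; phi[ ,1] and
## psi[, n_res] are ignored). Returns array (4 * n_res) x 3 x F with atom
## order N, CA, C, O per residue.
build_backbone_frames <- function(phi, psi) {
  Fn <- nrow(psi); n_res <- ncol(psi)
  g <- BB_GEOM
  one <- function(x, y, z) matrix(rep(c(x, y, z), each = Fn), ncol = 3)
  N <- vector("list", n_res); CA <- vector("list", n_res)
  Cc <- vector("list", n_res); O <- vector("list", n_res)
  N[[1]] <- one(0, 0, 0)
  CA[[1]] <- one(g$n_ca, 0, 0)
  ## first C placed via a fixed dummy reference (same in every frame)
  dummy <- one(0, 1, 0)
  Cc[[1]] <- nerf_place(dummy, N[[1]], CA[[1]], g$ca_c, g$ang_n_ca_c,
                        rep(0, Fn))
  for (i in seq_len(n_res - 1)) {
    N[[i + 1]] <- nerf_place(N[[i]], CA[[i]], Cc[[i]], g$c_n, g$ang_ca_c_n,
                             psi[, i])
    CA[[i + 1]] <- nerf_place(CA[[i]], Cc[[i]], N[[i + 1]], g$n_ca,
                              g$ang_c_n_ca, rep(g$omega, Fn))
    Cc[[i + 1]] <- nerf_place(Cc[[i]], N[[i + 1]], CA[[i + 1]], g$ca_c,
                              g$ang_n_ca_c, phi[, i + 1])
  }
  for (i in seq_len(n_res)) {
    tors <- if (i < n_res) psi[, i] + 180 else rep(0, Fn)
    O[[i]] <- nerf_place(N[[i]], CA[[i]], Cc[[i]], g$c_o, g$ang_ca_c_o, tors)
  }
  coords <- array(NA_real_, dim = c(4 * n_res, 3, Fn))
  for (i in seq_len(n_res)) {
    coords[4 * i - 3, , ] <- t(N[[i]])
    coords[4 * i - 2, , ] <- t(CA[[i]])
    coords[4 * i - 1, , ] <- t(Cc[[i]])
    coords[4 * i, , ] <- t(O[[i]])
  }
  coords
}

backbone_topology <- function(n_res, chain = "A") {
  structure3d(atom_name = rep(c("N", "CA", "C", "O"), n_res),
              resid = rep(seq_len(n_res), each = 4),
              chain = rep(chain, 4 * n_res),
              element = rep(c("N", "C", "C", "O"), n_res),
              xyz = matrix(0, 4 * n_res, 3))
}

#' Simulate a discrete-time Markov chain
#'
#' @param P row-stochastic transition matrix.
#' @param n number of steps.
#' @param seed RNG seed (NULL to use the current RNG state).
#' @param init initial state (1-based; default: sampled from the stationary
#'   distribution).
#' @return integer vector of 1-based states, length `n`.
#' @export
simulate_markov_chain <- function(P, n, seed = NULL, init = NULL) {
  P <- as.matrix(P)
  if (any(abs(rowSums(P) - 1) > 1e-10)) stop("P must be row-stochastic")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(P)
  if (is.null(init)) {
    e <- eigen(t(P))
    v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
    init <- sample.int(m, 1, prob = v / sum(v))
  }
  s <- integer(n)
  s[1] <- init
  u <- stats::runif(n)
  cums <- lapply(seq_len(m), function(i) cumsum(P[i, ]))
  if (n >= 2)
    for (t in 2:n) s[t] <- findInterval(u[t], cums[[s[t - 1]]]) + 1L
  s
}

#' Specification for a hidden-Markov dihedral trajectory
#'
#' @param transition row-stochastic hidden transition matrix (n_h states).
#' @param psi_means n_h x n_res matrix of per-state psi means, degrees
#'   (entry for the last residue is unused: the terminal psi is undefined).
#' @param phi_means n_h x n_res matrix of per-state phi means, degrees
#'   (first-residue entry unused); default -60 everywhere.
#' @param emission_sd Gaussian emission noise, degrees (> 0).
#' @param n_frames frames to generate.
#' @param frame_interval ns between frames.
#' @param seed RNG seed.
#' @return an object of class `hmm_dihedral_spec`.
#' @export
hmm_dihedral_spec <- function(transition, psi_means, phi_means = NULL,
                              emission_sd = 10, n_frames = 1000,
                              frame_interval = 1, seed = 1) {
  transition <- as.matrix(transition)
  psi_means <- as.matrix(psi_means)
  if (any(abs(rowSums(transition) - 1) > 1e-10))
    stop("hidden transition matrix rows must sum to 1")
  if (nrow(psi_means) != nrow(transition))
    stop("psi_means must have one row per hidden state")
  if (is.null(phi_means))
    phi_means <- matrix(-60, nrow(psi_means), ncol(psi_means))
  stopifnot(emission_sd > 0, n_frames >= 1, frame_interval > 0,
            all(dim(phi_means) == dim(psi_means)))
  structure(list(transition = transition, psi_means = psi_means,
                 phi_means = as.matrix(phi_means), emission_sd = emission_sd,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "hmm_dihedral_spec")
}

#' Generate a hidden-Markov dihedral trajectory
#'
#' Samples a hidden discrete-state chain from the spec's transition matrix
#' and builds, per frame, an idealized polyalanine-like backbone whose
#' phi/psi angles are the state means plus Gaussian emission noise
#' (NeRF-style chain extension, standard bond lengths/angles, omega = 180).
#'
#' @param spec an `hmm_dihedral_spec`.
#' @return list with `trajectory` (a `trajectory3d`), `hidden` (1-based
#'   hidden state per frame), and `spec`.
#' @export
generate_hmm_trajectory <- function(spec) {
  stopifnot(inherits(spec, "hmm_dihedral_spec"))
  set.seed(spec$seed)
  n_res <- ncol(spec$psi_means)
  Fn <- spec$n_frames
  hidden <- simulate_markov_chain(spec$transition, Fn, seed = NULL)
  psi <- spec$psi_means[hidden, , drop = FALSE] +
    matrix(stats::rnorm(Fn * n_res, sd = spec$emission_sd), Fn, n_res)
  phi <- spec$phi_means[hidden, , drop = FALSE] +
    matrix(stats::rnorm(Fn * n_res, sd = spec$emission_sd), Fn, n_res)
  coords <- build_backbone_frames(phi, psi)
  traj <- trajectory3d(backbone_topology(n_res), coords,
                       frame_interval = spec$frame_interval)
  list(trajectory = traj, hidden = hidden, spec = spec)
}

#' Specification for a two-domain assembly trajectory
#'
#' @param targets per-macrostate interdomain torsion targets, degrees in
#'   (-180, 180].
#' @param occupancy per-macrostate probabilities (sum to 1).
#' @param jitter_sd isotropic Gaussian coordinate jitter, Angstrom (>= 0).
#' @param n_frames frames to generate.
#' @param frame_interval ns between frames.
#' @param seed RNG seed.
#' @return an object of class `two_domain_spec`.
#' @export
two_domain_spec <- function(targets, occupancy = NULL, jitter_sd = 0,
                            n_frames = 100, frame_interval = 1, seed = 1) {
  targets <- as.numeric(targets)
  if (any(targets <= -180 | targets > 180))
    stop("torsion targets must lie in (-180, 180]")
  if (is.null(occupancy)) occupancy <- rep(1 / length(targets), length(targets))
  if (length(occupancy) != length(targets) || abs(sum(occupancy) - 1) > 1e-10)
    stop("occupancies must match targets and sum to 1")
  stopifnot(jitter_sd >= 0, n_frames >= 1, frame_interval > 0)
  structure(list(targets = targets, occupancy = as.numeric(occupancy),
                 jitter_sd = jitter_sd, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "two_domain_spec")
}

## The four standard selections of the synthetic assembly.
#' Region selections for the synthetic two-domain assembly
#'
#' @return named list of the four `region_selection`s (cdr_alpha, v_alpha,
#'   v_beta, cdr_beta).
#' @export
two_domain_selections <- function() {
  list(cdr_alpha = region_selection("CDR_loops_alpha", "A", c(1, 8)),
       v_alpha = region_selection("V_alpha", "A", c(101, 108)),
       v_beta = region_selection("V_beta", "B", c(101, 108)),
       cdr_beta = region_selection("CDR_loops_beta", "B", c(1, 8)))
}

#' Generate a two-domain assembly trajectory with prescribed torsions
#'
#' Builds two rigid pseudo-domains, each carrying a pseudo-CDR atom
#' cluster, arranged so that the four-COM torsion (CDR-alpha cluster,
#' V-alpha, V-beta, CDR-beta cluster) is exact by construction. Per frame a
#' macrostate label is drawn from the occupancies and the beta-side is
#' rotated about the V-alpha/V-beta COM axis to the state's target torsion;
#' optional isotropic coordinate jitter adds angle noise.
#'
#' @param spec a `two_domain_spec`.
#' @return list with `trajectory` (a `trajectory3d`), `labels` (1-based
#'   macrostate per frame), `selections` (see [two_domain_selections()]),
#'   and `spec`.
#' @export
generate_two_domain_trajectory <- function(spec) {
  stopifnot(inherits(spec, "two_domain_spec"))
  set.seed(spec$seed)
  k <- 8                                   # atoms per pseudo-group
  centers <- list(cdr_a = c(10, 0, -5), v_a = c(0, 0, 0),
                  v_b = c(0, 0, 20), cdr_b_base = c(10, 0, 25))
  cloud <- function(center) {
    off <- matrix(stats::rnorm(3 * k, sd = 2), k, 3)
    off <- sweep(off, 2, colMeans(off))    # zero-mean: COM is exact
    sweep(off, 2, center, `+`)
  }
  g_cdr_a <- cloud(centers$cdr_a)
  g_v_a <- cloud(centers$v_a)
  g_v_b <- cloud(centers$v_b)
  g_cdr_b <- cloud(centers$cdr_b_base)
  base <- rbind(g_cdr_a, g_v_a, g_v_b, g_cdr_b)
  top <- structure3d(
    atom_name = rep("CA", 4 * k),
    resid = c(1:k, 101:(100 + k), 101:(100 + k), 1:k),
    chain = rep(c("A", "B"), each = 2 * k),
    element = rep("C", 4 * k),
    xyz = base)
  labels <- sample.int(length(spec$targets), spec$n_frames, replace = TRUE,
                       prob = spec$occupancy)
  beta_rows <- (2 * k + 1):(4 * k)         # V-beta + CDR-beta (chain B)
  coords <- array(NA_real_, dim = c(4 * k, 3, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    th <- deg2rad(spec$targets[labels[f]])
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    xyz <- base
    xyz[beta_rows, ] <- base[beta_rows, ] %*% t(R)
    if (spec$jitter_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$jitter_sd),
                          nrow(xyz), 3)
    coords[, , f] <- xyz
  }
  traj <- trajectory3d(top, coords, frame_interval = spec$frame_interval)
  list(trajectory = traj, labels = labels,
       selections = two_domain_selections(), spec = spec)
}

#' Analytic symmetric double-well potential
#'
#' V(s) = a s^4 - b s^2 with minima at +/- `min_separation` / 2 and barrier
#' height V(0) - V(min) exactly `barrier`.
#'
#' @param barrier barrier height, kcal/mol (> 0).
#' @param min_separation distance between the two minima (CV units).
#' @param domain CV domain (default +/- 2 * min_separation).
#' @return an `analytic_potential`.
#' @export
double_well <- function(barrier = 2, min_separation = 2, domain = NULL) {
  stopifnot(barrier > 0, min_separation > 0)
  m <- min_separation / 2
  a <- barrier / m^4
  b <- 2 * barrier / m^2
  if (is.null(domain)) domain <- c(-2, 2) * min_separation
  analytic_potential(
    evaluator = function(s) a * s^4 - b * s^2,
    gradient = function(s) 4 * a * s^3 - 2 * b * s,
    domain = domain)
}

#' Generate a coupled loop + assembly trajectory
#'
#' The end-to-end fixture: two hidden-Markov CDR3-like backbone loops
#' (chains A and B) plus a rigid two-domain assembly whose interdomain
#' torsion is driven by the same hidden state (or decoupled, for null
#' controls). Ground-truth hidden states are returned.
#'
#' @param hmm an `hmm_dihedral_spec` driving the loop dihedrals; its
#'   psi/phi mean matrices are used for both loops.
#' @param angle_targets per-hidden-state interdomain torsion targets,
#'   degrees (length = number of hidden states).
#' @param angle_jitter_sd coordinate jitter on the assembly atoms, Angstrom.
#' @param coupled drive the torsion by the hidden state (TRUE) or by an
#'   independent uniform draw (FALSE; the shuffled null).
#' @return list with `trajectory`, `hidden` (1-based state per frame),
#'   `feature_selections` (CDR3 alpha/beta loops), `angle_selections`
#'   (the four assembly regions), and `angle_labels` (state driving the
#'   torsion per frame).
#' @export
generate_coupled_trajectory <- function(hmm, angle_targets,
                                        angle_jitter_sd = 0.5,
                                        coupled = TRUE) {
  stopifnot(inherits(hmm, "hmm_dihedral_spec"))
  n_h <- nrow(hmm$transition)
  if (length(angle_targets) != n_h)
    stop("need one angle target per hidden state")
  set.seed(hmm$seed)
  n_res <- ncol(hmm$psi_means)
  Fn <- hmm$n_frames
  hidden <- simulate_markov_chain(hmm$transition, Fn, seed = NULL)
  mk_loop <- function() {
    psi <- hmm$psi_means[hidden, , drop = FALSE] +
      matrix(stats::rnorm(Fn * n_res, sd = hmm$emission_sd), Fn, n_res)
    phi <- hmm$phi_means[hidden, , drop = FALSE] +
      matrix(stats::rnorm(Fn * n_res, sd = hmm$emission_sd), Fn, n_res)
    build_backbone_frames(phi, psi)
  }
  loop_a <- mk_loop()
  loop_b <- mk_loop()
  loop_b[, 1, ] <- loop_b[, 1, ] + 100      # keep chains apart
  ## assembly (same construction as generate_two_domain_trajectory)
  k <- 8
  centers <- list(cdr_a = c(10, 0, -5), v_a = c(0, 0, 0),
                  v_b = c(0, 0, 20), cdr_b = c(10, 0, 25))
  cloud <- function(center) {
    off <- matrix(stats::rnorm(3 * k, sd = 2), k, 3)
    off <- sweep(off, 2, colMeans(off))
    sweep(off, 2, center, `+`)
  }
  base <- rbind(cloud(centers$cdr_a), cloud(centers$v_a),
                cloud(centers$v_b), cloud(centers$cdr_b))
  base <- sweep(base, 2, c(-100, 0, 0), `+`)  # keep the assembly apart too
  angle_labels <- if (coupled) hidden else
    sample.int(n_h, Fn, replace = TRUE)
  n_loop <- 4 * n_res
  n_all <- 2 * n_loop + 4 * k
  coords <- array(NA_real_, dim = c(n_all, 3, Fn))
  coords[seq_len(n_loop), , ] <- loop_a
  coords[n_loop + seq_len(n_loop), , ] <- loop_b
  beta_rows <- (2 * k + 1):(4 * k)
  arows <- 2 * n_loop + seq_len(4 * k)
  ctr <- c(-100, 0, 0)
  for (f in seq_len(Fn)) {
    th <- deg2rad(angle_targets[angle_labels[f]])
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    xyz <- sweep(base, 2, ctr)
    xyz[beta_rows, ] <- xyz[beta_rows, ] %*% t(R)
    xyz <- sweep(xyz, 2, ctr, `+`)
    if (angle_jitter_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = angle_jitter_sd),
                          nrow(xyz), 3)
    coords[arows, , f] <- xyz
  }
  top <- structure3d(
    atom_name = c(rep(c("N", "CA", "C", "O"), 2 * n_res), rep("CA", 4 * k)),
    resid = c(rep(seq_len(n_res), each = 4), rep(seq_len(n_res), each = 4),
              301:(300 + k), 201:(200 + k), 201:(200 + k), 301:(300 + k)),
    chain = c(rep("A", n_loop), rep("B", n_loop),
              rep("A", 2 * k), rep("B", 2 * k)),
    element = c(rep(c("N", "C", "C", "O"), 2 * n_res), rep("C", 4 * k)),
    xyz = coords[, , 1])
  traj <- trajectory3d(top, coords, frame_interval = hmm$frame_interval)
  list(trajectory = traj, hidden = hidden, angle_labels = angle_labels,
       feature_selections = list(
         cdr3_alpha = region_selection("CDR3_alpha", "A", c(1, n_res)),
         cdr3_beta = region_selection("CDR3_beta", "B", c(1, n_res))),
       angle_selections = list(
         cdr_alpha = region_selection("CDR_loops_alpha", "A", c(301, 300 + k)),
         v_alpha = region_selection("V_alpha", "A", c(201, 200 + k)),
         v_beta = region_selection("V_beta", "B", c(201, 200 + k)),
         cdr_beta = region_selection("CDR_loops_beta", "B", c(301, 300 + k))))
}
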