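## Independent oracles and small fixture builders used across tests.

## Independent torsion oracle (projection formula, distinct from the
## package's cross-product route); fixes the sign convention.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  a <- atan2(y, x) * 180 / pi
  if (a <= -180) a + 360 else a
}

## Random rigid motion (proper rotation + translation).
random_rigid_motion <- function() {
  M <- matrix(rnorm(9), 3, 3)
  q <- qr(M)
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, rm) sweep(xyz %*% rm$R, 2, rm$t, `+`)

## Independent optimal-superposition RMSD oracle: Horn's closed-form
## quaternion method (eigenvector of the 4x4 key matrix), no SVD.
oracle_rmsd_horn <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  M <- crossprod(A0, B0)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,    -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,    -Sxx-Syy+Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A0^2) + sum(B0^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

## Brute-force O(n^3) average-linkage agglomeration with a height cutoff.
oracle_average_linkage <- function(D, cutoff) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    m <- length(clusters)
    if (m == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      d <- mean(D[clusters[[i]], clusters[[j]], drop = FALSE])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

## Partition-equality up to label permutation.
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(outer(a, a, `==`) == outer(b, b, `==`))
}

## Tiny hand-written PDB fixture (3 atoms) as text.
write_toy_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.679   6.623  -4.123  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

## Small backbone trajectory with prescribed psi/phi per frame.
toy_backbone_traj <- function(psi, phi = NULL, frame_interval = 1) {
  if (is.null(phi)) phi <- matrix(-60, nrow(psi), ncol(psi))
  co <- tcrmsm:::build_backbone_frames(phi, psi)
  tcrmsm:::trajectory3d(tcrmsm:::backbone_topology(ncol(psi)), co,
                        frame_interval = frame_interval)
}
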