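## Rigid-body superposition, RMSD seed clustering, and k-means microstating.

#' Optimal rigid superposition (Kabsch) and RMSD
#'
#' Least-squares rotation + translation of `mobile` onto `reference`
#' (proper rotation enforced via the determinant correction).
#'
#' @param mobile,reference n x 3 coordinate matrices (same n >= 3).
#' @param subset optional row indices used to fit the superposition
#'   (the RMSD is computed over the same subset).
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fitted
#'   map is x %*% R + t), `rmsd` (post-superposition, Angstrom), and
#'   `coords` (all mobile rows transformed).
#' @export
superpose <- function(mobile, reference, subset = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(subset)) subset <- seq_len(nrow(mobile))
  A <- mobile[subset, , drop = FALSE]
  B <- reference[subset, , drop = FALSE]
  if (nrow(A) < 3) stop("superposition needs at least 3 atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  ## collinearity check: centered coordinates must span a plane
  sv0 <- svd(A0)$d
  if (sv0[2] < 1e-9 * max(sv0[1], 1))
    stop("degenerate superposition subset: atoms are (nearly) collinear")
  H <- crossprod(A0, B0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  R <- t(R)  # so that x %*% R maps mobile frame onto reference frame
  tr <- cb - as.numeric(ca %*% R)
  fitted <- sweep(A %*% R, 2, tr, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  all_fit <- sweep(mobile %*% R, 2, tr, `+`)
  list(rotation = R, translation = tr, rmsd = rmsd, coords = all_fit)
}

pairwise_rmsd_matrix <- function(traj, atom_idx) {
  nf <- n_frames(traj)
  ## pre-superpose every frame onto frame 1, then pairwise-optimal RMSD
  frames <- lapply(seq_len(nf), function(i)
    frame_coords(traj, i)[atom_idx, , drop = FALSE])
  frames <- c(frames[1],
              lapply(frames[-1], function(f) superpose(f, frames[[1]])$coords))
  D <- matrix(0, nf, nf)
  if (nf > 1) for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
    D[i, j] <- D[j, i] <- superpose(frames[[i]], frames[[j]])$rmsd
  }
  if (!all(is.finite(D))) stop("non-finite values in the pairwise RMSD matrix")
  D
}

#' Average-linkage RMSD clustering of trajectory frames
#'
#' Agglomerative clustering on the pairwise post-superposition backbone RMSD
#' matrix; merging stops when the minimum average inter-cluster distance
#' exceeds `cutoff`. Representatives are medoids (minimal mean in-cluster
#' distance; ties to the lower frame index).
#'
#' @param traj a `trajectory3d`.
#' @param selection a `region_selection`; backbone atoms are used.
#' @param cutoff distance cutoff, Angstrom (default 1.2).
#' @return an object of class `cluster_result`: `labels` (1-based cluster id
#'   per frame), `representatives` (frame index per cluster), `cutoff`,
#'   `linkage`, `rmsd_matrix`.
#' @export
average_linkage_cluster <- function(traj, selection, cutoff = 1.2) {
  stopifnot(inherits(traj, "trajectory3d"), cutoff >= 0)
  idx <- resolve_selection(selection, traj$topology, backbone_only = TRUE)
  D <- pairwise_rmsd_matrix(traj, idx)
  nf <- nrow(D)
  if (nf == 1) {
    labels <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    labels <- unname(stats::cutree(hc, h = cutoff))
  }
  k <- max(labels)
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1) return(members)
    avg <- rowMeans(D[members, members, drop = FALSE])
    members[which.min(avg)]
  }, 1L)
  structure(list(labels = labels, representatives = reps,
                 cutoff = cutoff, linkage = "average", rmsd_matrix = D),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("average-linkage clustering:", length(x$labels), "frames ->",
      length(x$representatives), "clusters (cutoff", x$cutoff, "A)\n")
  invisible(x)
}

#' Export a cluster table as CSV (frame, cluster, is_representative)
#'
#' @param clusters a `cluster_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_cluster_table <- function(clusters, path) {
  df <- data.frame(frame = seq_along(clusters$labels),
                   cluster = clusters$labels,
                   is_representative =
                     seq_along(clusters$labels) %in% clusters$representatives)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## kmeans++ initial centers
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' k-means microstating of feature or tICA space
#'
#' kmeans++ initialization with a fixed seed, Lloyd iterations to
#' convergence (maximum center shift < `tol`). Empty clusters are re-seeded
#' at the point farthest from its current center. The within-cluster sum of
#' squares is asserted non-increasing across iterations.
#'
#' @param points numeric matrix (frames x dims) or `feature_matrix`.
#' @param k number of microstates (default 150).
#' @param seed RNG seed.
#' @param max_iter Lloyd iteration cap.
#' @param tol convergence threshold on the center shift.
#' @param frame_interval ns between frames (taken from `points` when it is a
#'   `feature_matrix`).
#' @return an object of class `microstates`: `assignment` (0-based state per
#'   frame), `centers` (k x dims), `n_states`, `objective` (per-iteration
#'   within-cluster sum of squares), `frame_interval`.
#' @export
kmeans_microstates <- function(points, k = 150, seed = 1, max_iter = 200,
                               tol = 1e-8, frame_interval = NULL) {
  if (is.null(frame_interval))
    frame_interval <- attr(points, "frame_interval") %||% 1
  X <- unclass(as.matrix(points))
  attributes(X) <- attributes(X)["dim"]
  n_distinct <- nrow(unique(X))
  if (k > n_distinct)
    stop("k (", k, ") exceeds the number of distinct points (", n_distinct, ")")
  set.seed(seed)
  centers <- kmeanspp_init(X, k)
  obj_trace <- numeric(0)
  assign_pts <- function(C) {
    ## squared distances via the expansion |x|^2 - 2 x.c + |c|^2
    d2 <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
      outer(rep(1, nrow(X)), rowSums(C^2))
    list(lab = max.col(-d2, ties.method = "first"),
         d2 = pmax(d2[cbind(seq_len(nrow(X)), max.col(-d2, ties.method = "first"))], 0))
  }
  for (it in seq_len(max_iter)) {
    a <- assign_pts(centers)
    ## empty-cluster repair: re-seed at the point farthest from its center
    empty <- setdiff(seq_len(k), unique(a$lab))
    while (length(empty) > 0) {
      far <- which.max(a$d2)
      centers[empty[1], ] <- X[far, ]
      a <- assign_pts(centers)
      empty <- setdiff(seq_len(k), unique(a$lab))
    }
    obj <- sum(a$d2)
    if (length(obj_trace) > 0 && obj > utils::tail(obj_trace, 1) + 1e-7 * (1 + obj))
      stop("internal error: k-means objective increased")
    obj_trace <- c(obj_trace, obj)
    new_centers <- centers
    for (j in unique(a$lab))
      new_centers[j, ] <- colMeans(X[a$lab == j, , drop = FALSE])
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  a <- assign_pts(centers)
  structure(list(assignment = a$lab - 1L, centers = centers, n_states = k,
                 objective = obj_trace, frame_interval = frame_interval,
                 seed = seed),
            class = "microstates")
}

#' @export
print.microstates <- function(x, ...) {
  cat("k-means microstates: k =", x$n_states, "over", length(x$assignment),
      "frames;", length(x$objective), "Lloyd iterations\n")
  invisible(x)
}

#' Nearest microstate center for new points
#'
#' @param object a `microstates` model.
#' @param newdata numeric matrix of points (rows) in the same space.
#' @param ... unused.
#' @return 0-based microstate ids.
#' @export
predict.microstates <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  C <- object$centers
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  max.col(-d2, ties.method = "first") - 1L
}
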