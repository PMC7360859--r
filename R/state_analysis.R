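## Macrostate-conditioned interdomain-angle distributions, their pairwise
## Kolmogorov-Smirnov comparison, and per-residue RMSF.

#' Macrostate-conditioned interdomain-angle distributions
#'
#' Splits an angle series by the per-frame macrostate assignment and
#' summarizes each macrostate's distribution. Circular mean/variance by
#' default (the distributions live on a circle); linear statistics are
#' available for comparability with conventions that ignore wraparound.
#'
#' @param angles an `angle_series` (or numeric vector of degrees).
#' @param assignment integer macro id per frame (NA = unassignable; such
#'   frames are excluded with a message).
#' @param circular use circular statistics (default TRUE).
#' @return an object of class `angle_distributions`: data.frame `summary`
#'   (macrostate, n, mean_deg, variance_deg2, flagged_empty) plus `samples`
#'   (list of per-macrostate angle vectors).
#' @export
macrostate_angle_distributions <- function(angles, assignment,
                                           circular = TRUE) {
  a <- as.numeric(angles)
  if (length(a) != length(assignment))
    stop("angle series and assignment must have equal length")
  drop_n <- sum(is.na(assignment))
  if (drop_n > 0)
    message(drop_n, " unassignable frame(s) excluded from angle distributions")
  keep <- !is.na(assignment)
  a <- a[keep]; g <- assignment[keep]
  ids <- seq_len(max(g))
  samples <- lapply(ids, function(m) a[g == m])
  rows <- lapply(ids, function(m) {
    x <- samples[[m]]
    if (length(x) == 0)
      return(data.frame(macrostate = m, n = 0L, mean_deg = NA_real_,
                        variance_deg2 = NA_real_, flagged_empty = TRUE))
    data.frame(macrostate = m, n = length(x),
               mean_deg = if (circular) circular_mean(x) else mean(x),
               variance_deg2 = if (circular) circular_variance(x)
                               else stats::var(x),
               flagged_empty = FALSE)
  })
  structure(list(summary = do.call(rbind, rows), samples = samples,
                 circular = circular, n_excluded = drop_n),
            class = "angle_distributions")
}

#' @export
print.angle_distributions <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |ECDF_a - ECDF_b|; p-value from the asymptotic Kolmogorov
#' distribution with the effective sample size n1 n2 / (n1 + n2).
#'
#' @param a,b numeric samples (non-empty).
#' @param stride optional thinning stride applied to both samples before
#'   testing (MD frames are autocorrelated; thinning is the user's call).
#' @return an object of class `ks_result`: `statistic` (D), `p_value`,
#'   `n1`, `n2`.
#' @export
ks_two_sample <- function(a, b, stride = 1) {
  if (length(a) == 0 || length(b) == 0)
    stop("KS test requires non-empty samples")
  if (stride > 1) {
    message("thinning samples by stride ", stride,
            " before the KS test (autocorrelation mitigation)")
    a <- a[seq(1, length(a), by = stride)]
    b <- b[seq(1, length(b), by = stride)]
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(list(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 n1 = length(a), n2 = length(b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Pairwise KS comparison of macrostate angle distributions
#'
#' @param distributions an `angle_distributions` object or a list of
#'   numeric samples.
#' @param stride optional thinning stride (see [ks_two_sample()]).
#' @param alpha significance level for the Bonferroni-adjusted column.
#' @return an object of class `ks_table`: `D` and `p` symmetric matrices
#'   (diagonal D = 0, p = 1), `p_bonferroni`, `n` per macrostate.
#' @export
pairwise_ks_table <- function(distributions, stride = 1, alpha = 0.05) {
  samples <- if (inherits(distributions, "angle_distributions"))
    distributions$samples else distributions
  m <- length(samples)
  if (m < 2) stop("need at least 2 distributions to compare")
  D <- matrix(0, m, m); P <- matrix(1, m, m)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    if (length(samples[[i]]) == 0 || length(samples[[j]]) == 0)
      stop("macrostate ", if (length(samples[[i]]) == 0) i else j,
           " has an empty angle sample")
    r <- ks_two_sample(samples[[i]], samples[[j]], stride = stride)
    D[i, j] <- D[j, i] <- r$statistic
    P[i, j] <- P[j, i] <- r$p_value
  }
  n_tests <- m * (m - 1) / 2
  Pb <- pmin(P * n_tests, 1)
  diag(Pb) <- 1
  structure(list(D = D, p = P, p_bonferroni = Pb,
                 n = vapply(samples, length, 1L), alpha = alpha),
            class = "ks_table")
}

#' @export
print.ks_table <- function(x, ...) {
  cat("pairwise KS D matrix (", nrow(x$D), " macrostates):\n", sep = "")
  print(signif(x$D, 3))
  invisible(x)
}

#' Export a pairwise KS table as CSV
#'
#' @param x a `ks_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_ks_table <- function(x, path) {
  m <- nrow(x$D)
  pairs <- which(upper.tri(x$D), arr.ind = TRUE)
  df <- data.frame(macro_i = pairs[, 1], macro_j = pairs[, 2],
                   D = x$D[pairs], p_value = x$p[pairs],
                   p_bonferroni = x$p_bonferroni[pairs],
                   n_i = x$n[pairs[, 1]], n_j = x$n[pairs[, 2]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the subset-average structure in two passes
#' (superpose to the first frame, average, re-superpose to the average);
#' RMSF_r is the root-mean-square deviation of residue r's backbone
#' centroid from its mean position.
#'
#' @param traj a `trajectory3d`.
#' @param selection a `region_selection` (backbone atoms used).
#' @param frames frame indices to include (default all; >= 2 required).
#' @return data.frame with columns `resid`, `chain`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection, frames = NULL) {
  stopifnot(inherits(traj, "trajectory3d"))
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (length(frames) < 2) stop("RMSF needs at least 2 frames")
  idx <- resolve_selection(selection, traj$topology, backbone_only = TRUE)
  top <- traj$topology
  coords <- lapply(frames, function(i)
    frame_coords(traj, i)[idx, , drop = FALSE])
  ## pass 1: superpose to the first frame, average
  ref <- coords[[1]]
  fitted <- c(list(ref), lapply(coords[-1], function(f) superpose(f, ref)$coords))
  avg <- Reduce(`+`, fitted) / length(fitted)
  ## pass 2: re-superpose to the average
  fitted <- lapply(coords, function(f) superpose(f, avg)$coords)
  avg <- Reduce(`+`, fitted) / length(fitted)
  key <- paste(top$chain[idx], top$resid[idx], top$icode[idx], sep = "|")
  res_keys <- unique(key)
  out <- vapply(res_keys, function(k) {
    rows <- which(key == k)
    cent <- t(vapply(fitted, function(f)
      colMeans(f[rows, , drop = FALSE]), numeric(3)))
    mean_cent <- colMeans(cent)
    sqrt(mean(rowSums(sweep(cent, 2, mean_cent)^2)))
  }, 0)
  data.frame(resid = top$resid[idx][match(res_keys, key)],
             chain = top$chain[idx][match(res_keys, key)],
             rmsf = unname(out))
}
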