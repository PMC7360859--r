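## Time-lagged independent component analysis with the symmetrized
## (reversible) covariance estimator, and free-energy surfaces over the
## leading components.

#' Fit time-lagged independent component analysis
#'
#' Estimates instantaneous (C0) and time-lagged (Ct) covariances over one or
#' several trajectories (lagged pairs never span trajectory boundaries), with
#' Ct symmetrized, and solves the generalized symmetric eigenproblem
#' Ct v = lambda C0 v after adding `reg` to C0's diagonal. Components are
#' normalized to unit instantaneous covariance.
#'
#' @param features a `feature_matrix`, plain matrix, or list of those (one
#'   per trajectory, identical feature definitions).
#' @param lag lag time in ns (positive multiple of the frame interval).
#' @param n_components number of components retained (default 2).
#' @param reg variance floor added to C0's diagonal (default 1e-6).
#' @param frame_interval ns between frames, when `features` carries none.
#' @return an object of class `tica`: `mean`, `eigenvalues` (descending,
#'   clipped to (-1, 1] for reporting), `components` (features x
#'   n_components), `lag` (ns), `lag_frames`, `reg`, `labels`.
#' @export
fit_tica <- function(features, lag, n_components = 2, reg = 1e-6,
                     frame_interval = NULL) {
  if (!is.list(features)) features <- list(features)
  fi <- frame_interval %||% attr(features[[1]], "frame_interval") %||% 1
  labels <- attr(features[[1]], "labels")
  lag_frames <- as.integer(round(lag / fi))
  if (lag_frames < 1 || abs(lag_frames * fi - lag) > 1e-8 * max(lag, 1))
    stop("lag (", lag, " ns) must be a positive multiple of the frame interval (",
         fi, " ns)")
  Xs <- lapply(features, function(f) {
    m <- unclass(as.matrix(f)); attributes(m) <- attributes(m)["dim"]; m
  })
  short <- vapply(Xs, nrow, 1L) <= lag_frames
  if (any(short))
    stop("lag (", lag_frames, " frames) must be shorter than every trajectory")
  d <- ncol(Xs[[1]])
  n_pairs <- 0
  sum_x <- numeric(d)
  for (X in Xs) {
    Tn <- nrow(X)
    h <- seq_len(Tn - lag_frames)
    n_pairs <- n_pairs + length(h)
    sum_x <- sum_x + colSums(X[h, , drop = FALSE]) +
      colSums(X[h + lag_frames, , drop = FALSE])
  }
  mu <- sum_x / (2 * n_pairs)
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d)
  for (X in Xs) {
    Tn <- nrow(X)
    h <- seq_len(Tn - lag_frames)
    Xh <- sweep(X[h, , drop = FALSE], 2, mu)
    Xt <- sweep(X[h + lag_frames, , drop = FALSE], 2, mu)
    C0 <- C0 + crossprod(Xh) + crossprod(Xt)
    Ct <- Ct + crossprod(Xh, Xt)
  }
  C0 <- C0 / (2 * n_pairs)
  Ct <- Ct / n_pairs
  Ct <- (Ct + t(Ct)) / 2                      # symmetrized (reversible) estimate
  C0r <- C0 + diag(reg, d)
  e0 <- eigen(C0r, symmetric = TRUE)
  if (min(e0$values) <= 0)
    stop("singular instantaneous covariance; increase reg")
  S <- e0$vectors %*% (t(e0$vectors) / sqrt(e0$values))
  M <- S %*% Ct %*% S
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  n_components <- min(n_components, d)
  comps <- S %*% ee$vectors[, seq_len(n_components), drop = FALSE]
  evals <- pmin(pmax(ee$values, -1), 1)       # clipped for reporting
  structure(list(mean = mu, eigenvalues = evals, components = comps,
                 lag = lag, lag_frames = lag_frames, reg = reg,
                 labels = labels, n_components = n_components,
                 frame_interval = fi),
            class = "tica")
}

#' @export
print.tica <- function(x, ...) {
  cat("tICA model: lag", x$lag, "ns,", x$n_components, "components\n")
  cat("leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.tica <- function(object, ...) {
  lam <- object$eigenvalues
  its <- ifelse(lam > 0 & lam < 1, -object$lag / log(lam), NA_real_)
  out <- data.frame(component = seq_along(lam), eigenvalue = lam,
                    implied_timescale_ns = its)
  class(out) <- c("summary.tica", "data.frame")
  out
}

#' Project features onto tICA components
#'
#' Mean-centered linear map; projecting the training mean gives zero.
#'
#' @param object a `tica` model.
#' @param newdata a `feature_matrix` or matrix with the model's features.
#' @param ... unused.
#' @return numeric matrix frames x n_components.
#' @export
predict.tica <- function(object, newdata, ...) {
  lab <- attr(newdata, "labels")
  if (!is.null(lab) && !is.null(object$labels) && !identical(lab, object$labels))
    stop("feature labels do not match the tICA model")
  X <- unclass(as.matrix(newdata)); attributes(X) <- attributes(X)["dim"]
  if (ncol(X) != length(object$mean))
    stop("feature count (", ncol(X), ") does not match the tICA model (",
         length(object$mean), ")")
  sweep(X, 2, object$mean) %*% object$components
}

#' Project a single structure into tICA space
#'
#' Featurizes one structure with the same selections/angles used in
#' training and maps it through the fitted model; used to overlay crystal
#' structures on the free-energy landscape.
#'
#' @param model a `tica` model.
#' @param structure a `structure3d`.
#' @param selections the `region_selection` list used for training features.
#' @param angles dihedral kinds used for training features.
#' @return length `n_components` numeric point.
#' @export
project_structure <- function(model, structure, selections,
                              angles = c("psi", "phi")) {
  traj <- trajectory3d(structure, structure$xyz, frame_interval = 1)
  fm <- psi_phi_features(traj, selections, angles = angles)
  as.numeric(predict(model, fm))
}

#' Free-energy surface over projected coordinates
#'
#' F = -kB T ln(bin density), shifted so the occupied-bin minimum is zero.
#' Empty bins are marked unsampled (NA), not given a number.
#'
#' @param projections numeric matrix (frames x 1 or 2).
#' @param temperature K (default 300).
#' @param bins bins per axis (>= 2).
#' @return an object of class `free_energy_surface`: `edges` (list per
#'   axis), `values` (kcal/mol, NA where unsampled), `counts`, `temperature`.
#' @export
free_energy_surface <- function(projections, temperature = 300, bins = 50) {
  P <- as.matrix(projections)
  if (nrow(P) < 1) stop("need at least one projected point")
  if (bins < 2) stop("need at least 2 bins per axis")
  nd <- ncol(P)
  if (!nd %in% c(1, 2)) stop("free-energy surfaces support 1 or 2 dimensions")
  edges <- lapply(seq_len(nd), function(j) {
    r <- range(P[, j])
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1)
  })
  bin_of <- function(x, e) pmin(pmax(findInterval(x, e, all.inside = TRUE), 1),
                                length(e) - 1)
  if (nd == 1) {
    counts <- tabulate(bin_of(P[, 1], edges[[1]]), nbins = bins)
  } else {
    i <- bin_of(P[, 1], edges[[1]]); j <- bin_of(P[, 2], edges[[2]])
    counts <- matrix(tabulate((j - 1) * bins + i, nbins = bins * bins),
                     bins, bins)
  }
  dens <- counts / nrow(P)
  f <- ifelse(counts > 0, -KB_KCAL * temperature * log(dens), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  structure(list(edges = edges, values = f, counts = counts,
                 temperature = temperature),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat("free-energy surface:", paste(dim(as.matrix(x$values)), collapse = " x "),
      "bins,", sum(x$counts > 0), "occupied; max F =",
      signif(max(x$values, na.rm = TRUE), 4), "kcal/mol\n")
  invisible(x)
}

#' Export a free-energy surface as a CSV grid
#'
#' @param fes a `free_energy_surface`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_fes <- function(fes, path) {
  mids <- lapply(fes$edges, function(e) (e[-1] + e[-length(e)]) / 2)
  if (length(mids) == 1) {
    df <- data.frame(x = mids[[1]], free_energy = fes$values,
                     count = fes$counts)
  } else {
    g <- expand.grid(x = mids[[1]], y = mids[[2]])
    df <- data.frame(g, free_energy = as.vector(fes$values),
                     count = as.vector(fes$counts))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a tICA model to JSON
#'
#' @param model a `tica`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_tica <- function(model, path) {
  jsonlite::write_json(list(mean = model$mean, eigenvalues = model$eigenvalues,
                            components = model$components, lag_ns = model$lag,
                            reg = model$reg, labels = model$labels),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
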