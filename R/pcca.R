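## PCCA+ coarse-graining of microstates into metastable macrostates, and
## assignment of external structures to macrostates.

#' PCCA+ macrostate decomposition
#'
#' Robust Perron Cluster Analysis: fuzzy memberships are obtained from the
#' simplex structure of the leading right eigenvectors of the reversible
#' transition matrix. Spanning vertices are located with the inner-simplex
#' (index) algorithm; the transformation is then made feasible (memberships
#' in [0, 1], rows summing to 1) by the standard first-row fill. Crisp
#' assignment is the argmax membership (ties to the lower macrostate id).
#'
#' @param model an `msm_model`.
#' @param n_macro number of macrostates (2 <= n_macro <= n_states).
#' @return an object of class `macrostates`: `memberships` (n_micro x
#'   n_macro), `crisp_assignment` (1-based macro id per microstate),
#'   `macro_stationary` (aggregated over the crisp assignment), `n_macro`,
#'   `spectral_gap_ratio`.
#' @export
pcca_plus <- function(model, n_macro) {
  stopifnot(inherits(model, "msm_model"))
  n <- nrow(model$transition_matrix)
  if (n_macro < 2 || n_macro > n)
    stop("n_macro must be between 2 and the number of microstates (", n, ")")
  lam <- model$eigenvalues
  if (n_macro < n && lam[n_macro] <= 0)
    stop("no spectral structure for ", n_macro, " macrostates: eigenvalue ",
         n_macro, " is ", signif(lam[n_macro], 3))
  gap <- if (n_macro < n) (lam[n_macro] - lam[n_macro + 1]) /
    max(1 - lam[n_macro], .Machine$double.eps) else NA_real_
  X <- model$eigenvectors[, seq_len(n_macro), drop = FALSE]
  X[, 1] <- 1                              # constant eigenvector, exactly
  ## inner-simplex vertex search: pick the most distant row, then repeatedly
  ## the row farthest from the affine span of those already picked
  idx <- integer(n_macro)
  idx[1] <- which.max(sqrt(rowSums(X^2)))
  Y <- sweep(X, 2, X[idx[1], ])
  for (k in 2:n_macro) {
    idx[k] <- which.max(sqrt(rowSums(Y^2)))
    v <- Y[idx[k], ]
    v <- v / sqrt(sum(v^2))
    Y <- Y - outer(as.numeric(Y %*% v), v)
  }
  A <- solve(X[idx, , drop = FALSE])
  chi <- X %*% A
  ## feasibility fill: raise the affine part so chi >= 0, then renormalize
  if (min(chi) < 0) {
    for (j in seq_len(n_macro)) {
      off <- X[, -1, drop = FALSE] %*% A[-1, j, drop = FALSE]
      A[1, j] <- -min(off)
    }
    s1 <- sum(A[1, ])
    if (s1 <= 0) stop("PCCA+ feasibility fill failed (degenerate simplex)")
    A <- A / s1
    chi <- X %*% A
  }
  chi <- pmax(chi, 0)
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  if (length(unique(crisp)) < n_macro)
    warning("PCCA+: some macrostates have no crisp microstate members")
  macro_pi <- vapply(seq_len(n_macro), function(a)
    sum(model$stationary[crisp == a]), 0)
  structure(list(memberships = chi, crisp_assignment = crisp,
                 macro_stationary = macro_pi, n_macro = n_macro,
                 spectral_gap_ratio = gap, model = model),
            class = "macrostates")
}

#' @export
print.macrostates <- function(x, ...) {
  cat("PCCA+ macrostates:", x$n_macro, "macrostates over",
      nrow(x$memberships), "microstates\n")
  cat("stationary probabilities:",
      paste(signif(x$macro_stationary, 3), collapse = " "), "\n")
  invisible(x)
}

#' Map frames of a discrete trajectory to macrostates
#'
#' Microstates outside the model's active set map to NA (unassignable).
#'
#' @param macro a `macrostates` object.
#' @param dtraj 0-based microstate ids per frame (original state space).
#' @return integer macro id per frame (1-based; NA where unassignable).
#' @export
frames_to_macrostates <- function(macro, dtraj) {
  dtraj <- if (inherits(dtraj, "microstates")) dtraj$assignment else dtraj
  pos <- match(as.integer(dtraj) + 1L, macro$model$active_set)
  out <- rep(NA_integer_, length(dtraj))
  ok <- !is.na(pos)
  out[ok] <- macro$crisp_assignment[pos[ok]]
  out
}

#' Assign a structure (or feature vector) to a kinetic macrostate
#'
#' featurize -> tICA projection -> nearest k-means center -> crisp
#' macrostate of that microstate.
#'
#' @param x a `structure3d`, or a 1-row `feature_matrix`/matrix of features.
#' @param tica_model the fitted `tica` model.
#' @param micro the `microstates` (k-means) model in tICA space.
#' @param macro the `macrostates` model.
#' @param selections,angles featurization definition (needed when `x` is a
#'   `structure3d`).
#' @return 1-based macrostate id, or NA when the nearest microstate lies
#'   outside the MSM active set (unassignable).
#' @export
assign_to_macrostate <- function(x, tica_model, micro, macro,
                                 selections = NULL, angles = c("psi", "phi")) {
  if (inherits(x, "structure3d")) {
    if (is.null(selections))
      stop("selections are required to featurize a structure")
    y <- matrix(project_structure(tica_model, x, selections, angles), nrow = 1)
  } else {
    y <- predict(tica_model, x)
  }
  ms <- predict(micro, y)
  out <- frames_to_macrostates(macro, ms)
  if (length(out) == 1) out[[1]] else out
}
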