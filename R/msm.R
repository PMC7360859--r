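## Markov-state model estimation: transition counts, connectivity,
## reversible maximum-likelihood transition matrices, implied timescales
## and mean first-passage times.

as_dtraj_list <- function(dtrajs) {
  if (is.list(dtrajs) && !inherits(dtrajs, "microstates")) {
    lapply(dtrajs, function(d)
      as.integer(if (inherits(d, "microstates")) d$assignment else d))
  } else if (inherits(dtrajs, "microstates")) {
    list(as.integer(dtrajs$assignment))
  } else list(as.integer(dtrajs))
}

#' Count microstate transitions at a lag
#'
#' Sliding-window counts: C[i, j] = number of (t, t + lag) pairs observing
#' states (i, j), summed over trajectories.
#'
#' @param dtrajs 0-based discrete trajectory (integer vector), a
#'   `microstates` object, or a list of either.
#' @param lag lag in frames (>= 1, shorter than every trajectory).
#' @param n_states number of states (default: 1 + max observed id).
#' @return integer n_states x n_states count matrix.
#' @export
count_transitions <- function(dtrajs, lag, n_states = NULL) {
  dts <- as_dtraj_list(dtrajs)
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be >= 1 frame")
  if (any(vapply(dts, length, 1L) <= lag))
    stop("lag (", lag, " frames) must be shorter than every trajectory")
  if (is.null(n_states)) n_states <- max(unlist(dts)) + 1L
  C <- matrix(0L, n_states, n_states)
  for (d in dts) {
    Tn <- length(d)
    from <- d[seq_len(Tn - lag)] + 1L
    to <- d[seq_len(Tn - lag) + lag] + 1L
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    C <- C + matrix(as.integer(tab), n_states, n_states)
  }
  C
}

#' Largest strongly connected set of the count graph
#'
#' States i, j are connected when counts allow a directed path both ways.
#' Among maximal strongly connected components the one with the largest
#' total outgoing counts is returned (ties to more states, then lower ids).
#'
#' @param counts square count matrix.
#' @return sorted integer vector of 1-based state indices.
#' @export
largest_connected_set <- function(counts) {
  n <- nrow(counts)
  A <- counts > 0
  ## Tarjan-free SCC via reachability (n is small at desk scale)
  reach <- A | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n); cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[reach[i, ] & reach[, i]] <- cid
    }
  }
  weight <- vapply(seq_len(cid), function(k) sum(counts[comp == k, , drop = FALSE]), 0)
  size <- tabulate(comp, cid)
  best <- order(-weight, -size)[1]
  sort(which(comp == best))
}

#' Reversible maximum-likelihood Markov-state model
#'
#' Estimates the row-stochastic transition matrix maximizing the likelihood
#' of the counts under detailed balance, by the classic self-consistent
#' fixed-point iteration; the stationary distribution comes from the
#' converged unnormalized flux matrix.
#'
#' @param counts count matrix (from [count_transitions()]); restricted to
#'   its largest connected set automatically.
#' @param lag lag time in ns used for reporting kinetics.
#' @param tol relative convergence tolerance (default 1e-10).
#' @param max_iter iteration cap.
#' @return an object of class `msm_model`: `count_matrix`,
#'   `transition_matrix`, `stationary`, `lag` (ns), `active_set` (1-based
#'   indices into the original state space), `eigenvalues`.
#' @export
estimate_msm <- function(counts, lag = 1, tol = 1e-10, max_iter = 1e6) {
  active <- largest_connected_set(counts)
  C <- counts[active, active, drop = FALSE]
  n <- nrow(C)
  Csym <- C + t(C)
  ci <- rowSums(C)
  if (any(ci == 0)) stop("state with no outgoing counts in the active set")
  x <- Csym / sum(Csym)
  xi <- rowSums(x)
  it <- 0
  repeat {
    it <- it + 1
    denom <- outer(ci / xi, ci / xi, `+`)
    x_new <- Csym / denom
    x_new <- x_new / sum(x_new)
    xi_new <- rowSums(x_new)
    delta <- max(abs(x_new - x) / pmax(x_new, 1e-300))
    x <- x_new; xi <- xi_new
    if (delta < tol) break
    if (it >= max_iter)
      stop("reversible MLE did not converge in ", max_iter,
           " iterations (residual ", signif(delta, 3), ")")
  }
  T_mat <- x / xi
  pi_vec <- xi / sum(xi)
  ev <- msm_spectrum(T_mat, pi_vec)
  structure(list(count_matrix = C, transition_matrix = T_mat,
                 stationary = pi_vec, lag = lag, active_set = active,
                 eigenvalues = ev$values, eigenvectors = ev$vectors,
                 reversible = TRUE),
            class = "msm_model")
}

## Real spectrum of a reversible T via the symmetric conjugate
## S = D^{1/2} T D^{-1/2}; returns right eigenvectors of T, descending.
msm_spectrum <- function(T_mat, pi_vec) {
  sq <- sqrt(pi_vec)
  S <- T_mat * outer(sq, 1 / sq)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vecs <- e$vectors / sq            # right eigenvectors of T (columns)
  ## normalize: pi-weighted 2-norm = 1; sign: first component positive
  for (j in seq_len(ncol(vecs))) {
    nrm <- sqrt(sum(pi_vec * vecs[, j]^2))
    vecs[, j] <- vecs[, j] / nrm
    if (vecs[1, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(values = e$values, vectors = vecs)
}

#' @export
print.msm_model <- function(x, ...) {
  cat("reversible MSM:", nrow(x$transition_matrix), "states, lag", x$lag, "ns\n")
  cat("leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.msm_model <- function(object, ...) {
  lam <- object$eigenvalues
  its <- c(NA_real_, vapply(lam[-1], function(l)
    if (is.na(l) || l <= 0 || l >= 1) NA_real_ else -object$lag / log(l), 0))
  data.frame(eigenvalue = lam, implied_timescale_ns = its,
             stationary = object$stationary[seq_along(lam)])
}

#' Implied relaxation timescales across lag times
#'
#' t_i(tau) = -tau / ln lambda_i(tau) for eigenvalues in (0, 1); negative
#' eigenvalues yield NA (undefined), unit eigenvalues Inf.
#'
#' @param models list of `msm_model`s estimated at different lags, or a
#'   single model.
#' @param n_timescales how many (excluding the stationary process).
#' @return data.frame with columns `lag_ns`, `timescale_index`,
#'   `timescale_ns`.
#' @export
implied_timescales <- function(models, n_timescales = 3) {
  if (inherits(models, "msm_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    lam <- m$eigenvalues[-1]
    k <- min(n_timescales, length(lam))
    ts <- vapply(lam[seq_len(k)], function(l) {
      if (is.na(l)) return(NA_real_)
      if (l >= 1) return(Inf)
      if (l <= 0) return(NA_real_)
      -m$lag / log(l)
    }, 0)
    data.frame(lag_ns = m$lag, timescale_index = seq_len(k) + 1,
               timescale_ns = ts)
  })
  do.call(rbind, rows)
}

#' Mean first-passage time between state sets
#'
#' Solves the standard linear system tau_i = lag + sum_j T[i, j] tau_j over
#' non-target states (tau = 0 on the target); the source value is the
#' stationary-weighted average over the source set.
#'
#' @param model an `msm_model`.
#' @param source,target disjoint non-empty 1-based state-index vectors
#'   (within the active-set-restricted model).
#' @return MFPT in ns (Inf when the target is unreachable).
#' @export
mfpt <- function(model, source, target) {
  T_mat <- model$transition_matrix
  n <- nrow(T_mat)
  source <- as.integer(source); target <- as.integer(target)
  if (length(unique(target)) == n) return(0)  # already there: no passage
  if (length(source) == 0 || length(target) == 0)
    stop("source and target must be non-empty")
  if (length(intersect(source, target)) > 0)
    stop("source and target sets must be disjoint")
  free <- setdiff(seq_len(n), target)
  A <- diag(length(free)) - T_mat[free, free, drop = FALSE]
  tau <- tryCatch(solve(A, rep(model$lag, length(free))),
                  error = function(e) rep(Inf, length(free)))
  tau_full <- numeric(n)
  tau_full[free] <- tau
  w <- model$stationary[source]
  sum(w * tau_full[source]) / sum(w)
}

#' Pairwise macrostate mean first-passage times
#'
#' @param model an `msm_model`.
#' @param macro a `macrostates` object (crisp assignment groups microstates).
#' @return n_macro x n_macro matrix of MFPTs (ns), 0 on the diagonal.
#' @export
macro_mfpt_matrix <- function(model, macro) {
  m <- macro$n_macro
  M <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) if (a != b) {
    src <- which(macro$crisp_assignment == a)
    tgt <- which(macro$crisp_assignment == b)
    M[a, b] <- mfpt(model, src, tgt)
  }
  M
}
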