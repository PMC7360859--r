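## Chapman-Kolmogorov validation of Markov-state models.

## Bootstrap resample of trajectories; single trajectories are resampled as
## contiguous blocks (~10 lags long) so bands exist either way.
bootstrap_dtrajs <- function(dts, lag) {
  if (length(dts) > 1) {
    dts[sample.int(length(dts), length(dts), replace = TRUE)]
  } else {
    d <- dts[[1]]
    bl <- max(10 * lag, 50)
    starts <- seq(1, length(d), by = bl)
    blocks <- lapply(starts, function(s) d[s:min(s + bl - 1, length(d))])
    blocks <- blocks[vapply(blocks, length, 1L) > lag]
    blocks[sample.int(length(blocks), length(blocks), replace = TRUE)]
  }
}

## Set-stay probability: w_A^T [T]^k 1_A with w_A = pi restricted to A.
set_stay_probability <- function(T_mat, pi_vec, members, k = 1) {
  Tk <- diag(nrow(T_mat))
  for (i in seq_len(k)) Tk <- Tk %*% T_mat
  w <- pi_vec[members] / sum(pi_vec[members])
  ind <- as.numeric(seq_len(nrow(T_mat)) %in% members)
  sum(w * (Tk[members, , drop = FALSE] %*% ind))
}

#' Chapman-Kolmogorov test of an MSM
#'
#' For each macro-set A and lag multiple k, compares the model prediction
#' (probability of remaining in A after propagating [T(tau)]^k) against the
#' same probability under a model re-estimated at lag k*tau. Uncertainty
#' bands on the re-estimates come from a bootstrap over trajectories
#' (block bootstrap for a single trajectory).
#'
#' @param dtrajs discrete trajectory(ies), 0-based, or `microstates`.
#' @param model the `msm_model` estimated at the base lag.
#' @param macro a `macrostates` object (its crisp sets are tested), or an
#'   integer n_macro to compute PCCA+ internally.
#' @param lag_frames the base lag in frames at which `model`'s counts were
#'   taken (default 1).
#' @param multiples integer lag multiples to test (default 1:5).
#' @param n_boot bootstrap resamples (default 100).
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `ck_report`: data.frame `table` with columns
#'   macro_set, multiple, predicted, estimated, lower, upper, ok, flagged.
#' @export
chapman_kolmogorov <- function(dtrajs, model, macro, lag_frames = 1,
                               multiples = 1:5, n_boot = 100, seed = 1) {
  dts <- as_dtraj_list(dtrajs)
  if (!inherits(macro, "macrostates")) macro <- pcca_plus(model, macro)
  base_lag <- as.integer(lag_frames)
  n_states_orig <- max(unlist(dts)) + 1L
  sets <- lapply(seq_len(macro$n_macro), function(a)
    which(macro$crisp_assignment == a))
  set.seed(seed)
  rows <- list()
  for (k in sort(unique(as.integer(multiples)))) {
    lag_k <- base_lag * k
    enough <- any(vapply(dts, length, 1L) > lag_k)
    flagged <- !enough
    est_model <- NULL
    if (enough) {
      usable <- dts[vapply(dts, length, 1L) > lag_k]
      Ck <- count_transitions(usable, lag_k, n_states = n_states_orig)
      Ck <- Ck[model$active_set, model$active_set, drop = FALSE]
      est_model <- tryCatch(estimate_msm(Ck, lag = model$lag * k),
                            error = function(e) NULL)
    }
    boot_vals <- NULL
    if (enough && !is.null(est_model)) {
      boot_vals <- matrix(NA_real_, n_boot, length(sets))
      for (b in seq_len(n_boot)) {
        bs <- bootstrap_dtrajs(dts, lag_k)
        bs <- bs[vapply(bs, length, 1L) > lag_k]
        if (length(bs) == 0) next
        Cb <- count_transitions(bs, lag_k, n_states = n_states_orig)
        Cb <- Cb[model$active_set, model$active_set, drop = FALSE]
        mb <- tryCatch(estimate_msm(Cb, lag = model$lag * k),
                       error = function(e) NULL)
        if (is.null(mb)) next
        act <- mb$active_set
        for (a in seq_along(sets)) {
          mem <- match(sets[[a]], act)
          mem <- mem[!is.na(mem)]
          if (length(mem) > 0)
            boot_vals[b, a] <- set_stay_probability(mb$transition_matrix,
                                                    mb$stationary, mem)
        }
      }
    }
    for (a in seq_along(sets)) {
      pred <- set_stay_probability(model$transition_matrix, model$stationary,
                                   sets[[a]], k = k)
      est <- low <- up <- NA_real_
      if (enough && !is.null(est_model)) {
        act <- est_model$active_set
        mem <- match(sets[[a]], act)
        mem <- mem[!is.na(mem)]
        if (length(mem) > 0)
          est <- set_stay_probability(est_model$transition_matrix,
                                      est_model$stationary, mem)
        bv <- boot_vals[, a]
        bv <- bv[is.finite(bv)]
        if (length(bv) >= 10) {
          q <- stats::quantile(bv, c(0.025, 0.975), names = FALSE)
          low <- q[1]; up <- q[2]
        }
      }
      ok <- if (any(is.na(c(pred, low, up)))) NA else (pred >= low & pred <= up)
      rows[[length(rows) + 1]] <-
        data.frame(macro_set = a, multiple = k, predicted = pred,
                   estimated = est, lower = low, upper = up, ok = ok,
                   flagged = flagged)
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, n_boot = n_boot, n_macro = macro$n_macro),
            class = "ck_report")
}

#' @export
print.ck_report <- function(x, ...) {
  t <- x$table
  frac <- mean(t$ok[!is.na(t$ok)])
  cat("Chapman-Kolmogorov report:", nrow(t), "points;",
      sprintf("%.0f%%", 100 * frac), "within 95% bootstrap bands\n")
  invisible(x)
}

#' Fraction of CK points whose prediction lies inside the bands
#'
#' @param report a `ck_report`.
#' @param exclude_trivial drop multiple == 1 (predicted equals estimated by
#'   construction).
#' @return fraction in [0, 1].
#' @export
ck_pass_fraction <- function(report, exclude_trivial = FALSE) {
  t <- report$table
  if (exclude_trivial) t <- t[t$multiple > 1, ]
  ok <- t$ok[!is.na(t$ok)]
  if (length(ok) == 0) return(NA_real_)
  mean(ok)
}

#' Export a CK report as CSV
#'
#' @param report a `ck_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_ck <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
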