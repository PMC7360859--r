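## Toy well-tempered metadynamics: overdamped Langevin dynamics in collective
## variable space on analytic potentials, with history-dependent Gaussian
## biasing and the standard well-tempered free-energy estimator.
##
## Units: energies kcal/mol, temperature K, kB in kcal/(mol K).

#' Analytic potential in CV space
#'
#' @param evaluator function(s) -> energy (kcal/mol); vectorized in s.
#' @param gradient function(s) -> dV/ds; vectorized in s.
#' @param domain length-2 numeric bounds of the CV domain.
#' @param periodic treat the domain as periodic (minimum-image distances).
#' @return an object of class `analytic_potential`.
#' @export
analytic_potential <- function(evaluator, gradient, domain, periodic = FALSE) {
  stopifnot(is.function(evaluator), is.function(gradient),
            length(domain) == 2, domain[1] < domain[2])
  structure(list(evaluator = evaluator, gradient = gradient,
                 domain = as.numeric(domain), periodic = isTRUE(periodic)),
            class = "analytic_potential")
}

#' Well-tempered bias settings and deposited-hill state
#'
#' Defaults follow common practice for CDR-loop metadynamics: initial hill
#' height 10 kcal/mol, deposition every 1000 steps, bias factor 10, 300 K.
#' The hill width is a free parameter (default 0.35 CV units).
#'
#' @param initial_height Gaussian height w0, kcal/mol (> 0).
#' @param hill_width Gaussian sigma per CV dimension (> 0).
#' @param bias_factor dimensionless gamma (> 1).
#' @param temperature K.
#' @param deposition_stride steps between depositions.
#' @param periodic CV is periodic (hills use minimum-image distance).
#' @param period period length when `periodic`.
#' @return an object of class `bias_state` with empty hill history.
#' @export
bias_state <- function(initial_height = 10, hill_width = 0.35,
                       bias_factor = 10, temperature = 300,
                       deposition_stride = 1000, periodic = FALSE,
                       period = 360) {
  stopifnot(initial_height > 0, hill_width > 0, bias_factor > 1,
            temperature > 0, deposition_stride >= 1)
  structure(list(initial_height = initial_height, hill_width = hill_width,
                 bias_factor = bias_factor, temperature = temperature,
                 deposition_stride = as.integer(deposition_stride),
                 periodic = isTRUE(periodic), period = period,
                 hill_centers = numeric(0), hill_heights = numeric(0)),
            class = "bias_state")
}

hill_displacement <- function(bias, s, centers) {
  d <- s - centers
  if (bias$periodic) d <- d - bias$period * round(d / bias$period)
  d
}

#' Total bias energy at CV value(s)
#'
#' Sum over all deposited Gaussian hills.
#'
#' @param bias a `bias_state`.
#' @param s numeric CV value(s).
#' @return bias energy (kcal/mol), same length as `s`.
#' @export
bias_energy <- function(bias, s) {
  if (length(bias$hill_centers) == 0) return(rep(0, length(s)))
  vapply(s, function(si) {
    d <- hill_displacement(bias, si, bias$hill_centers)
    sum(bias$hill_heights * exp(-d^2 / (2 * bias$hill_width^2)))
  }, 0)
}

bias_gradient1 <- function(bias, s) {
  if (length(bias$hill_centers) == 0) return(0)
  d <- hill_displacement(bias, s, bias$hill_centers)
  g <- bias$hill_heights * exp(-d^2 / (2 * bias$hill_width^2))
  sum(g * (-d / bias$hill_width^2))
}

#' Run toy well-tempered metadynamics
#'
#' Overdamped Langevin dynamics (unit mobility) in 1-D CV space:
#' ds = -(dV/ds + dVbias/ds) dt + sqrt(2 kB T dt) eta. Every
#' `deposition_stride` steps a Gaussian of height
#' w0 * exp(-Vbias(s) / ((gamma - 1) kB T)) is deposited at the current CV
#' value. Deterministic for a fixed seed.
#'
#' @param potential an `analytic_potential`.
#' @param bias a `bias_state` (may already hold hills).
#' @param steps number of integration steps.
#' @param step_size time step dt (arbitrary CV-time units).
#' @param seed RNG seed.
#' @param s0 starting CV value (default: domain midpoint).
#' @return an object of class `wtmetad_run`: list with `cv` (CV value per
#'   step), `bias` (final `bias_state`), and run settings.
#' @export
run_wt_metadynamics <- function(potential, bias, steps, step_size,
                                seed = 1, s0 = NULL) {
  stopifnot(inherits(potential, "analytic_potential"),
            inherits(bias, "bias_state"), steps > 0, step_size > 0)
  set.seed(seed)
  dom <- potential$domain
  if (is.null(s0)) s0 <- mean(dom)
  kT <- KB_KCAL * bias$temperature
  noise_sd <- sqrt(2 * kT * step_size)
  span <- dom[2] - dom[1]
  s <- s0
  cv <- numeric(steps)
  noise <- stats::rnorm(steps, sd = noise_sd)
  for (t in seq_len(steps)) {
    force <- -(potential$gradient(s) + bias_gradient1(bias, s))
    s <- s + step_size * force + noise[t]
    if (potential$periodic) {
      s <- dom[1] + (s - dom[1]) %% span
    } else if (s < dom[1] - 10 * span || s > dom[2] + 10 * span) {
      stop("trajectory diverged at step ", t,
           " (CV = ", signif(s, 4), "); use a smaller step size")
    }
    cv[t] <- s
    if (t %% bias$deposition_stride == 0) {
      h <- bias$initial_height *
        exp(-bias_energy(bias, s) / ((bias$bias_factor - 1) * kT))
      bias$hill_centers <- c(bias$hill_centers, s)
      bias$hill_heights <- c(bias$hill_heights, h)
    }
  }
  structure(list(cv = cv, bias = bias, steps = steps, step_size = step_size,
                 seed = seed), class = "wtmetad_run")
}

#' @export
print.wtmetad_run <- function(x, ...) {
  cat("well-tempered metadynamics run:", x$steps, "steps,",
      length(x$bias$hill_centers), "hills deposited\n")
  invisible(x)
}

#' Reconstruct the free-energy profile from the deposited bias
#'
#' Well-tempered estimator F(s) = -(gamma / (gamma - 1)) * Vbias(s),
#' shifted so the grid minimum is zero.
#'
#' @param bias a `bias_state` with at least one hill.
#' @param grid numeric vector of CV values.
#' @return numeric free energies (kcal/mol) on `grid`, min 0.
#' @export
reconstruct_free_energy <- function(bias, grid) {
  stopifnot(inherits(bias, "bias_state"))
  if (length(grid) == 0) stop("free-energy grid must be non-empty")
  if (length(bias$hill_centers) == 0)
    stop("no hills deposited; nothing to reconstruct")
  g <- bias$bias_factor
  f <- -(g / (g - 1)) * bias_energy(bias, grid)
  f - min(f)
}

#' Export the hills log as CSV (time step, center, width, height)
#'
#' @param run a `wtmetad_run`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_hills <- function(run, path) {
  b <- run$bias
  df <- data.frame(step = seq_along(b$hill_centers) * b$deposition_stride,
                   center = b$hill_centers, width = b$hill_width,
                   height = b$hill_heights)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
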