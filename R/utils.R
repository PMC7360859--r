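## Shared constants and small numeric helpers.

#' Boltzmann constant in kcal/(mol K)
#'
#' Used for free-energy surfaces and the well-tempered bias damping.
#' @export
KB_KCAL <- 0.0019872041

#' Wrap angles in degrees into (-180, 180]
#'
#' @param x numeric vector of angles, degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Row-wise cross product of two n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rowdot <- function(a, b) rowSums(a * b)

rownorm <- function(a) sqrt(rowSums(a * a))

## Circular mean (degrees) of angles in degrees.
circular_mean <- function(x) {
  r <- deg2rad(x)
  rad2deg(atan2(mean(sin(r)), mean(cos(r))))
}

## Circular variance reported in degrees^2: square of the circular
## standard deviation sqrt(-2 log R), R the mean resultant length.
circular_variance <- function(x) {
  r <- deg2rad(x)
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  R <- min(max(R, .Machine$double.xmin), 1)
  (rad2deg(sqrt(-2 * log(R))))^2
}

## Deterministic per-stage seed fan-out from a master seed.
stage_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 1009 + 97 * counter) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
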