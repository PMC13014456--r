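#' Tempered perturbation-schedule parameters for one component
#'
#' Each rigid-motion component of a diffusion docking sampler (translation,
#' rotation, torsion) carries a log-interpolated noise scale and three
#' temperature-sampling knobs: a base interpolation weight `eps0`, a
#' temperature `T`, and the pair `T0`/`psi` entering the tempered update,
#' raised to a per-component exponent.
#'
#' @param sigma_min,sigma_max positive noise-scale bounds.
#' @param eps0 interpolation weight in [0, 1].
#' @param T temperature (> 0); `T = 1` recovers the untempered update.
#' @param T0,psi additional tempering terms (default 0).
#' @param exponent per-component exponent applied to the tempered factor
#'   (default 1).
#' @return object of class `ScheduleParams`.
#' @export
schedule_params <- function(sigma_min, sigma_max, eps0 = 0.5, T = 1,
                            T0 = 0, psi = 0, exponent = 1) {
  stopifnot(sigma_min > 0, sigma_max > 0, sigma_min <= sigma_max,
            eps0 >= 0, eps0 <= 1, T > 0)
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max, eps0 = eps0,
                 T = T, T0 = T0, psi = psi, exponent = exponent),
            class = "ScheduleParams")
}

#' Log-linear noise-scale interpolation
#'
#' `exp(eps0 * log(sigma_max) + (1 - eps0) * log(sigma_min))`: the geometric
#' interpolation between the scale bounds, hitting `sigma_min` at `eps0 = 0`
#' and `sigma_max` at `eps0 = 1`.
#'
#' @param eps0 interpolation weight in [0, 1].
#' @param sigma_min,sigma_max positive scale bounds.
#' @return interpolated scale.
#' @export
sigma_interp <- function(eps0, sigma_min, sigma_max) {
  if (sigma_min <= 0 || sigma_max <= 0) stop("sigmas must be positive")
  exp(eps0 * log(sigma_max) + (1 - eps0) * log(sigma_min))
}

#' Temperature rescaling factor
#'
#' `lambda = (eps + sigma) / (eps + sigma * T)`. Identically 1 at `T = 1`
#' (temperature off changes nothing) and `1 / T` as `eps -> 0`. The printed
#' source formula lacks explicit operators; this reading is fixed here and
#' isolated so an alternative grouping is a one-function change.
#'
#' @param eps interpolated scale from [sigma_interp()].
#' @param sigma current noise scale.
#' @param T temperature.
#' @return scalar rescaling factor.
#' @export
lambda_scale <- function(eps, sigma, T) {
  denom <- eps + sigma * T
  if (abs(denom) < .Machine$double.eps) stop("zero denominator in lambda")
  (eps + sigma) / denom
}

#' Tempered perturbation magnitude
#'
#' One shared update serves translation, rotation and torsion with
#' component-specific parameters:
#' `delta = dsigma2 * (lambda + T0 * psi^2)^exponent + t * (1 + psi) * z`,
#' where `dsigma2` is the variance increment of the step and `z` a standard
#' normal draw. With `psi = 0`, `T0 = 0` and `T = 1` this reduces to the
#' untempered `dsigma2 + t * z`.
#'
#' @param params a `ScheduleParams`.
#' @param dsigma2 variance increment of the step.
#' @param t diffusion time in [0, 1].
#' @param z standard normal draw.
#' @return update magnitude.
#' @export
perturbation_magnitude <- function(params, dsigma2, t, z) {
  eps <- sigma_interp(params$eps0, params$sigma_min, params$sigma_max)
  sigma <- sigma_interp(t, params$sigma_min, params$sigma_max)
  lam <- lambda_scale(eps, sigma, params$T)
  dsigma2 * (lam + params$T0 * params$psi^2)^params$exponent +
    t * (1 + params$psi) * z
}

#' Beta-distributed diffusion-time sampler
#'
#' @param alpha,beta positive shape parameters (defaults 1.25 and 2.25,
#'   biasing sampled times toward the early stages of reverse diffusion).
#' @param seed integer seed.
#' @return object of class `BetaTimeSampler`.
#' @export
beta_time_sampler <- function(alpha = 1.25, beta = 2.25, seed = 1L) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta, seed = as.integer(seed)),
            class = "BetaTimeSampler")
}

#' Beta density
#'
#' `f(x) = x^(alpha-1) (1-x)^(beta-1) / B(alpha, beta)` with the Euler beta
#' function as normaliser, evaluated in closed form.
#'
#' @param x values in [0, 1].
#' @param sampler a `BetaTimeSampler`.
#' @return density values.
#' @export
beta_pdf <- function(x, sampler = beta_time_sampler()) {
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  a <- sampler$alpha; b <- sampler$beta
  x^(a - 1) * (1 - x)^(b - 1) / beta(a, b)
}

#' Sample diffusion times
#'
#' Inverse-CDF sampling on a seeded uniform stream (reproducible across
#' platforms for a fixed seed).
#'
#' @param sampler a `BetaTimeSampler`.
#' @param n number of draws.
#' @return numeric vector of n draws in [0, 1].
#' @export
sample_time <- function(sampler, n) {
  stopifnot(n >= 1)
  set.seed(sampler$seed)
  qbeta(runif(n), sampler$alpha, sampler$beta)
}

#' Tabulate the schedule over a time grid
#'
#' @param params a `ScheduleParams`.
#' @param n_grid number of time points (default 101).
#' @return data.frame with `t`, `sigma`, `lambda` and the deterministic
#'   (z = 0) update magnitude for a unit variance increment.
#' @export
schedule_table <- function(params, n_grid = 101) {
  t <- seq(0, 1, length.out = n_grid)
  eps <- sigma_interp(params$eps0, params$sigma_min, params$sigma_max)
  sigma <- sigma_interp(t, params$sigma_min, params$sigma_max)
  lam <- vapply(sigma, function(s) lambda_scale(eps, s, params$T), numeric(1))
  mag <- vapply(t, function(tt)
    perturbation_magnitude(params, dsigma2 = 1, t = tt, z = 0), numeric(1))
  data.frame(t = t, sigma = sigma, lambda = lam, magnitude = mag)
}
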