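# Ornstein-Uhlenbeck core: closed-form transition and stationary moments,
# exact-discretization simulation, analytic predictive trajectories, and
# Monte Carlo predictive envelopes.
#
# The process is dY = theta * (mu - Y) dt + sigma dW. Over a step of length
# dt the transition is Gaussian with
#   m = mu + (y_prev - mu) * exp(-theta * dt)
#   v = sigma^2 / (2 theta) * (1 - exp(-2 theta dt))
# which is exact for any dt, so irregular sampling needs no discretization
# error control.

#' Ornstein-Uhlenbeck parameter triple
#'
#' Construct a validated OU parameter set. `mu` is the equilibrium mean (for
#' mutation-frequency applications, on the log10 scale), `theta` the
#' mean-reversion rate per unit time, and `sigma` the diffusion scale
#' (so `sigma^2` is the variance accumulation rate).
#'
#' @param mu Equilibrium mean (any finite real).
#' @param theta Mean-reversion rate, strictly positive.
#' @param sigma Diffusion scale, strictly positive.
#' @return An object of class `ou_params`.
#' @examples
#' ou_params(mu = -6.799, theta = 0.775, sigma = 0.727)
#' @export
ou_params <- function(mu, theta, sigma) {
  stop_if_not_scalar(mu, "mu")
  stop_if_not_scalar(theta, "theta", positive = TRUE)
  stop_if_not_scalar(sigma, "sigma", positive = TRUE)
  structure(list(mu = mu, theta = theta, sigma = sigma), class = "ou_params")
}

#' @export
print.ou_params <- function(x, ...) {
  sm <- stationary_moments(x)
  cat(sprintf(
    "OU parameters: mu = %.6g, theta = %.6g, sigma = %.6g\n  stationary variance sigma^2/(2 theta) = %.6g, equilibrium 10^mu = %.6g\n",
    x$mu, x$theta, x$sigma, sm[["variance"]], equilibrium_frequency(x)))
  invisible(x)
}

as_ou_params <- function(x) {
  if (inherits(x, "ou_params")) return(x)
  if (is.numeric(x) && length(x) == 3L) {
    nm <- names(x) %||% c("mu", "theta", "sigma")
    return(ou_params(x[[match("mu", nm)]], x[[match("theta", nm)]],
                     x[[match("sigma", nm)]]))
  }
  if (is.list(x) && all(c("mu", "theta", "sigma") %in% names(x)))
    return(ou_params(x$mu, x$theta, x$sigma))
  stop("cannot interpret `params` as OU parameters", call. = FALSE)
}

#' Stationary mean and variance of an OU process
#'
#' The stationary law of the OU process is Normal(mu, sigma^2 / (2 theta)).
#'
#' @param params An [ou_params] object.
#' @return Named numeric vector `c(mean = mu, variance = sigma^2/(2*theta))`.
#' @export
stationary_moments <- function(params) {
  p <- as_ou_params(params)
  c(mean = p$mu, variance = p$sigma^2 / (2 * p$theta))
}

#' Equilibrium frequency on the original scale
#'
#' For a trait modelled as log10 frequency, the equilibrium frequency is
#' `10^mu`.
#'
#' @inheritParams stationary_moments
#' @return `10^mu`.
#' @export
equilibrium_frequency <- function(params) {
  10^as_ou_params(params)$mu
}

#' Exact OU transition moments
#'
#' Conditional mean and variance of `Y(t + dt)` given `Y(t) = y_prev`.
#' Vectorized over `y_prev` and `dt` (recycled against each other).
#'
#' @inheritParams stationary_moments
#' @param y_prev Conditioning value(s).
#' @param dt Elapsed time(s), each `>= 0`.
#' @return A list with components `m`, `v`, `dt` (all the common length).
#' @export
transition_moments <- function(params, y_prev, dt) {
  p <- as_ou_params(params)
  if (any(!is.finite(dt)) || any(dt < 0))
    stop("`dt` must be finite and >= 0", call. = FALSE)
  a <- exp(-p$theta * dt)
  m <- p$mu + (y_prev - p$mu) * a
  v <- p$sigma^2 / (2 * p$theta) * (1 - a^2)
  list(m = m, v = v, dt = dt)
}

#' Simulate OU trajectories by exact discretization
#'
#' Each step draws from the exact Gaussian transition, so the law of the
#' sampled skeleton is exact on any (strictly increasing) time grid; no
#' Euler error is incurred.
#'
#' @inheritParams stationary_moments
#' @param y0 Initial value at `times[1]`.
#' @param times Strictly increasing time grid; the first entry is the time
#'   of `y0`.
#' @param n_reps Number of independent trajectories.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return Numeric matrix, `length(times)` rows x `n_reps` columns, with
#'   `times` attached as rownames.
#' @export
simulate_exact <- function(params, y0, times, n_reps = 1L, seed = NULL) {
  p <- as_ou_params(params)
  if (length(times) < 1L || any(!is.finite(times)) || any(diff(times) <= 0))
    stop("`times` must be finite and strictly increasing", call. = FALSE)
  stop_if_not_scalar(y0, "y0")
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  nt <- length(times)
  out <- matrix(NA_real_, nrow = nt, ncol = n_reps)
  out[1L, ] <- y0
  with_seed(seed, {
    if (nt > 1L) {
      dts <- diff(times)
      a <- exp(-p$theta * dts)
      sdv <- sqrt(p$sigma^2 / (2 * p$theta) * (1 - a^2))
      for (i in 2:nt) {
        out[i, ] <- p$mu + (out[i - 1L, ] - p$mu) * a[i - 1L] +
          sdv[i - 1L] * stats::rnorm(n_reps)
      }
    }
  })
  rownames(out) <- format(times, trim = TRUE)
  attr(out, "times") <- times
  out
}

#' Analytic predictive trajectory
#'
#' Predictive mean `m(t)` and variance `v(t)` of the OU process conditioned
#' on `Y(t0) = y0`, evaluated on an arbitrary grid `times >= t0`.
#'
#' @inheritParams simulate_exact
#' @param t0 Conditioning time.
#' @param times Evaluation times, all `>= t0`.
#' @return An object of class `predictive_trajectory`: list with `times`,
#'   `mean`, `var`, `y0`, `t0`, `params`.
#' @export
predictive_trajectory <- function(params, y0, t0, times) {
  p <- as_ou_params(params)
  stop_if_not_scalar(y0, "y0")
  stop_if_not_scalar(t0, "t0")
  if (any(times < t0)) stop("all `times` must be >= t0", call. = FALSE)
  tm <- transition_moments(p, y0, times - t0)
  structure(list(times = times, mean = tm$m, var = tm$v, y0 = y0, t0 = t0,
                 params = p),
            class = "predictive_trajectory")
}

#' Empirical predictive envelope from simulated trajectories
#'
#' Per-time empirical quantiles (default 2.5th and 97.5th percentiles,
#' i.e. a 95% predictive band) of a trajectory matrix as produced by
#' [simulate_exact()]. Quantiles use linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param simulations Matrix, times in rows and replicates in columns.
#' @param q Length-2 probability pair, lower then upper.
#' @return An object of class `envelope`: list with `times`, `lo`, `hi`, `q`.
#' @export
predictive_envelope <- function(simulations, q = c(0.025, 0.975)) {
  if (!is.matrix(simulations) || ncol(simulations) < 2L)
    stop("`simulations` must be a matrix with >= 2 trajectories", call. = FALSE)
  if (length(q) != 2L || any(q < 0) || any(q > 1) || q[1] > q[2])
    stop("`q` must be an ordered probability pair", call. = FALSE)
  lo <- apply(simulations, 1L, stats::quantile, probs = q[1], names = FALSE)
  hi <- apply(simulations, 1L, stats::quantile, probs = q[2], names = FALSE)
  times <- attr(simulations, "times") %||% seq_len(nrow(simulations))
  structure(list(times = times, lo = lo, hi = hi, q = q), class = "envelope")
}
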