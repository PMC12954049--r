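# Phase-plane analysis of the coupled (trait, population) system and the
# cyclic-therapy simulator.
#
# The deterministic skeleton is
#   dY/dt = theta (mu - Y)
#   dN/dt = (lambda(Y) - delta(Y)) N
# Stochastic trajectories combine exact discrete-time OU updates of Y with
# Poisson (tau-leap) birth and death events for N. Under therapy, a
# pharmacokinetic exposure C(t) enters the rates through the saturating
# effect g(C) = C / (C + EC50):
#   lambda(Y, C) = lambda0 exp(alpha (Y - mu0) - k_lambda g(C))
#   delta(Y, C)  = delta0  exp(-beta (Y - mu0) + k_delta  g(C))
# so increasing exposure suppresses division and increases death while the
# OU parameters themselves stay fixed.

#' Phase-plane specification
#'
#' @param ou An [ou_params] object for the trait.
#' @param rates A [branching_config()]; its `mu_ref` defaults to `ou$mu`.
#' @param y_range,n_range Display ranges for the trait and population axes.
#' @param grid_density Integer pair: number of grid points per axis.
#' @param dt Step of the stochastic simulator (default 0.05).
#' @param y0 Initial trait (default `ou$mu`).
#' @param n0 Initial population size (default `rates$n0`).
#' @param t_max Horizon (default `rates$t_max`).
#' @return List of class `phase_plane_spec`.
#' @export
phase_plane_spec <- function(ou, rates, y_range = NULL, n_range = NULL,
                             grid_density = c(20L, 20L), dt = 0.05,
                             y0 = NULL, n0 = NULL, t_max = NULL) {
  p <- as_ou_params(ou)
  stopifnot(inherits(rates, "branching_config"))
  if (is.na(rates$mu_ref)) rates$mu_ref <- p$mu
  sv <- sqrt(p$sigma^2 / (2 * p$theta))
  y_range <- y_range %||% c(p$mu - 3 * sv, p$mu + 3 * sv)
  n_range <- n_range %||% c(1, 10 * rates$n0)
  if (diff(y_range) <= 0 || diff(n_range) <= 0)
    stop("ranges must be non-degenerate", call. = FALSE)
  stop_if_not_scalar(dt, "dt", positive = TRUE)
  structure(list(ou = p, rates = rates, y_range = y_range, n_range = n_range,
                 grid_density = as.integer(grid_density), dt = dt,
                 y0 = y0 %||% p$mu, n0 = as.integer(n0 %||% rates$n0),
                 t_max = t_max %||% rates$t_max),
            class = "phase_plane_spec")
}

#' Deterministic vector field of the coupled dynamics
#'
#' Samples `dY/dt = theta (mu - Y)` and `dN/dt = (lambda(Y) - delta(Y)) N`
#' on a regular (Y, N) grid (N spaced on the log scale, as displayed).
#'
#' @param spec A [phase_plane_spec()].
#' @return Data frame with columns `Y`, `N`, `dY`, `dN`.
#' @export
vector_field <- function(spec) {
  stopifnot(inherits(spec, "phase_plane_spec"))
  ys <- seq(spec$y_range[1], spec$y_range[2],
            length.out = spec$grid_density[1])
  ns <- exp(seq(log(max(spec$n_range[1], 1e-9)), log(spec$n_range[2]),
                length.out = spec$grid_density[2]))
  g <- expand.grid(Y = ys, N = ns)
  r <- phenotype_rates(g$Y, spec$rates)
  data.frame(Y = g$Y, N = g$N,
             dY = spec$ou$theta * (spec$ou$mu - g$Y),
             dN = (r$lambda - r$delta) * g$N)
}

#' Demographic nullcline of the phenotype-coupled rates
#'
#' The trait value where division balances death,
#' `Y* = mu_ref + log(delta0 / lambda0) / (alpha + beta)`. With
#' `alpha + beta = 0` the rates are flat in Y: every Y is a nullcline if
#' `lambda0 = delta0`, otherwise none exists and `NA` is returned with a
#' message.
#'
#' @param rates A [branching_config()] with a resolved (non-`NA`) `mu_ref`.
#' @return The nullcline trait value, or `NA` if none exists.
#' @export
demographic_nullcline <- function(rates) {
  stopifnot(inherits(rates, "branching_config"))
  if (is.na(rates$mu_ref))
    stop("`mu_ref` is NA; resolve it before computing the nullcline",
         call. = FALSE)
  if (rates$alpha + rates$beta == 0) {
    if (rates$lambda0 == rates$delta0) return(rates$mu_ref)
    message("no demographic nullcline: rates are Y-independent and unequal")
    return(NA_real_)
  }
  rates$mu_ref + log(rates$delta0 / rates$lambda0) / (rates$alpha + rates$beta)
}

#' Stochastic phase-plane trajectory
#'
#' One realization of the hybrid system: per step of length `spec$dt`, the
#' trait advances by an exact OU transition, then births
#' `~ Poisson(lambda(Y) N dt)` and deaths `~ Poisson(delta(Y) N dt)`
#' (capped at N) update the population, with N = 0 absorbing.
#'
#' @param spec A [phase_plane_spec()].
#' @param seed Integer seed.
#' @return Data frame with columns `time`, `Y`, `N`.
#' @export
simulate_phase_trajectory <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phase_plane_spec"))
  nt <- floor(spec$t_max / spec$dt) + 1L
  times <- (seq_len(nt) - 1L) * spec$dt
  with_seed(seed, {
    Y <- numeric(nt); N <- numeric(nt)
    Y[1L] <- spec$y0; N[1L] <- spec$n0
    a <- exp(-spec$ou$theta * spec$dt)
    sdv <- sqrt(spec$ou$sigma^2 / (2 * spec$ou$theta) * (1 - a^2))
    for (i in seq_len(nt - 1L)) {
      Y[i + 1L] <- spec$ou$mu + (Y[i] - spec$ou$mu) * a +
        sdv * stats::rnorm(1L)
      if (N[i] == 0) { N[i + 1L] <- 0; next }
      r <- phenotype_rates(Y[i + 1L], spec$rates)
      births <- stats::rpois(1L, r$lambda * N[i] * spec$dt)
      deaths <- min(stats::rpois(1L, r$delta * N[i] * spec$dt), N[i])
      N[i + 1L] <- N[i] + births - deaths
    }
    data.frame(time = times, Y = Y, N = N)
  })
}

#' Therapy configuration
#'
#' Exposure schedule, drug-effect couplings and simulation settings for
#' the cyclic-therapy ensemble. Defaults follow the high-plasticity
#' profile (mu = -5.000, theta = 0.117, sigma = 0.436) with six 21-day
#' cycles, a 200-day horizon, a 0.5-day step and 256 replicates. The
#' baseline demographic constants and drug couplings are illustrative
#' defaults; they shape regimes qualitatively and are all overridable.
#'
#' @param ou [ou_params] of the trait (held fixed during therapy).
#' @param mu0 Baseline (pre-therapy) optimum; default `ou$mu`.
#' @param lambda0,delta0 Baseline division/death rates per day.
#' @param alpha,beta Trait couplings as in [branching_config()].
#' @param k_lambda,k_delta Drug effect strengths on division and death.
#' @param ec50 Exposure at half-maximal drug effect.
#' @param n_cycles,cycle_length Number and length (days) of dosing cycles.
#' @param amplitude Peak exposure; default `2 * ec50`.
#' @param shape `"pulse"` (rectangular, default) or `"decay"`
#'   (exponential within each cycle).
#' @param pulse_duration Days of dosing per cycle for the pulse shape
#'   (default 14, i.e. 14 days on / 7 days off: with the default rate
#'   constants the regimen is then net-lethal at the baseline optimum,
#'   the regime in which mean reversion favors cure and diffusion favors
#'   escape).
#' @param k_elim Elimination rate per day for the decay shape.
#' @param t_max,dt Horizon and step in days.
#' @param n_reps Stochastic replicates per arm.
#' @param n0 Initial population size.
#' @param rate_cap,n_cap Clipping ceiling for rates and population
#'   truncation cap.
#' @return List of class `therapy_config`.
#' @export
therapy_config <- function(ou = ou_params(-5.000, 0.117, 0.436),
                           mu0 = NULL,
                           lambda0 = 0.30, delta0 = 0.15,
                           alpha = 0.5, beta = 0.5,
                           k_lambda = 1.5, k_delta = 1.5,
                           ec50 = 1.0,
                           n_cycles = 6L, cycle_length = 21,
                           amplitude = NULL, shape = c("pulse", "decay"),
                           pulse_duration = 14, k_elim = 0.5,
                           t_max = 200, dt = 0.5, n_reps = 256L,
                           n0 = 500L, rate_cap = 10, n_cap = 1000000L) {
  p <- as_ou_params(ou)
  shape <- match.arg(shape)
  for (nm in c("lambda0", "delta0", "ec50", "dt", "t_max"))
    stop_if_not_scalar(get(nm), nm, positive = TRUE)
  for (nm in c("alpha", "beta", "k_lambda", "k_delta"))
    stop_if_not_scalar(get(nm), nm, nonneg = TRUE)
  structure(list(ou = p, mu0 = mu0 %||% p$mu,
                 lambda0 = lambda0, delta0 = delta0,
                 alpha = alpha, beta = beta,
                 k_lambda = k_lambda, k_delta = k_delta, ec50 = ec50,
                 n_cycles = as.integer(n_cycles), cycle_length = cycle_length,
                 amplitude = amplitude %||% (2 * ec50), shape = shape,
                 pulse_duration = pulse_duration, k_elim = k_elim,
                 t_max = t_max, dt = dt, n_reps = as.integer(n_reps),
                 n0 = as.integer(n0), rate_cap = rate_cap,
                 n_cap = as.integer(n_cap)),
            class = "therapy_config")
}

#' Pharmacokinetic exposure profile C(t)
#'
#' Rectangular pulse (amplitude for the first `pulse_duration` days of
#' each cycle) or within-cycle exponential decay
#' (`amplitude * exp(-k_elim * (t - cycle_start))`). Exposure is zero
#' after the last cycle ends. Vectorized over `t`.
#'
#' @param config A [therapy_config()].
#' @param t Time(s) in `[0, t_max]`.
#' @return Exposure value(s), `>= 0`.
#' @export
exposure_profile <- function(config, t) {
  stopifnot(inherits(config, "therapy_config"))
  if (any(t < 0) || any(t > config$t_max))
    stop("`t` must lie in [0, t_max]", call. = FALSE)
  treat_end <- config$n_cycles * config$cycle_length
  within <- t %% config$cycle_length
  on <- t < treat_end
  C <- switch(config$shape,
              pulse = ifelse(on & within < config$pulse_duration,
                             config$amplitude, 0),
              decay = ifelse(on, config$amplitude *
                               exp(-config$k_elim * within), 0))
  C
}

#' Saturating drug-effect function
#'
#' `g(C) = C / (C + EC50)`, bounded in `[0, 1)` and strictly increasing.
#'
#' @param C Exposure(s), `>= 0`.
#' @param ec50 Exposure at half effect, `> 0`.
#' @export
drug_effect <- function(C, ec50) {
  if (any(C < 0)) stop("`C` must be >= 0", call. = FALSE)
  stop_if_not_scalar(ec50, "ec50", positive = TRUE)
  C / (C + ec50)
}

#' Exposure-modulated division and death rates
#'
#' `lambda(Y, C) = lambda0 exp(alpha (Y - mu0) - k_lambda g(C))` and
#' `delta(Y, C) = delta0 exp(-beta (Y - mu0) + k_delta g(C))`, clipped to
#' `[0, rate_cap]`. At `C = 0` these reduce to the phenotype-only rates.
#'
#' @param Y Trait value(s).
#' @param C Exposure value(s).
#' @param config A [therapy_config()].
#' @return List with `lambda` and `delta`.
#' @export
therapy_rates <- function(Y, C, config) {
  stopifnot(inherits(config, "therapy_config"))
  g <- drug_effect(C, config$ec50)
  list(lambda = clip(config$lambda0 *
                       exp(config$alpha * (Y - config$mu0) - config$k_lambda * g),
                     0, config$rate_cap),
       delta = clip(config$delta0 *
                      exp(-config$beta * (Y - config$mu0) + config$k_delta * g),
                    0, config$rate_cap))
}

# Vectorized (across replicates) hybrid simulation of one arm.
simulate_arm <- function(config, treated, seed) {
  nt <- floor(config$t_max / config$dt) + 1L
  times <- (seq_len(nt) - 1L) * config$dt
  R <- config$n_reps
  with_seed(seed, {
    Ymat <- matrix(NA_real_, nt, R)
    Nmat <- matrix(NA_real_, nt, R)
    p <- config$ou
    sv <- p$sigma^2 / (2 * p$theta)
    Ymat[1L, ] <- stats::rnorm(R, p$mu, sqrt(sv))
    Nmat[1L, ] <- config$n0
    a <- exp(-p$theta * config$dt)
    sdv <- sqrt(sv * (1 - a^2))
    truncated <- rep(FALSE, R)
    for (i in seq_len(nt - 1L)) {
      Y <- p$mu + (Ymat[i, ] - p$mu) * a + sdv * stats::rnorm(R)
      Ymat[i + 1L, ] <- Y
      C <- if (treated) exposure_profile(config, times[i + 1L]) else 0
      r <- therapy_rates(Y, C, config)
      N <- Nmat[i, ]
      # replicates at the cap are frozen there (escaped, certainly not
      # cured); extinct ones are absorbed at 0
      alive <- N > 0 & !truncated
      births <- deaths <- numeric(R)
      if (any(alive)) {
        births[alive] <- stats::rpois(sum(alive),
                                      r$lambda[alive] * N[alive] * config$dt)
        deaths[alive] <- pmin(
          stats::rpois(sum(alive), r$delta[alive] * N[alive] * config$dt),
          N[alive])
      }
      N2 <- N + births - deaths
      hit <- N2 >= config$n_cap
      truncated <- truncated | hit
      N2[hit] <- config$n_cap
      Nmat[i + 1L, ] <- N2
    }
    list(times = times, Y = Ymat, N = Nmat, truncated = truncated)
  })
}

#' Cyclic-therapy ensemble with a matched untreated control arm
#'
#' Simulates `n_reps` replicates of the hybrid trait/population system
#' under the dosing schedule (treated arm) and, from the identical seed,
#' with exposure held at zero (untreated arm). Records per-time medians
#' and 2.5/97.5% quantiles of Y and N for both arms, and the extinction
#' probability (fraction of replicates with N = 0 by `t_max`).
#'
#' @param config A [therapy_config()].
#' @param seed Integer seed; both arms derive from it, so a null therapy
#'   (`k_lambda = k_delta = 0`) gives identical arms.
#' @param arms `"both"` (default) or `"treated"` (skips the control, e.g.
#'   for cure-map sweeps).
#' @return Object of class `therapy_ensemble`: `times`, `summary` (long
#'   data frame: time, arm, variable, q025, q50, q975),
#'   `extinction_probability` (named per arm), `n_truncated`, `seed`,
#'   `config`.
#' @export
simulate_therapy_ensemble <- function(config, seed = 1L,
                                      arms = c("both", "treated")) {
  stopifnot(inherits(config, "therapy_config"))
  arms <- match.arg(arms)
  run <- list(treated = simulate_arm(config, treated = TRUE, seed = seed))
  if (arms == "both")
    run$untreated <- simulate_arm(config, treated = FALSE, seed = seed)
  if (all(run$treated$truncated))
    stop("every treated replicate hit n_cap; increase `n_cap`",
         call. = FALSE)
  qs <- function(M) t(apply(M, 1L, stats::quantile,
                            probs = c(0.025, 0.5, 0.975), names = FALSE))
  summ <- do.call(rbind, lapply(names(run), function(arm) {
    do.call(rbind, lapply(c("Y", "N"), function(v) {
      q <- qs(run[[arm]][[v]])
      data.frame(time = run[[arm]]$times, arm = arm, variable = v,
                 q025 = q[, 1L], q50 = q[, 2L], q975 = q[, 3L])
    }))
  }))
  ext <- vapply(run, function(a) mean(a$N[nrow(a$N), ] == 0), numeric(1))
  structure(list(times = run$treated$times, summary = summ,
                 extinction_probability = ext,
                 n_truncated = vapply(run, function(a) sum(a$truncated),
                                      integer(1)),
                 seed = as.integer(seed), config = config),
            class = "therapy_ensemble")
}

#' @export
print.therapy_ensemble <- function(x, ...) {
  cat(sprintf("Therapy ensemble: %d replicate(s)/arm, %d day(s), dt = %g\n",
              x$config$n_reps, max(x$times), x$config$dt))
  cat("extinction probability:",
      paste(sprintf("%s = %.3f", names(x$extinction_probability),
                    x$extinction_probability), collapse = ", "), "\n")
  invisible(x)
}

#' Cure-probability map over (theta, sigma)
#'
#' For each grid cell, overrides the OU mean-reversion rate and diffusion
#' scale of the base therapy configuration, runs a treated-arm ensemble of
#' `reps_per_cell` replicates and records the extinction fraction
#' P(cure) - the model-based probability that the population reaches zero
#' by `t_max`.
#'
#' @param base A [therapy_config()] supplying everything but (theta, sigma).
#' @param theta_grid,sigma_grid Positive parameter grids.
#' @param reps_per_cell Replicates per grid cell.
#' @param seed Integer seed; per-cell seeds are derived from it.
#' @return Object of class `cure_map`: `theta_grid`, `sigma_grid`,
#'   `p_cure` (length(theta_grid) x length(sigma_grid) matrix),
#'   `reps_per_cell`, `seed`.
#' @export
cure_probability_map <- function(base, theta_grid, sigma_grid,
                                 reps_per_cell = 64L, seed = 1L) {
  stopifnot(inherits(base, "therapy_config"),
            all(theta_grid > 0), all(sigma_grid > 0), reps_per_cell >= 1L)
  pc <- matrix(NA_real_, length(theta_grid), length(sigma_grid))
  cell <- 0L
  for (i in seq_along(theta_grid)) {
    for (j in seq_along(sigma_grid)) {
      cell <- cell + 1L
      cfg <- base
      cfg$ou <- ou_params(base$ou$mu, theta_grid[i], sigma_grid[j])
      cfg$n_reps <- as.integer(reps_per_cell)
      # a cell whose every replicate escapes to n_cap is certainly uncured
      pc[i, j] <- tryCatch(
        simulate_therapy_ensemble(cfg, seed = child_seed(seed, cell),
                                  arms = "treated")$extinction_probability[["treated"]],
        error = function(e) {
          if (grepl("n_cap", conditionMessage(e))) 0 else stop(e)
        })
    }
  }
  structure(list(theta_grid = theta_grid, sigma_grid = sigma_grid,
                 p_cure = pc, reps_per_cell = as.integer(reps_per_cell),
                 seed = as.integer(seed)),
            class = "cure_map")
}
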