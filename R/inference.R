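# Replicate-grouped exact-transition likelihood and everything built on it:
# multi-restart MLE, shared-parameter fits, LRT/AIC model comparison,
# profile-likelihood surfaces and the replicate bootstrap.
#
# The objective is NLL(mu, theta, sigma) =
#   0.5 * sum_i [ log(2 pi v_i) + (y_i - m_i)^2 / v_i ]
# summed over the within-replicate transitions of every replicate; the first
# observation of each replicate is conditioned on and contributes no term
# (optionally a stationary-density term can be added).

#' Replicate-grouped negative log-likelihood of an OU model
#'
#' @param params An [ou_params] object (theta, sigma > 0 enforced).
#' @param data A `lineage_dataset` on the log10 scale with >= 2 points per
#'   replicate.
#' @param stationary_init If `TRUE`, each replicate's first observation
#'   contributes a Normal(mu, sigma^2/(2 theta)) stationary-density term
#'   instead of being conditioned on.
#' @return The negative log-likelihood (a scalar).
#' @export
negative_log_likelihood <- function(params, data, stationary_init = FALSE) {
  p <- as_ou_params(params)
  stopifnot(inherits(data, "lineage_dataset"))
  if (!identical(data$scale, "log10"))
    stop("`data` must be on the log10 scale", call. = FALSE)
  total <- 0
  sv <- p$sigma^2 / (2 * p$theta)
  for (r in data$replicates) {
    n <- length(r$y)
    if (n < 2L)
      stop("each replicate needs >= 2 time points for the transition likelihood",
           call. = FALSE)
    dt <- diff(r$times)
    if (any(dt <= 0))
      stop("zero or negative time step within a replicate", call. = FALSE)
    a <- exp(-p$theta * dt)
    m <- p$mu + (r$y[-n] - p$mu) * a
    v <- sv * (1 - a^2)
    if (any(v <= 0))
      stop("degenerate transition variance (dt too small or theta overflow)",
           call. = FALSE)
    total <- total + 0.5 * sum(log(2 * pi * v) + (r$y[-1L] - m)^2 / v)
    if (stationary_init)
      total <- total + 0.5 * (log(2 * pi * sv) + (r$y[1L] - p$mu)^2 / sv)
  }
  total
}

# Objective in the internal parameterization (mu, log theta, log sigma),
# which enforces theta, sigma > 0; a large finite value is returned where
# the likelihood is undefined so L-BFGS-B always sees finite objectives.
nll_internal <- function(par, datasets, stationary_init = FALSE) {
  if (any(!is.finite(par))) return(1e10)
  p <- list(mu = par[1], theta = exp(par[2]), sigma = exp(par[3]))
  class(p) <- "ou_params"
  val <- tryCatch(
    sum(vapply(datasets, function(d)
      negative_log_likelihood(p, d, stationary_init), numeric(1))),
    error = function(e) NA_real_)
  if (!is.finite(val)) 1e10 else val
}

# Box bounds in internal coordinates: wide enough never to bind for real
# data, tight enough to keep every objective evaluation finite.
internal_bounds <- function(ys) {
  list(lower = c(min(ys) - 20, log(1e-8), log(1e-8)),
       upper = c(max(ys) + 20, log(1e8), log(1e8)))
}

default_fit_config <- function() {
  list(n_restarts = 24L,
       theta_start_range = c(1e-3, 1e2),
       sigma_start_range = c(1e-2, 1e1),
       reltol = 1e-10,
       maxit = 500L,
       tie_tol = 1e-6)
}

fit_datasets <- function(datasets, config, seed, stationary_init = FALSE,
                         start = NULL) {
  cfg <- utils::modifyList(default_fit_config(), config %||% list())
  ys <- unlist(lapply(datasets, function(d)
    unlist(lapply(d$replicates, `[[`, "y"))))
  n_restarts <- as.integer(cfg$n_restarts)
  starts <- with_seed(seed, {
    s <- matrix(NA_real_, nrow = n_restarts, ncol = 3L)
    # heuristic first start: sample moments of the pooled series
    s[1L, ] <- c(mean(ys), log(1), log(max(stats::sd(ys), 0.05)))
    if (n_restarts > 1L) {
      k <- n_restarts - 1L
      s[-1L, 1L] <- stats::runif(k, min(ys) - 1, max(ys) + 1)
      s[-1L, 2L] <- stats::runif(k, log(cfg$theta_start_range[1]),
                                 log(cfg$theta_start_range[2]))
      s[-1L, 3L] <- stats::runif(k, log(cfg$sigma_start_range[1]),
                                 log(cfg$sigma_start_range[2]))
    }
    s
  })
  if (!is.null(start))
    starts[1L, ] <- c(start$mu, log(start$theta), log(start$sigma))
  bounds <- internal_bounds(ys)
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(n_restarts)) {
    par0 <- clip(starts[i, ], bounds$lower, bounds$upper)
    f0 <- nll_internal(par0, datasets, stationary_init)
    if (f0 >= 1e10) next
    opt <- tryCatch(
      stats::optim(par0, nll_internal, datasets = datasets,
                   stationary_init = stationary_init, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(factr = cfg$reltol / .Machine$double.eps,
                                  maxit = cfg$maxit)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10 ||
        opt$value > f0 + 1e-9) next
    n_ok <- n_ok + 1L
    if (is.null(best)) { best <- opt; next }
    # ties within tolerance broken toward smaller sigma, then smaller theta,
    # so output is deterministic
    if (opt$value < best$value - cfg$tie_tol) best <- opt
    else if (abs(opt$value - best$value) <= cfg$tie_tol) {
      if (opt$par[3] < best$par[3] - 1e-12 ||
          (abs(opt$par[3] - best$par[3]) <= 1e-12 && opt$par[2] < best$par[2]))
        best <- opt
    }
  }
  if (is.null(best))
    stop("no optimization restart converged to a finite optimum (",
         n_restarts, " attempted)", call. = FALSE)
  params <- ou_params(best$par[1], exp(best$par[2]), exp(best$par[3]))
  list(params = params, nll = best$value,
       converged = best$convergence == 0L,
       # sigma pinned at (or near) its floor: no variance to explain
       degenerate = params$sigma < 1e-6,
       n_restarts_used = n_ok)
}

#' Fit lineage-specific OU parameters by maximum likelihood
#'
#' Minimizes the replicate-grouped exact-transition NLL over
#' (mu, log theta, log sigma) with BFGS from multiple random restarts; the
#' log parameterization enforces theta, sigma > 0. Deterministic given
#' `seed`.
#'
#' @param data A `lineage_dataset` (log10 scale).
#' @param config Optional list overriding the defaults: `n_restarts` (24),
#'   `theta_start_range`, `sigma_start_range` (log-uniform start windows),
#'   `reltol`, `maxit`, `tie_tol`.
#' @param seed Integer seed for the restart draws.
#' @param stationary_init Add a stationary-density term for each replicate's
#'   first observation (default conditions on it).
#' @return An object of class `ou_fit`: `params`, `nll`, `k` (= 3),
#'   `converged`, `n_restarts_used`, `dataset_id`.
#' @export
fit_mle <- function(data, config = list(), seed = 1L, stationary_init = FALSE) {
  stopifnot(inherits(data, "lineage_dataset"))
  res <- fit_datasets(list(data), config, seed, stationary_init)
  structure(c(res, list(k = 3L, dataset_id = data$lineage,
                        stationary_init = stationary_init)),
            class = "ou_fit")
}

#' Fit a single shared OU parameter triple to several lineages
#'
#' The null model of the lineage-comparison test: one (mu, theta, sigma)
#' minimizing the pooled NLL summed over all datasets (`k = 3`).
#'
#' @param datasets List of >= 2 `lineage_dataset` objects (log10 scale).
#' @inheritParams fit_mle
#' @return An `ou_fit` with `dataset_id` naming all lineages.
#' @export
fit_shared <- function(datasets, config = list(), seed = 1L,
                       stationary_init = FALSE) {
  stopifnot(is.list(datasets), length(datasets) >= 2L)
  lapply(datasets, function(d) stopifnot(inherits(d, "lineage_dataset")))
  res <- fit_datasets(datasets, config, seed, stationary_init)
  id <- paste(vapply(datasets, `[[`, character(1), "lineage"), collapse = "+")
  structure(c(res, list(k = 3L, dataset_id = id,
                        stationary_init = stationary_init)),
            class = "ou_fit")
}

#' @export
print.ou_fit <- function(x, ...) {
  cat(sprintf("OU fit [%s]: mu = %.4f, theta = %.4f, sigma = %.4f\n  NLL = %.4f (k = %d, %sconverged, %d restart(s) finished)\n",
              x$dataset_id, x$params$mu, x$params$theta, x$params$sigma,
              x$nll, x$k, if (x$converged) "" else "NOT ", x$n_restarts_used))
  invisible(x)
}

#' Akaike information criterion
#'
#' `AIC = 2k + 2 * NLL`.
#'
#' @param k Number of free parameters.
#' @param nll Minimized negative log-likelihood.
#' @export
aic <- function(k, nll) {
  stopifnot(k >= 0)
  2 * k + 2 * nll
}

#' Likelihood-ratio and AIC comparison of nested OU models
#'
#' `LRT = 2 (NLL_null - NLL_alt)` referred to a chi-square distribution
#' with `df = k_alt - k_null` degrees of freedom; AIC for both models and
#' their difference are reported alongside.
#'
#' @param null,alt `ou_fit` objects, or lists with elements `nll` and `k`;
#'   `alt` must have more parameters than `null`.
#' @return An object of class `model_comparison` with fields `nll_null`,
#'   `nll_alt`, `k_null`, `k_alt`, `lrt`, `df`, `p`, `aic_null`, `aic_alt`,
#'   `delta_aic`.
#' @export
model_comparison <- function(null, alt) {
  kn <- null$k; ka <- alt$k
  if (ka <= kn)
    stop("`alt` must have more parameters than `null` (k_alt > k_null)",
         call. = FALSE)
  lrt <- 2 * (null$nll - alt$nll)
  df <- ka - kn
  p <- stats::pchisq(lrt, df = df, lower.tail = FALSE)
  structure(list(nll_null = null$nll, nll_alt = alt$nll,
                 k_null = kn, k_alt = ka,
                 lrt = lrt, df = df, p = p,
                 aic_null = aic(kn, null$nll), aic_alt = aic(ka, alt$nll),
                 delta_aic = aic(kn, null$nll) - aic(ka, alt$nll)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("LRT = %.4f, df = %d, p = %.3g\nAIC null = %.4f, AIC alt = %.4f (delta = %.4f)\n",
              x$lrt, x$df, x$p, x$aic_null, x$aic_alt, x$delta_aic))
  invisible(x)
}

#' Profile-likelihood surface over (theta, sigma)
#'
#' With mu fixed at its MLE, evaluates the NLL on log-spaced grids of theta
#' and sigma spanning +/- `span_log_units` log10 units around the optimum,
#' reported as `delta_nll` above the minimized NLL (tiny negatives from
#' finite optimizer tolerance are clamped to 0; non-finite evaluations are
#' recorded as `Inf`).
#'
#' @param data A `lineage_dataset`.
#' @param fit The corresponding converged [fit_mle()] result.
#' @param n_theta,n_sigma Grid sizes (default 61 x 61).
#' @param span_log_units Half-width of each grid in log10 units (default 3).
#' @return An object of class `profile_surface`: `theta_grid`, `sigma_grid`,
#'   `delta_nll` (n_theta x n_sigma), `mu_fixed`, `mle`, `nll_min`.
#' @export
profile_surface <- function(data, fit, n_theta = 61L, n_sigma = 61L,
                            span_log_units = 3) {
  stopifnot(inherits(fit, "ou_fit"))
  if (!isTRUE(fit$converged)) stop("`fit` did not converge", call. = FALSE)
  th <- 10^seq(log10(fit$params$theta) - span_log_units,
               log10(fit$params$theta) + span_log_units, length.out = n_theta)
  sg <- 10^seq(log10(fit$params$sigma) - span_log_units,
               log10(fit$params$sigma) + span_log_units, length.out = n_sigma)
  dn <- matrix(NA_real_, n_theta, n_sigma)
  si <- isTRUE(fit$stationary_init)
  for (i in seq_len(n_theta)) {
    for (j in seq_len(n_sigma)) {
      val <- tryCatch(
        negative_log_likelihood(
          ou_params(fit$params$mu, th[i], sg[j]), data, si),
        error = function(e) Inf)
      dn[i, j] <- if (is.finite(val)) val - fit$nll else Inf
    }
  }
  neg <- is.finite(dn) & dn < 0
  if (any(dn[neg] < -1e-6))
    warning("profile surface found a point ", format(min(dn[neg])),
            " below the reported optimum; fit may not be at the MLE")
  dn[neg] <- 0
  structure(list(theta_grid = th, sigma_grid = sg, delta_nll = dn,
                 mu_fixed = fit$params$mu,
                 mle = c(theta = fit$params$theta, sigma = fit$params$sigma),
                 nll_min = fit$nll),
            class = "profile_surface")
}

#' Replicate bootstrap of OU parameter estimates
#'
#' Nonparametric bootstrap over biological replicates: each draw resamples
#' the replicate trajectories with replacement (same count), refits the OU
#' model, and records (mu, theta, sigma) together with the derived
#' quantities 10^mu and sigma^2/(2 theta). Percentile intervals
#' (2.5/50/97.5) are computed per quantity directly from the bootstrap
#' draws - derived quantities are transformed per draw before taking
#' quantiles, never by transforming interval endpoints. The correlation of
#' log(theta) and log(sigma) across draws summarizes parameter coupling.
#'
#' Refits start from the full-data MLE with small jitter and a few
#' restarts, which is cheap and stable; draws whose refit fails are skipped
#' and counted, and more than 20% failures is an error.
#'
#' @param data A `lineage_dataset`.
#' @param B Number of bootstrap draws (default 2000).
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param config Optional list: `n_restarts` (default 3), `jitter` (sd of
#'   the start perturbation in (mu, log theta, log sigma), default 0.05),
#'   plus [fit_mle()] config entries for the refits.
#' @param fit Optional precomputed full-data [fit_mle()] result.
#' @return An object of class `ou_bootstrap`: `B`, `draws` (data frame with
#'   columns mu, theta, sigma, eq_freq, stat_var), `ci` (3 x quantity
#'   matrix), `corr_log_theta_log_sigma`, `n_failed`, `seed`.
#' @export
bootstrap <- function(data, B = 2000L, seed = 1L, config = list(), fit = NULL) {
  stopifnot(inherits(data, "lineage_dataset"), B >= 1L)
  cfg <- utils::modifyList(list(n_restarts = 3L, jitter = 0.05),
                           config %||% list())
  if (is.null(fit))
    fit <- fit_mle(data, config = cfg[setdiff(names(cfg), "jitter")],
                   seed = child_seed(seed, 0L))
  R <- length(data$replicates)
  draws <- matrix(NA_real_, nrow = B, ncol = 3L)
  n_failed <- 0L
  with_seed(seed, {
    idx <- matrix(sample.int(R, B * R, replace = TRUE), nrow = B)
    jit <- matrix(stats::rnorm(B * 3L, sd = cfg$jitter), nrow = B)
    for (b in seq_len(B)) {
      reps <- data$replicates[idx[b, ]]
      names(reps) <- paste0("bs", seq_len(R))
      d_b <- lineage_dataset(data$lineage, reps, data$epsilon, data$scale)
      start <- list(mu = fit$params$mu + jit[b, 1L],
                    theta = fit$params$theta * exp(jit[b, 2L]),
                    sigma = fit$params$sigma * exp(jit[b, 3L]))
      res <- tryCatch(
        fit_datasets(list(d_b),
                     utils::modifyList(cfg[setdiff(names(cfg), "jitter")],
                                       list(n_restarts = cfg$n_restarts)),
                     seed = child_seed(seed, b), start = start),
        error = function(e) NULL)
      if (is.null(res) || !is.finite(res$nll)) n_failed <- n_failed + 1L
      else draws[b, ] <- c(res$params$mu, res$params$theta, res$params$sigma)
    }
  })
  if (n_failed > 0.2 * B)
    stop("bootstrap refit failure rate above 20% (", n_failed, "/", B, ")",
         call. = FALSE)
  ok <- stats::complete.cases(draws)
  d <- data.frame(mu = draws[ok, 1L], theta = draws[ok, 2L],
                  sigma = draws[ok, 3L])
  d$eq_freq <- 10^d$mu
  d$stat_var <- d$sigma^2 / (2 * d$theta)
  ci <- vapply(d, stats::quantile, numeric(3L),
               probs = c(0.025, 0.5, 0.975), names = FALSE)
  rownames(ci) <- c("q025", "q50", "q975")
  corr <- if (nrow(d) > 1L && stats::sd(log(d$theta)) > 0 &&
              stats::sd(log(d$sigma)) > 0)
    stats::cor(log(d$theta), log(d$sigma)) else NA_real_
  structure(list(B = as.integer(B), draws = d, ci = ci,
                 corr_log_theta_log_sigma = corr,
                 n_failed = n_failed, seed = as.integer(seed),
                 fit = fit, lineage = data$lineage),
            class = "ou_bootstrap")
}

#' @export
print.ou_bootstrap <- function(x, ...) {
  cat(sprintf("Replicate bootstrap [%s]: B = %d (%d failed)\n",
              x$lineage, x$B, x$n_failed))
  print(signif(x$ci, 4))
  cat(sprintf("corr[log theta, log sigma] = %.3f\n",
              x$corr_log_theta_log_sigma))
  invisible(x)
}
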