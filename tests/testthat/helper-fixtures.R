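# Shared fixtures and independent oracles used across the suite.

# Canonical small synthetic panel (study-condition defaults, fixed seed).
std_panel <- function(seed = 42L) generate_panel(synthetic_panel_spec(seed = seed))

std_dataset <- function(lineage = "WT", seed = 42L) {
  floor_and_log(std_panel(seed)$table, lineage)
}

# A dense synthetic lineage with known parameters, for recovery checks.
dense_dataset <- function(params = ou_params(-6.8, 0.8, 0.7),
                          n_reps = 6L, n_points = 200L, seed = 7L) {
  reps <- lapply(seq_len(n_reps), function(r) {
    times <- seq_len(n_points) - 1
    list(times = times,
         y = simulate_exact(params, params$mu, times, 1L,
                            seed = seed * 1000L + r)[, 1L])
  })
  names(reps) <- paste0("r", seq_len(n_reps))
  lineage_dataset("dense", reps, 1e-8)
}

# Brute-force likelihood oracle: per-transition Gaussian log-density via
# dnorm, independent of the vectorized closed-form accumulation in the
# package.
oracle_nll <- function(params, data) {
  total <- 0
  for (r in data$replicates) {
    for (i in seq_along(r$y)[-1L]) {
      dt <- r$times[i] - r$times[i - 1L]
      m <- params$mu + (r$y[i - 1L] - params$mu) * exp(-params$theta * dt)
      v <- params$sigma^2 / (2 * params$theta) *
        (1 - exp(-2 * params$theta * dt))
      total <- total - stats::dnorm(r$y[i], m, sqrt(v), log = TRUE)
    }
  }
  total
}

# Upper-tail chi-square probability for even df via the finite Poisson
# series Q(2k, x) = exp(-x/2) * sum_{j<k} (x/2)^j / j! - an independent
# incomplete-gamma oracle.
oracle_chisq_upper_even_df <- function(x, df) {
  stopifnot(df %% 2 == 0)
  k <- df / 2
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# Closed-form P(extinct by t) for the linear birth-death process from one
# founder (b != d).
oracle_bd_extinction_by_t <- function(b, d, t) {
  e <- exp((b - d) * t)
  d * (e - 1) / (b * e - d)
}

write_panel_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  path
}
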