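# Birth-death branching simulators: exact Gillespie for the constant-rate
# linear process and a time-stepped phenotype-coupled clone simulator that
# builds an explicit lineage network (rooted forest) with per-edge division
# rates, snapshot classification and GraphML export.

#' Configuration for phenotype-coupled birth-death dynamics
#'
#' Division and death rates are tied to the OU trait by
#' `lambda(Y) = lambda0 * exp(alpha * (Y - mu_ref))` and
#' `delta(Y) = delta0 * exp(-beta * (Y - mu_ref))`, each clipped to
#' `[0, rate_cap]` for numerical stability. With `alpha = beta = 0` the
#' model reduces to the constant-rate linear birth-death process with
#' `b = lambda0`, `d = delta0`.
#'
#' @param lambda0 Baseline per-capita division rate (default 0.05).
#' @param delta0 Baseline per-capita death rate (default 0.04).
#' @param alpha,beta Non-negative coupling exponents of division and death
#'   to the trait deviation `Y - mu_ref` (defaults 0).
#' @param mu_ref Reference phenotype around which rates pivot; `NA`
#'   (default) means "use the OU equilibrium mean" in simulators that have
#'   one.
#' @param rate_cap Ceiling applied to both rates (default 10 per time unit).
#' @param n0 Initial number of clones (default 40).
#' @param t_max Simulation horizon (default 40 time units).
#' @param dt Time step of the clone simulator (default 0.05).
#' @param n_cap Population ceiling at which a run is truncated (flagged,
#'   not an error; default 1e5).
#' @param snapshot_time Time at which extant/extinct status is recorded
#'   (default 20).
#' @param inherit_sd Standard deviation of an optional Gaussian inheritance
#'   jitter added to a daughter's trait at division (default 0: daughters
#'   start exactly at the parent's current trait).
#' @return A list of class `branching_config`.
#' @export
branching_config <- function(lambda0 = 0.05, delta0 = 0.04,
                             alpha = 0, beta = 0, mu_ref = NA_real_,
                             rate_cap = 10, n0 = 40L, t_max = 40,
                             dt = 0.05, n_cap = 100000L,
                             snapshot_time = 20, inherit_sd = 0) {
  stop_if_not_scalar(lambda0, "lambda0", nonneg = TRUE)
  stop_if_not_scalar(delta0, "delta0", nonneg = TRUE)
  stop_if_not_scalar(alpha, "alpha", nonneg = TRUE)
  stop_if_not_scalar(beta, "beta", nonneg = TRUE)
  stop_if_not_scalar(rate_cap, "rate_cap", positive = TRUE)
  stop_if_not_scalar(dt, "dt", positive = TRUE)
  if (dt > t_max) stop("`dt` must not exceed `t_max`", call. = FALSE)
  if (n0 < 1L) stop("`n0` must be >= 1", call. = FALSE)
  structure(list(lambda0 = lambda0, delta0 = delta0, alpha = alpha,
                 beta = beta, mu_ref = mu_ref, rate_cap = rate_cap,
                 n0 = as.integer(n0), t_max = t_max, dt = dt,
                 n_cap = as.integer(n_cap), snapshot_time = snapshot_time,
                 inherit_sd = inherit_sd),
            class = "branching_config")
}

#' Phenotype-dependent division and death rates
#'
#' @param Y Trait value(s).
#' @param config A [branching_config()].
#' @return A list with components `lambda` and `delta`, clipped to
#'   `[0, rate_cap]`.
#' @export
phenotype_rates <- function(Y, config) {
  stopifnot(inherits(config, "branching_config"))
  if (is.na(config$mu_ref))
    stop("`mu_ref` is NA; set it explicitly or let a simulator resolve it ",
         "from the OU equilibrium mean", call. = FALSE)
  list(lambda = clip(config$lambda0 * exp(config$alpha * (Y - config$mu_ref)),
                     0, config$rate_cap),
       delta = clip(config$delta0 * exp(-config$beta * (Y - config$mu_ref)),
                    0, config$rate_cap))
}

#' Exact simulation of the constant-rate linear birth-death process
#'
#' Event-driven (Gillespie) realization: at population size n the next
#' event arrives after an Exponential((b + d) n) waiting time and is a
#' birth with probability b/(b + d). The run stops at extinction, at
#' `t_max`, or upon reaching `n_max` individuals.
#'
#' @param b,d Per-capita birth and death rates.
#' @param n0 Initial population size.
#' @param t_max Time horizon (may be `Inf` when `n_max` is finite).
#' @param seed Integer seed.
#' @param n_max Optional absorbing ceiling (default `Inf`).
#' @param record If `FALSE`, event times/sizes are not stored (cheaper for
#'   large ensembles); final state is always returned.
#' @return List with `times`, `sizes` (event-time step function, starting
#'   at (0, n0); `NULL` when `record = FALSE`), `final_time`, `final_size`,
#'   `n_births`, `n_deaths`, and `stopped` (one of "extinct", "t_max",
#'   "n_max").
#' @export
simulate_constant_bd <- function(b, d, n0, t_max, seed = NULL,
                                 n_max = Inf, record = TRUE) {
  stop_if_not_scalar(b, "b", nonneg = TRUE)
  stop_if_not_scalar(d, "d", nonneg = TRUE)
  if (n0 < 1L) stop("`n0` must be >= 1", call. = FALSE)
  if (b + d == 0) {
    return(list(times = if (record) 0, sizes = if (record) n0,
                final_time = t_max, final_size = n0,
                n_births = 0L, n_deaths = 0L, stopped = "t_max"))
  }
  with_seed(seed, {
    n <- as.integer(n0); t <- 0
    p_birth <- b / (b + d)
    nb <- 0L; nd <- 0L
    cap <- 256L
    if (record) {
      times <- numeric(cap); sizes <- integer(cap)
      times[1L] <- 0; sizes[1L] <- n; k <- 1L
    }
    # RNG draws consumed from pre-generated chunks to keep the event loop
    # cheap; chunking does not change the sampled law or seed determinism
    chunk <- 512L; ei <- chunk + 1L
    E <- numeric(0); U <- numeric(0)
    stopped <- "t_max"
    repeat {
      if (n == 0L) { stopped <- "extinct"; break }
      if (n >= n_max) { stopped <- "n_max"; break }
      if (ei > chunk) {
        E <- stats::rexp(chunk); U <- stats::runif(chunk); ei <- 1L
      }
      t_next <- t + E[ei] / ((b + d) * n)
      if (t_next > t_max) { t <- t_max; break }
      t <- t_next
      if (U[ei] < p_birth) { n <- n + 1L; nb <- nb + 1L }
      else { n <- n - 1L; nd <- nd + 1L }
      ei <- ei + 1L
      if (record) {
        k <- k + 1L
        if (k > cap) {
          cap <- cap * 2L
          length(times) <- cap; length(sizes) <- cap
        }
        times[k] <- t; sizes[k] <- n
      }
    }
    list(times = if (record) times[seq_len(k)],
         sizes = if (record) sizes[seq_len(k)],
         final_time = t, final_size = n,
         n_births = nb, n_deaths = nd, stopped = stopped)
  })
}

#' Simulate a phenotype-coupled lineage network
#'
#' Time-stepped hybrid simulation: every extant clone carries an OU trait
#' `Y` that advances by one exact OU transition per step of length
#' `config$dt`; it then divides with probability `1 - exp(-lambda(Y) dt)`
#' (the daughter inheriting the parent's current trait, plus optional
#' jitter) and dies with probability `1 - exp(-delta(Y) dt)`, death
#' resolved after division within the step. The result is a rooted forest
#' of clones with birth/death times, traits, per-edge division rates, and
#' extant/extinct status at `config$snapshot_time`.
#'
#' @param ou An [ou_params] object governing the trait; `config$mu_ref`
#'   defaults to `ou$mu` when `NA`.
#' @param config A [branching_config()].
#' @param seed Integer seed; identical seeds give node-for-node identical
#'   networks.
#' @param y0 Founder trait values (scalar recycled, or length `n0`);
#'   default: independent draws from the OU stationary law.
#' @param record_paths If `TRUE`, store each clone's sampled (time, Y)
#'   path (memory-heavy for large runs).
#' @return An object of class `lineage_network`: `nodes` data frame (id,
#'   parent, birth_time, death_time, y_birth, y_final, y_snapshot,
#'   status_snapshot), `edges` data frame (from, to, lambda), plus
#'   `snapshot_time`, `t_max`, `dt`, `truncated`, `seed`, and the
#'   configurations used.
#' @export
simulate_lineage_network <- function(ou, config, seed = NULL, y0 = NULL,
                                     record_paths = FALSE) {
  p <- as_ou_params(ou)
  stopifnot(inherits(config, "branching_config"))
  cfg <- config
  if (is.na(cfg$mu_ref)) cfg$mu_ref <- p$mu
  max_lambda_seen <- 0
  net <- with_seed(seed, {
    n0 <- cfg$n0
    cap <- max(256L, 2L * n0)
    id <- seq_len(n0)
    parent <- rep(NA_integer_, cap)
    birth_t <- rep(NA_real_, cap); death_t <- rep(NA_real_, cap)
    y_birth <- rep(NA_real_, cap); y_final <- rep(NA_real_, cap)
    y_snap <- rep(NA_real_, cap)
    sv <- p$sigma^2 / (2 * p$theta)
    founders_y <- if (is.null(y0)) stats::rnorm(n0, p$mu, sqrt(sv))
                  else rep_len(y0, n0)
    birth_t[seq_len(n0)] <- 0
    y_birth[seq_len(n0)] <- founders_y
    n_nodes <- n0
    alive_ids <- seq_len(n0)
    Y <- founders_y
    paths <- if (record_paths)
      lapply(seq_len(n0), function(i) list(t = 0, y = founders_y[i]))
    edges_from <- integer(0); edges_to <- integer(0); edges_lam <- numeric(0)
    a_step <- exp(-p$theta * cfg$dt)
    sd_step <- sqrt(sv * (1 - a_step^2))
    truncated <- FALSE
    snapshot_done <- FALSE
    t <- 0
    while (t < cfg$t_max - 1e-12 && length(alive_ids) > 0L) {
      t <- min(t + cfg$dt, cfg$t_max)
      na <- length(alive_ids)
      Y <- p$mu + (Y - p$mu) * a_step + sd_step * stats::rnorm(na)
      r <- phenotype_rates(Y, cfg)
      max_lambda_seen <- max(max_lambda_seen, r$lambda)
      u_div <- stats::runif(na)
      u_die <- stats::runif(na)
      divides <- u_div < 1 - exp(-r$lambda * cfg$dt)
      dies <- u_die < 1 - exp(-r$delta * cfg$dt)
      nd <- sum(divides)
      if (nd > 0L) {
        new_ids <- n_nodes + seq_len(nd)
        n_nodes <- n_nodes + nd
        while (n_nodes > cap) {
          cap <- cap * 2L
          length(parent) <- cap; length(birth_t) <- cap
          length(death_t) <- cap; length(y_birth) <- cap
          length(y_final) <- cap; length(y_snap) <- cap
        }
        par_ids <- alive_ids[divides]
        child_y <- Y[divides]
        if (cfg$inherit_sd > 0)
          child_y <- child_y + stats::rnorm(nd, 0, cfg$inherit_sd)
        parent[new_ids] <- par_ids
        birth_t[new_ids] <- t
        y_birth[new_ids] <- child_y
        edges_from <- c(edges_from, par_ids)
        edges_to <- c(edges_to, new_ids)
        edges_lam <- c(edges_lam, r$lambda[divides])
        if (record_paths)
          paths <- c(paths, lapply(seq_len(nd), function(i)
            list(t = t, y = child_y[i])))
        alive_ids <- c(alive_ids, new_ids)
        Y <- c(Y, child_y)
      } else {
        new_ids <- integer(0)
      }
      # death after division: a clone may leave a daughter born this step
      if (any(dies)) {
        dead_ids <- alive_ids[seq_len(na)][dies]
        death_t[dead_ids] <- t
        y_final[dead_ids] <- Y[seq_len(na)][dies]
        keep <- rep(TRUE, length(alive_ids))
        keep[seq_len(na)][dies] <- FALSE
        alive_ids <- alive_ids[keep]
        Y <- Y[keep]
      }
      if (record_paths && length(alive_ids)) {
        for (i in seq_along(alive_ids)) {
          pp <- paths[[alive_ids[i]]]
          paths[[alive_ids[i]]] <- list(t = c(pp$t, t), y = c(pp$y, Y[i]))
        }
      }
      if (!snapshot_done && t >= cfg$snapshot_time - 1e-12) {
        y_snap[alive_ids] <- Y
        snapshot_done <- TRUE
      }
      if (length(alive_ids) >= cfg$n_cap) { truncated <- TRUE; break }
    }
    y_final[alive_ids] <- Y
    nodes <- data.frame(id = seq_len(n_nodes),
                        parent = parent[seq_len(n_nodes)],
                        birth_time = birth_t[seq_len(n_nodes)],
                        death_time = death_t[seq_len(n_nodes)],
                        y_birth = y_birth[seq_len(n_nodes)],
                        y_final = y_final[seq_len(n_nodes)],
                        y_snapshot = y_snap[seq_len(n_nodes)])
    nodes$status_snapshot <- snapshot_status(nodes, cfg$snapshot_time)
    structure(
      list(nodes = nodes,
           edges = data.frame(from = edges_from, to = edges_to,
                              lambda = edges_lam),
           snapshot_time = cfg$snapshot_time, t_max = cfg$t_max,
           dt = cfg$dt, truncated = truncated, end_time = t,
           seed = seed, ou = p, config = cfg,
           paths = if (record_paths) paths),
      class = "lineage_network")
  })
  # one division per clone per step: flag step sizes too coarse for the
  # realized division rates
  if (max_lambda_seen * cfg$dt > 0.2)
    warning(sprintf(
      "max lambda * dt = %.3g > 0.2; division probabilities may saturate, consider a smaller dt",
      max_lambda_seen * cfg$dt), call. = FALSE)
  net
}

snapshot_status <- function(nodes, t_snap) {
  status <- rep(NA_character_, nrow(nodes))
  born <- nodes$birth_time <= t_snap + 1e-12
  dead <- !is.na(nodes$death_time) & nodes$death_time <= t_snap + 1e-12
  status[born & !dead] <- "extant"
  status[born & dead] <- "extinct"
  status  # NA for clones not yet born at the snapshot
}

#' @export
print.lineage_network <- function(x, ...) {
  cl <- snapshot_classification(x, x$snapshot_time)
  cat(sprintf("Lineage network: %d clone(s), %d division(s); at t = %g: %d extant, %d extinct%s\n",
              nrow(x$nodes), nrow(x$edges), x$snapshot_time,
              length(cl$extant), length(cl$extinct),
              if (x$truncated) " [truncated at n_cap]" else ""))
  invisible(x)
}

#' Classify clones as extant or extinct at a snapshot time
#'
#' Extant: born by `t_snap` and not yet dead; extinct: dead by `t_snap`;
#' clones born after the snapshot are excluded from both sets.
#'
#' @param net A `lineage_network`.
#' @param t_snap Snapshot time, at most the network's `t_max`.
#' @return List with integer vectors `extant` and `extinct` of clone ids.
#' @export
snapshot_classification <- function(net, t_snap) {
  stopifnot(inherits(net, "lineage_network"))
  if (t_snap > net$t_max)
    stop("`t_snap` exceeds the simulation horizon t_max", call. = FALSE)
  st <- snapshot_status(net$nodes, t_snap)
  list(extant = net$nodes$id[!is.na(st) & st == "extant"],
       extinct = net$nodes$id[!is.na(st) & st == "extinct"])
}

#' Downsample extant clones for display
#'
#' If the network has more than `max_nodes` extant clones at its snapshot
#' time, keeps a seeded uniform random subset of them plus all their
#' ancestors (so the displayed forest stays connected); otherwise returns
#' the network unchanged. The underlying simulation is never altered -
#' this is a view for visualization and export.
#'
#' @param net A `lineage_network`.
#' @param max_nodes Maximum number of extant clones to retain (default 2000).
#' @param seed Integer seed for the subset draw.
#' @return A `lineage_network` restricted to the selected clones and their
#'   ancestor paths, with attribute `downsampled = TRUE` when reduction
#'   occurred; the node column `in_sample` marks the drawn extant subset
#'   (ancestors kept only for connectivity have `in_sample = FALSE`).
#' @export
downsample_extant <- function(net, max_nodes = 2000L, seed = NULL) {
  stopifnot(inherits(net, "lineage_network"), max_nodes >= 1L)
  cl <- snapshot_classification(net, net$snapshot_time)
  if (length(cl$extant) <= max_nodes) return(net)
  keep_extant <- with_seed(seed, sample(cl$extant, max_nodes))
  keep <- unique(unlist(lapply(keep_extant, function(i) {
    path <- i
    while (!is.na(net$nodes$parent[path[1L]]))
      path <- c(net$nodes$parent[path[1L]], path)
    path
  })))
  keep <- sort(keep)
  out <- net
  out$nodes <- net$nodes[net$nodes$id %in% keep, , drop = FALSE]
  # ancestors enter only for connectivity; in_sample marks the drawn subset
  out$nodes$in_sample <- out$nodes$id %in% keep_extant
  out$edges <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep,
                         , drop = FALSE]
  if (!is.null(net$paths)) out$paths <- net$paths[keep]
  attr(out, "downsampled") <- TRUE
  out
}

as_igraph_network <- function(net) {
  nodes <- net$nodes
  vdf <- data.frame(name = as.character(nodes$id),
                    birth_time = nodes$birth_time,
                    death_time = ifelse(is.na(nodes$death_time), -1,
                                        nodes$death_time),
                    y_birth = nodes$y_birth,
                    y_final = ifelse(is.na(nodes$y_final), NaN, nodes$y_final),
                    status = ifelse(is.na(nodes$status_snapshot), "unborn",
                                    nodes$status_snapshot))
  edf <- data.frame(from = as.character(net$edges$from),
                    to = as.character(net$edges$to),
                    lambda = net$edges$lambda)
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Export a lineage network to file
#'
#' GraphML (loadable by standard graph tools), a delimited edge list, or a
#' JSON dump of nodes and edges. Node attributes carry trait values,
#' birth/death times and snapshot status; edges carry the division rate
#' `lambda` at the division event.
#'
#' @param net A `lineage_network`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"edgelist"`, `"json"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist", "json")) {
  stopifnot(inherits(net, "lineage_network"))
  format <- match.arg(format)
  switch(format,
    graphml = igraph::write_graph(as_igraph_network(net), path,
                                  format = "graphml"),
    edgelist = utils::write.csv(net$edges, path, row.names = FALSE),
    json = jsonlite::write_json(
      list(nodes = net$nodes, edges = net$edges,
           snapshot_time = net$snapshot_time, t_max = net$t_max),
      path, dataframe = "columns", digits = NA, auto_unbox = TRUE,
      na = "null"))
  invisible(path)
}
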