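# Seeded generator of evolution-experiment-like replicate frequency panels
# with known ground-truth OU parameters. Trajectories are simulated exactly
# on the log10 scale, mapped back to frequencies x = 10^y, and observations
# below a true detection floor are recorded as exact zeros - emulating the
# censoring structure of real mutation-frequency assays so the full
# pipeline (flooring, log transform, likelihood, bootstrap) is testable
# end to end.

default_panel_lineages <- function() {
  list(WT = ou_params(-6.799, 0.775, 0.727),
       priA = ou_params(-5.000, 0.117, 0.436),
       recG = ou_params(-7.652, 8.516, 2.789))
}

#' Specification of a synthetic replicate frequency panel
#'
#' Defaults mirror the reference study conditions: three lineages (WT,
#' priA, recG) with their fitted OU triples, 5 replicates each, sampling
#' grid t = 0, 3, ..., 21, stationary initial draws, and a true detection
#' floor of 1e-8 below which frequencies are recorded as 0.
#'
#' @param lineages Named list of [ou_params] per lineage.
#' @param n_replicates Replicates per lineage (default 5).
#' @param t_grid Sampling times (default `seq(0, 21, by = 3)`).
#' @param y0_mode `"stationary"` (draw each replicate's start from the
#'   stationary law) or `"fixed"` (start at `y0_fixed`).
#' @param y0_fixed Start value used when `y0_mode = "fixed"`.
#' @param detection_floor_true Frequency below which an observation is
#'   recorded as exact 0 (default 1e-8); 0 disables censoring.
#' @param seed Integer seed.
#' @return List of class `synthetic_panel_spec`.
#' @export
synthetic_panel_spec <- function(lineages = default_panel_lineages(),
                                 n_replicates = 5L,
                                 t_grid = seq(0, 21, by = 3),
                                 y0_mode = c("stationary", "fixed"),
                                 y0_fixed = NULL,
                                 detection_floor_true = 1e-8,
                                 seed = 1L) {
  stopifnot(is.list(lineages), length(lineages) >= 1L,
            !is.null(names(lineages)))
  lineages <- lapply(lineages, as_ou_params)
  if (any(diff(t_grid) <= 0)) stop("`t_grid` must be increasing", call. = FALSE)
  if (detection_floor_true < 0) stop("floor must be >= 0", call. = FALSE)
  structure(list(lineages = lineages, n_replicates = as.integer(n_replicates),
                 t_grid = t_grid, y0_mode = match.arg(y0_mode),
                 y0_fixed = y0_fixed, detection_floor_true = detection_floor_true,
                 seed = as.integer(seed)),
            class = "synthetic_panel_spec")
}

#' Generate a synthetic frequency panel with known truth
#'
#' @param spec A [synthetic_panel_spec()].
#' @return List of class `synthetic_panel` with `table` (long-format data
#'   frame: lineage, replicate, time, value) and `truth` (per-lineage OU
#'   parameters plus the generating spec), deterministic given
#'   `spec$seed`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_panel_spec"))
  rows <- list()
  for (li in seq_along(spec$lineages)) {
    lab <- names(spec$lineages)[li]
    p <- spec$lineages[[li]]
    sv <- p$sigma^2 / (2 * p$theta)
    for (r in seq_len(spec$n_replicates)) {
      sub_seed <- child_seed(spec$seed, 1000L * li + r)
      y0 <- if (spec$y0_mode == "stationary")
        with_seed(child_seed(sub_seed, 1L),
                  stats::rnorm(1L, p$mu, sqrt(sv)))
      else spec$y0_fixed %||% p$mu
      y <- simulate_exact(p, y0 = y0, times = spec$t_grid, n_reps = 1L,
                          seed = sub_seed)[, 1L]
      x <- 10^y
      if (spec$detection_floor_true > 0)
        x[x < spec$detection_floor_true] <- 0
      rows[[length(rows) + 1L]] <-
        data.frame(lineage = lab, replicate = paste0("rep", r),
                   time = spec$t_grid, value = x,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  truth <- list(
    lineages = lapply(spec$lineages, function(p)
      list(mu = p$mu, theta = p$theta, sigma = p$sigma)),
    n_replicates = spec$n_replicates, t_grid = spec$t_grid,
    y0_mode = spec$y0_mode,
    detection_floor_true = spec$detection_floor_true, seed = spec$seed)
  structure(list(table = tab, truth = truth), class = "synthetic_panel")
}

#' Write a canonical fixture bundle to a directory
#'
#' Writes a small panel (default lineages, 5 replicates, 8 time points) as
#' `panel.csv`, its ground truth as `truth.json`, and a hand-built 3-clone
#' network fixture (`network_nodes.csv`, `network_edges.csv`). Two calls
#' with the same seed produce byte-identical files.
#'
#' @param dir Target directory (created if needed).
#' @param seed Integer seed for the panel.
#' @return `dir`, invisibly.
#' @export
fixture_bundle <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  panel <- generate_panel(synthetic_panel_spec(seed = seed))
  tab <- panel$table
  tab$value <- format(tab$value, digits = 17, trim = TRUE, scientific = TRUE)
  utils::write.csv(tab, file.path(dir, "panel.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(panel$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  # minimal hand-built rooted forest: founder -> two daughters, one of
  # which dies before the snapshot
  utils::write.csv(
    data.frame(id = 1:3, parent = c(NA, 1L, 1L),
               birth_time = c(0, 4, 6), death_time = c(NA, 5, NA),
               y = c(-6.8, -6.5, -7.1)),
    file.path(dir, "network_nodes.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(from = c(1L, 1L), to = c(2L, 3L), lambda = c(0.05, 0.06)),
    file.path(dir, "network_edges.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
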