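test_that("phenotype rates follow the exponential coupling with clipping", {
  cfg <- branching_config(lambda0 = 0.05, delta0 = 0.04, alpha = 1,
                          beta = 0.5, mu_ref = -6)
  r <- phenotype_rates(-6, cfg)
  expect_equal(r$lambda, 0.05); expect_equal(r$delta, 0.04)
  # flat couplings: rates independent of Y
  cfg0 <- branching_config(alpha = 0, beta = 0, mu_ref = 0)
  expect_equal(phenotype_rates(c(-3, 0, 5), cfg0)$lambda, rep(0.05, 3))
  # clipping contract
  cfg_clip <- branching_config(lambda0 = 0.05, alpha = 1, mu_ref = 0,
                               rate_cap = 10)
  expect_equal(phenotype_rates(20, cfg_clip)$lambda, 10)
  expect_error(phenotype_rates(0, branching_config()), "mu_ref")
})

test_that("constant-rate birth-death matches classical closed forms", {
  # conservation at every event and seed determinism
  r1 <- simulate_constant_bd(0.05, 0.04, 40, 50, seed = 3)
  r2 <- simulate_constant_bd(0.05, 0.04, 40, 50, seed = 3)
  expect_identical(r1, r2)
  expect_equal(r1$final_size, 40L + r1$n_births - r1$n_deaths)
  expect_equal(r1$sizes[length(r1$sizes)], r1$final_size)

  # critical case b = d: ensemble mean stays at n0 (martingale)
  n_runs <- 2000L
  finals <- vapply(seq_len(n_runs), function(i)
    simulate_constant_bd(0.05, 0.05, 10, 20, seed = 4000L + i,
                         record = FALSE)$final_size, numeric(1))
  # Var[N_t] = 2 b n0 t in the critical case
  se <- sqrt(2 * 0.05 * 10 * 20 / n_runs)
  expect_lt(abs(mean(finals) - 10), 3 * se)

  # supercritical mean growth: E[N(t)] = n0 exp((b - d) t)
  finals2 <- vapply(seq_len(2000L), function(i)
    simulate_constant_bd(0.05, 0.04, 40, 10, seed = 8000L + i,
                         record = FALSE)$final_size, numeric(1))
  expect_lt(abs(mean(finals2) - 40 * exp(0.1)),
            3 * stats::sd(finals2) / sqrt(2000))
})

test_that("ultimate extinction fraction from one founder approximates d/b", {
  n_runs <- 4000L
  extinct <- vapply(seq_len(n_runs), function(i)
    simulate_constant_bd(0.05, 0.04, 1, Inf, seed = 12000L + i,
                         n_max = 1000, record = FALSE)$final_size == 0,
    logical(1))
  expect_lt(abs(mean(extinct) - 0.8), 0.02)
})

test_that("lineage networks are valid seeded forests", {
  p <- ou_params(-6.8, 0.775, 0.727)
  cfg <- branching_config(alpha = 0.5, beta = 0.5, n0 = 20L, t_max = 30,
                          n_cap = 20000L)
  net <- simulate_lineage_network(p, cfg, seed = 17)
  net2 <- simulate_lineage_network(p, cfg, seed = 17)
  expect_identical(net$nodes, net2$nodes)
  expect_identical(net$edges, net2$edges)
  expect_false(identical(
    net$nodes, simulate_lineage_network(p, cfg, seed = 18)$nodes))

  nodes <- net$nodes
  roots <- is.na(nodes$parent)
  expect_equal(sum(roots), 20L)
  # forest: each non-root has exactly one parent, born after it
  kids <- nodes[!roots, ]
  expect_true(all(kids$birth_time >=
                    nodes$birth_time[match(kids$parent, nodes$id)]))
  expect_equal(nrow(net$edges), nrow(kids))
  expect_true(all(net$edges$lambda > 0))
  # death times, when present, follow birth times
  dd <- nodes[!is.na(nodes$death_time), ]
  expect_true(all(dd$death_time >= dd$birth_time))
})

test_that("all-lethal and immortal limits behave as contracts state", {
  p <- ou_params(0, 1, 0.3)
  # overwhelming death, no division: founders die out as isolated nodes
  lethal <- branching_config(lambda0 = 1e-9, delta0 = 50, rate_cap = 50,
                             n0 = 15L, t_max = 5, snapshot_time = 5)
  net <- simulate_lineage_network(p, lethal, seed = 1)
  expect_equal(nrow(net$nodes), 15L)
  expect_equal(nrow(net$edges), 0L)
  cl <- snapshot_classification(net, 5)
  expect_equal(length(cl$extinct), 15L)
  expect_equal(length(cl$extant), 0L)
})

test_that("snapshot classification follows birth and death times", {
  p <- ou_params(0, 1, 0.2)
  cfg <- branching_config(alpha = 0.3, beta = 0.3, n0 = 12L, t_max = 20,
                          snapshot_time = 10)
  net <- simulate_lineage_network(p, cfg, seed = 5)
  # t = 0: exactly the founders are extant
  cl0 <- snapshot_classification(net, 0)
  expect_setequal(cl0$extant, net$nodes$id[is.na(net$nodes$parent)])
  expect_length(cl0$extinct, 0L)
  expect_error(snapshot_classification(net, 21), "t_max")

  # hand-built forest: deaths at 5 and 25 straddle the snapshot at 20
  hand <- net
  hand$nodes <- data.frame(id = 1:3, parent = c(NA, 1L, 1L),
                           birth_time = c(0, 1, 2),
                           death_time = c(25, 5, NA),
                           y_birth = 0, y_final = 0, y_snapshot = 0,
                           status_snapshot = NA)
  hand$t_max <- 40
  cl <- snapshot_classification(hand, 20)
  expect_setequal(cl$extant, c(1L, 3L))
  expect_equal(cl$extinct, 2L)
})

test_that("phenotype selection enriches extant clones when rates couple to the trait", {
  p <- ou_params(0, 0.5, 1)
  cfg <- branching_config(lambda0 = 0.15, delta0 = 0.15, alpha = 0.7,
                          beta = 0.7, n0 = 10L, t_max = 10, dt = 0.1,
                          rate_cap = 1.5, snapshot_time = 10, n_cap = 5000L)
  wins <- 0L; n_informative <- 0L
  for (s in 1:200) {
    net <- simulate_lineage_network(p, cfg, seed = 3000L + s)
    st <- net$nodes$status_snapshot
    y_ext <- net$nodes$y_snapshot[!is.na(st) & st == "extant"]
    y_dead <- net$nodes$y_final[!is.na(st) & st == "extinct"]
    if (length(y_ext) && length(y_dead)) {
      n_informative <- n_informative + 1L
      if (mean(y_ext) > mean(y_dead)) wins <- wins + 1L
    }
  }
  # sign test: survivors carry higher trait values than casualties
  expect_lt(stats::binom.test(wins, n_informative,
                              alternative = "greater")$p.value, 0.01)
})

test_that("small-step network dynamics reproduce constant-rate extinction", {
  # alpha = beta = 0 collapses the clone simulator onto the linear
  # birth-death process; compare P(extinct by t) with the Gillespie
  # simulator and the analytic value
  b <- 0.3; d <- 0.25; t_end <- 15
  cfg <- branching_config(lambda0 = b, delta0 = d, alpha = 0, beta = 0,
                          mu_ref = 0, n0 = 1L, t_max = t_end, dt = 0.05,
                          snapshot_time = t_end, n_cap = 100000L)
  p <- ou_params(0, 1, 0.3)
  n_runs <- 800L
  ext_net <- mean(vapply(seq_len(n_runs), function(i) {
    net <- simulate_lineage_network(p, cfg, seed = 40000L + i)
    cl <- snapshot_classification(net, t_end)
    length(cl$extant) == 0L
  }, logical(1)))
  ext_gil <- mean(vapply(seq_len(n_runs), function(i)
    simulate_constant_bd(b, d, 1, t_end, seed = 50000L + i,
                         record = FALSE)$final_size == 0, logical(1)))
  truth <- oracle_bd_extinction_by_t(b, d, t_end)
  se <- sqrt(truth * (1 - truth) / n_runs)
  expect_lt(abs(ext_net - ext_gil), 2 * sqrt(2) * se + 0.02)
  expect_lt(abs(ext_gil - truth), 4 * se)
})

test_that("halving the step hardly changes ensemble extinction", {
  b <- 0.3; d <- 0.25; t_end <- 12; n_runs <- 600L
  p <- ou_params(0, 1, 0.3)
  frac <- function(dt, seed0) {
    cfg <- branching_config(lambda0 = b, delta0 = d, alpha = 0, beta = 0,
                            mu_ref = 0, n0 = 1L, t_max = t_end, dt = dt,
                            snapshot_time = t_end, n_cap = 100000L)
    mean(vapply(seq_len(n_runs), function(i) {
      net <- simulate_lineage_network(p, cfg, seed = seed0 + i)
      length(snapshot_classification(net, t_end)$extant) == 0L
    }, logical(1)))
  }
  f1 <- frac(0.1, 60000L)
  f2 <- frac(0.05, 70000L)
  p_ref <- oracle_bd_extinction_by_t(b, d, t_end)
  se <- sqrt(p_ref * (1 - p_ref) / n_runs)
  expect_lt(abs(f1 - f2), 2 * sqrt(2) * se)
})

test_that("downsampling keeps ancestor paths and leaves the network intact", {
  p <- ou_params(0, 0.5, 0.6)
  cfg <- branching_config(lambda0 = 0.4, delta0 = 0.1, alpha = 0.2,
                          beta = 0.2, n0 = 5L, t_max = 12, dt = 0.05,
                          snapshot_time = 12, n_cap = 10000L)
  net <- simulate_lineage_network(p, cfg, seed = 9)
  n_extant <- length(snapshot_classification(net, 12)$extant)
  expect_gt(n_extant, 10)  # enough to downsample

  # request below the extant count: identity
  expect_identical(downsample_extant(net, n_extant + 10L, seed = 1), net)

  small <- downsample_extant(net, 3L, seed = 2)
  expect_true(isTRUE(attr(small, "downsampled")))
  expect_equal(sum(small$nodes$in_sample), 3L)
  # every kept non-root's parent is kept (connectivity via ancestors)
  kids <- small$nodes[!is.na(small$nodes$parent), ]
  expect_true(all(kids$parent %in% small$nodes$id))
  # underlying network untouched; same subset under the same seed
  expect_equal(nrow(net$nodes), nrow(simulate_lineage_network(p, cfg, seed = 9)$nodes))
  expect_identical(small$nodes, downsample_extant(net, 3L, seed = 2)$nodes)

  # max 1: a single drawn extant clone plus its root path
  one <- downsample_extant(net, 1L, seed = 3)
  expect_equal(sum(one$nodes$in_sample), 1L)
  expect_true(one$nodes$id[one$nodes$in_sample] %in%
                snapshot_classification(one, 12)$extant)
})

test_that("network export round-trips through GraphML and edge lists", {
  p <- ou_params(0, 1, 0.4)
  cfg <- branching_config(lambda0 = 0.3, delta0 = 0.1, n0 = 3L, t_max = 8,
                          mu_ref = 0, snapshot_time = 8)
  net <- simulate_lineage_network(p, cfg, seed = 2)
  f <- tempfile(fileext = ".graphml")
  export_network(net, f, format = "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(sort(igraph::E(g)$lambda), sort(net$edges$lambda),
               tolerance = 1e-6)
  expect_setequal(unique(igraph::V(g)$status),
                  unique(ifelse(is.na(net$nodes$status_snapshot), "unborn",
                                net$nodes$status_snapshot)))

  f2 <- tempfile(fileext = ".csv")
  export_network(net, f2, format = "edgelist")
  el <- utils::read.csv(f2)
  expect_equal(nrow(el), nrow(net$edges))

  f3 <- tempfile(fileext = ".json")
  export_network(net, f3, format = "json")
  back <- jsonlite::read_json(f3, simplifyVector = TRUE)
  expect_equal(length(back$nodes$id), nrow(net$nodes))

  expect_error(export_network(net, tempfile(), format = "pajek"))
})
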