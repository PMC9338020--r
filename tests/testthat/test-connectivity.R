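# Latency gating, graph construction, null models and edge-set contrasts.

test_that("pair latencies: exact shift, Gaussian FWHM, bimodal rejection", {
  a <- seq(1, 99, by = 0.4)
  b <- a + 0.005
  pl <- pair_latencies(a, b)
  expect_equal(pl$mean_latency, 5, tolerance = 1e-9)
  expect_lte(pl$fwhm, 1)
  expect_true(pl$unimodal)
  # Gaussian jitter sigma = 2.6 ms: FWHM ~ 2.355 * sigma ~ 6.1 ms
  set.seed(44)
  b2 <- sort(a + 0.005 + rnorm(length(a), 0, 0.0026))
  pl2 <- pair_latencies(a, b2)
  expect_lt(abs(pl2$fwhm - 6.1), 1.6)
  expect_lt(abs(pl2$mean_latency - 5), 0.5)
  # two latency clusters at -8 and +8 ms: multimodal, not unimodal
  off <- rep(c(-0.008, 0.008), length.out = length(a))
  b3 <- sort(a + off)
  pl3 <- pair_latencies(a, b3)
  expect_lt(pl3$dip_p, 0.1)
  expect_false(pl3$unimodal)
  # too few matches: unconnectable
  pl4 <- pair_latencies(c(1, 50), c(30, 80), min_latencies = 10)
  expect_false(pl4$connectable)
})

test_that("node classes follow the degree-imbalance threshold strictly", {
  sts <- spike_train_set(as.list(stats::setNames(lapply(1:12, function(i)
    sort(runif(20, 0, 60))), paste0("u", 1:12))), duration = 60,
    sort_times = TRUE)
  mk_edges <- function(pairs) {
    data.frame(source = pairs[, 1], target = pairs[, 2], sttc = 0.5,
               mean_latency_ms = 5, fwhm_ms = 5, dip_p = 0.5,
               stringsAsFactors = FALSE)
  }
  # u1: 10 incoming, 0 outgoing -> receiver (imbalance 1 > 0.8)
  e1 <- mk_edges(cbind(paste0("u", 2:11), rep("u1", 10)))
  g1 <- orgMEA:::graph_from_edges(sts, e1)
  expect_equal(g1$nodes$class[g1$nodes$unit_id == "u1"], "receiver")
  # u1: 9 outgoing, 1 incoming -> imbalance exactly 0.8, not > 0.8 -> broker
  e2 <- mk_edges(rbind(cbind(rep("u1", 9), paste0("u", 2:10)),
                       c("u11", "u1")))
  g2 <- orgMEA:::graph_from_edges(sts, e2)
  expect_equal(g2$nodes$class[g2$nodes$unit_id == "u1"], "broker")
  # class fractions always partition the nodes
  expect_equal(sum(table(g2$nodes$class)), nrow(g2$nodes))
  # largest / second component bookkeeping
  e3 <- mk_edges(rbind(c("u1", "u2"), c("u2", "u3"), c("u5", "u6")))
  g3 <- orgMEA:::graph_from_edges(sts, e3)
  expect_setequal(g3$largest_component, c("u1", "u2", "u3"))
  expect_setequal(g3$second_component, c("u5", "u6"))
})

test_that("a synthetic chain is classified sender -> broker -> receiver", {
  edges <- data.frame(source = c("1", "2"), target = c("2", "3"),
                      transmission_probability = 0.9,
                      latency_mean_ms = 5, latency_sd_ms = 1)
  sim <- simulate_spike_network(n_units = 3, duration_s = 300,
                                baseline_rate_hz = 2, edges = edges,
                                chain = FALSE, seed = 31)
  g <- build_graph(sim$trains)
  cls <- stats::setNames(g$nodes$class, g$nodes$unit_id)
  expect_equal(unname(cls["1"]), "sender")
  expect_equal(unname(cls["2"]), "broker")
  expect_equal(unname(cls["3"]), "receiver")
})

test_that("burst-shuffle surrogate preserves the population count vector exactly", {
  fx <- recovery_fixture()
  trains <- fx$sim$trains
  catalog <- detect_bursts(population_rate(trains, "mua_smooth"))
  expect_gte(nrow(catalog), 5)
  sh <- shuffle_unit_labels(trains, catalog)
  count_vec <- function(tr) {
    tabulate(pmin(floor(unlist(tr$spikes) / 0.001) + 1L, 300000L),
             nbins = 300000L)
  }
  expect_identical(count_vec(trains), count_vec(sh))
  # label permutation preserves the total spike count
  expect_equal(sum(lengths(sh$spikes)), sum(lengths(trains$spikes)))
})

test_that("burst-shuffle null places the bulk of STTC values below 0.35", {
  fx <- recovery_fixture()
  catalog <- detect_bursts(population_rate(fx$sim$trains, "mua_smooth"))
  nul <- null_threshold(trains = fx$sim$trains, catalog = catalog,
                        mode = "burst_shuffle", n_reps = 2, seed = 77)
  expect_gte(nul$frac_below_threshold, 0.9)
  expect_error(null_threshold(trains = fx$sim$trains, catalog = catalog,
                              mode = "burst_shuffle", n_reps = 0, seed = 1),
               "n_reps")
})

test_that("edge-swap surrogate preserves the undirected degree sequence", {
  g <- recovery_graph()
  expect_gte(nrow(g$edges), 5)
  nul <- null_threshold(graph = g, mode = "edge_swap", n_reps = 3, seed = 5)
  expect_length(nul$sender_counts, 3)
  # node-class counts partition all nodes in every replicate
  expect_equal(nul$sender_counts + nul$receiver_counts + nul$broker_counts,
               rep(nrow(g$nodes), 3))
})

test_that("edge-distribution fits rank a gamma-shaped histogram correctly", {
  # place points exactly at bin midpoints so the histogram matches the curve
  mids <- seq(0.375, 0.975, by = 0.05)
  k <- 2.5; sc <- 0.09
  curve <- (1 / (gamma(k) * sc^k)) * mids^(k - 1) * exp(-mids / sc)
  counts <- round(curve / sum(curve) * 5000)
  strengths <- rep(mids, counts)
  fit <- fit_edge_distributions(strengths)
  expect_equal(fit$best, "gamma")
  expect_lt(abs(fit$fits$gamma$params["b"] - k) / k, 0.05)
  expect_lt(abs(fit$fits$gamma$params["c"] - sc) / sc, 0.05)
  # identical conditions: fractional difference identically zero
  fd <- edge_fit_fractional_difference(fit, fit)
  expect_equal(max(abs(fd$fractional_difference)), 0)
  # 3 nonempty bins: 3-parameter models fail, 2-parameter power law survives
  few <- rep(c(0.4, 0.5, 0.6), c(30, 20, 10))
  fit2 <- fit_edge_distributions(few)
  expect_false(isTRUE(fit2$fits$gamma$converged))
  expect_false(isTRUE(fit2$fits$exponential$converged))
  expect_true(isTRUE(fit2$fits$power_law$converged))
})

test_that("edge-set comparison distinguishes shared, silenced and induced edges", {
  g <- recovery_graph()
  same <- compare_edge_sets(g, g)
  expect_equal(unname(same$fractions["shared"]), 1)
  expect_equal(unname(same$fractions["silenced"]), 0)
  expect_equal(nrow(same$induced), 0L)
  # synthetic drug condition: weak edges (< 0.45) deleted, strong ones added
  gb <- g
  keep <- g$edges$sttc >= 0.45
  added <- data.frame(source = "49", target = "50", sttc = 0.9,
                      mean_latency_ms = 4, fwhm_ms = 5, dip_p = 0.9,
                      stringsAsFactors = FALSE)
  gb$edges <- rbind(g$edges[keep, ], added)
  cmp <- compare_edge_sets(g, gb)
  if (nrow(cmp$silenced) && nrow(cmp$induced))
    expect_lt(mean(cmp$silenced$strength), mean(cmp$induced$strength))
  disjoint <- gb
  disjoint$edges <- added
  cmp2 <- compare_edge_sets(g, disjoint)
  expect_equal(unname(cmp2$fractions["shared"]),
               length(intersect(edge_key(g$edges), edge_key(added))) /
                 length(union(edge_key(g$edges), edge_key(added))))
})
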