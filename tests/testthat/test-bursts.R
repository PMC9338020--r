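# Population rate, burst detection and burst similarity.

test_that("smoothing conserves spike count and is additive", {
  one <- spike_train_set(list(u = 1.0), duration = 4)
  pr <- population_rate(one, mode = "unit_ma5")
  expect_equal(sum(pr$rate), 1, tolerance = 1e-9)
  on_idx <- which(pr$rate > 0)
  expect_true(all(abs(pr$t[on_idx] - 1.0) <= 0.0035))
  two <- spike_train_set(list(u = 1.0, v = 1.0), duration = 4)
  pr2 <- population_rate(two, mode = "unit_ma5")
  expect_equal(max(pr2$rate), 2 * max(pr$rate), tolerance = 1e-9)
  prg <- population_rate(one, mode = "mua_smooth")
  expect_equal(sum(prg$rate), 1, tolerance = 1e-9)
})

test_that("constant-rate populations produce no bursts", {
  per <- spike_train_set(list(u = seq(0.01, 29.99, by = 0.01)), duration = 30)
  pr <- population_rate(per, mode = "mua_smooth")
  expect_equal(nrow(detect_bursts(pr)), 0L)
})

test_that("Gaussian bumps are detected at their centers and merged within 1 s", {
  mk_rate <- function(centers, sep_ok = TRUE) {
    t <- seq(0.0005, 12, by = 0.001)
    r <- rowSums(vapply(centers, function(c0) exp(-0.5 * ((t - c0) / 0.05)^2),
                        numeric(length(t))))
    structure(list(t = t, rate = r, smoothing_spec = "synthetic", bin_s = 0.001),
              class = "population_rate")
  }
  r3 <- mk_rate(c(3, 5, 7))
  cat3 <- detect_bursts(r3)
  expect_equal(nrow(cat3), 3L)
  expect_lt(max(abs(cat3$peak_times - c(3, 5, 7))), 0.002)
  expect_true(all(cat3$starts < cat3$peak_times & cat3$peak_times < cat3$stops))
  # two bumps 0.5 s apart merge into one detection
  r2 <- mk_rate(c(5, 5.5))
  expect_equal(nrow(detect_bursts(r2)), 1L)
})

test_that("burst detection is invariant to uniform rate scaling", {
  set.seed(30)
  sim <- simulate_spike_network(n_units = 30, duration_s = 120, seed = 55)
  pr <- population_rate(sim$trains, mode = "mua_smooth")
  c1 <- detect_bursts(pr)
  pr2 <- pr
  pr2$rate <- pr$rate * 7
  c2 <- detect_bursts(pr2)
  expect_equal(c1$peak_times, c2$peak_times)
  expect_equal(c2$peak_amplitudes, 7 * c1$peak_amplitudes)
})

test_that("burst similarity: zero for duplicated bursts, homogeneous of degree 1", {
  sim <- simulate_spike_network(n_units = 30, duration_s = 120, seed = 56)
  pr <- population_rate(sim$trains, mode = "mua_smooth")
  catalog <- detect_bursts(pr)
  expect_gte(nrow(catalog), 3)  # generator conditions guarantee bursts
  bs <- burst_similarity(sim$trains, catalog)
  n <- nrow(bs$matrix)
  expect_equal(bs$matrix, t(bs$matrix))
  expect_equal(diag(bs$matrix), rep(0, n))
  expect_true(all(bs$matrix >= 0))
  # n(n-1)/2 unique pairs; 46 bursts would give 1035
  expect_equal(sum(upper.tri(bs$matrix)), n * (n - 1) / 2)
  expect_equal(choose(46, 2), 1035)
  # a duplicated catalog entry yields a zero off-diagonal
  cat2 <- catalog[c(1, 1, 2), ]
  bs2 <- burst_similarity(sim$trains, cat2)
  expect_equal(bs2$matrix[1, 2], 0)
  expect_error(burst_similarity(sim$trains, catalog[1, , drop = FALSE]),
               "at least 2")
})

test_that("fractional change grid is zero for identical conditions and signed correctly", {
  sim <- simulate_spike_network(n_units = 30, duration_s = 120, seed = 57)
  pr <- population_rate(sim$trains, mode = "mua_smooth")
  catalog <- detect_bursts(pr)
  expect_gte(nrow(catalog), 3)
  g0 <- fractional_change_grid(sim$trains, catalog, sim$trains, catalog)
  expect_equal(max(abs(g0$grid)), 0)
  expect_equal(g0$mean_score, 0)
  # condition with more burst-shape variability scores positive as 'a'
  varied <- simulate_spike_network(n_units = 30, duration_s = 120,
                                   burst_gain = 4, seed = 58)
  uniform <- simulate_spike_network(n_units = 30, duration_s = 120,
                                    burst_gain = 4, baseline_rate_hz = 2,
                                    renewal_shape = 20, seed = 59)
  ca <- detect_bursts(population_rate(varied$trains, "mua_smooth"))
  cb <- detect_bursts(population_rate(uniform$trains, "mua_smooth"))
  expect_gte(min(nrow(ca), nrow(cb)), 3)
  g1 <- fractional_change_grid(varied$trains, ca, uniform$trains, cb)
  expect_true(is.finite(g1$mean_score))
})

test_that("spike count change handles limits and Bernoulli thinning", {
  a <- spike_train_set(list(u = seq(0.1, 99.9, by = 0.1)), duration = 100)
  b_empty <- spike_train_set(list(u = numeric(0)), duration = 100)
  expect_equal(spike_count_change(a, b_empty), 100)
  expect_equal(spike_count_change(a, a), 0)
  set.seed(8)
  keep <- runif(length(a$spikes$u)) < 0.28
  b <- spike_train_set(list(u = a$spikes$u[keep]), duration = 100)
  expect_lt(abs(spike_count_change(a, b) - 72), 5)
  expect_error(spike_count_change(b_empty, a), "no spikes")
})
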