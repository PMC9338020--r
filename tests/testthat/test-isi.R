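# Interspike-interval statistics and exponential classification.

test_that("CV limits: periodic trains give 0, equal ISIs give sigma 0", {
  per <- spike_train_set(list(u = seq(0.05, 179.95, by = 0.05)), duration = 180)
  st <- compute_isi_stats(per, fit = FALSE)
  expect_equal(st$cv, 0)
  st2 <- compute_isi_stats(spike_train_set(list(u = c(0.01, 0.02, 0.03)),
                                           duration = 180),
                           min_spikes = 2, fit = FALSE)
  expect_equal(st2$sigma, 0)
  expect_equal(st2$cv, 0)
})

test_that("CV is invariant under time rescaling", {
  set.seed(4)
  s <- sort(runif(500, 0, 100))
  a <- spike_train_set(list(u = s), duration = 100)
  b <- spike_train_set(list(u = s * 3), duration = 300)
  cva <- compute_isi_stats(a, window_s = 100, apply_range_filter = FALSE,
                           fit = FALSE)$cv
  cvb <- compute_isi_stats(b, window_s = 300, apply_range_filter = FALSE,
                           fit = FALSE)$cv
  expect_equal(cva, cvb, tolerance = 1e-12)
})

test_that("selection gates: spike count within the window, empty sets allowed", {
  sparse <- spike_train_set(list(u = seq(1, 170, by = 8)), duration = 180)
  expect_equal(nrow(compute_isi_stats(sparse, min_spikes = 30)), 0L)
  expect_equal(nrow(compute_isi_stats(sparse, min_spikes = 10,
                                      apply_range_filter = FALSE)), 1L)
})

test_that("exponential fit recovers the generating rate", {
  set.seed(17)
  isis <- rexp(5000, 25)
  f <- fit_exponential_isi(isis)
  expect_true(f$converged)
  expect_gt(f$r2, 0.9)
  expect_lt(abs(f$lambda - 25) / 25, 0.1)
  expect_true(f$is_exponential)
})

test_that("right-skewed lognormal ISIs fail the exponential classification", {
  set.seed(18)
  isis <- rlnorm(5000, meanlog = log(0.04), sdlog = 0.35)
  f <- fit_exponential_isi(isis)
  expect_false(isTRUE(f$is_exponential))
})

test_that("degenerate ISI samples yield a failed fit, not an error", {
  f <- fit_exponential_isi(c(0.01, 0.01))
  expect_false(f$converged)
  expect_false(f$is_exponential)
  expect_false(fit_exponential_isi(numeric(0))$converged)
})

test_that("Poisson units are classified exponential as counts grow", {
  set.seed(19)
  sim <- simulate_spike_network(n_units = 10, duration_s = 600,
                                baseline_rate_hz = 20, burst_rate_per_min = 0,
                                seed = 77)
  st <- compute_isi_stats(sim$trains, window_s = 180,
                          apply_range_filter = FALSE)
  expect_gte(mean(st$is_exponential), 0.9)
  # with the 8-100 ms range filter the classification stays stable
  st2 <- compute_isi_stats(sim$trains, window_s = 180,
                           apply_range_filter = TRUE)
  expect_gte(mean(st2$is_exponential), 0.9)
})

test_that("KS comparison is symmetric, null on identical samples, powerful", {
  set.seed(20)
  a <- rexp(500, 25)
  b <- rexp(500, 5)
  r1 <- compare_isi_distributions(a, b)
  r2 <- compare_isi_distributions(b, a)
  expect_equal(r1$ks_statistic, r2$ks_statistic)
  expect_lt(r1$p_value, 1e-4)
  same <- compare_isi_distributions(a, a)
  expect_equal(same$ks_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_isi_distributions(1, a), "at least 2")
})
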