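# Ground-truth properties of the synthetic generators.

test_that("simulation is bit-reproducible under a fixed seed", {
  s1 <- simulate_spike_network(n_units = 8, duration_s = 30, seed = 5)
  s2 <- simulate_spike_network(n_units = 8, duration_s = 30, seed = 5)
  expect_identical(s1$trains$spikes, s2$trains$spikes)
  expect_identical(s1$ground_truth$burst_times, s2$ground_truth$burst_times)
  s3 <- simulate_spike_network(n_units = 8, duration_s = 30, seed = 6)
  expect_false(identical(s1$trains$spikes, s3$trains$spikes))
  l1 <- simulate_lfp(n_electrodes = 4, duration_s = 5, seed = 2)
  l2 <- simulate_lfp(n_electrodes = 4, duration_s = 5, seed = 2)
  expect_identical(l1$data, l2$data)
})

test_that("renewal shape controls ISI regularity (Poisson CV 1, periodic CV 0)", {
  sim <- simulate_spike_network(n_units = 3, duration_s = 300,
                                baseline_rate_hz = 5, renewal_shape = 1,
                                burst_rate_per_min = 0, seed = 8)
  isi <- compute_isi_stats(sim$trains, window_s = 300,
                           apply_range_filter = FALSE, fit = FALSE)
  expect_lt(max(abs(isi$cv - 1)), 0.08)
  sim_p <- simulate_spike_network(n_units = 3, duration_s = 300,
                                 baseline_rate_hz = 5, renewal_shape = 500,
                                 burst_rate_per_min = 0, seed = 8)
  isip <- compute_isi_stats(sim_p$trains, window_s = 300,
                            apply_range_filter = FALSE, fit = FALSE)
  expect_lt(max(isip$cv), 0.1)
})

test_that("deterministic transmission injects followers at the exact latency", {
  edges <- data.frame(source = "1", target = "2",
                      transmission_probability = 1,
                      latency_mean_ms = 5, latency_sd_ms = 0)
  sim <- simulate_spike_network(n_units = 2, duration_s = 60,
                                baseline_rate_hz = 1, burst_rate_per_min = 0,
                                edges = edges, seed = 3)
  src <- sim$trains$spikes[["1"]]
  tgt <- sim$trains$spikes[["2"]]
  has_follower <- vapply(src, function(t) any(abs(tgt - (t + 0.005)) < 1e-9),
                         logical(1))
  # a follower can only be missing when the refractory deletion removed it
  expect_gte(mean(has_follower), 0.95)
  expect_error(simulate_spike_network(n_units = 2, duration_s = 10,
                                      edges = data.frame(source = "1", target = "9",
                                                         transmission_probability = 1,
                                                         latency_mean_ms = 5,
                                                         latency_sd_ms = 0),
                                      seed = 1), "unknown unit")
})

test_that("burst envelope adds the configured expected spike count", {
  gain <- 4; width <- 200; rate <- 3
  sim <- simulate_spike_network(n_units = 40, duration_s = 200,
                                baseline_rate_hz = rate, burst_rate_per_min = 6,
                                burst_width_ms = width, burst_gain = gain,
                                seed = 12)
  nb <- length(sim$ground_truth$burst_times)
  sigma <- width / 1000 / (2 * sqrt(2 * log(2)))
  expected <- rate * (200 + gain * nb * sigma * sqrt(2 * pi))
  got <- mean(lengths(sim$trains$spikes))
  # refractory deletion removes a small fraction; allow 5% + sampling noise
  expect_lt(abs(got - expected) / expected, 0.07)
})

test_that("refractory period is enforced by deletion", {
  sim <- simulate_spike_network(n_units = 5, duration_s = 100,
                                baseline_rate_hz = 30, seed = 9)
  min_isi <- min(vapply(sim$trains$spikes, function(s) min(diff(s)), numeric(1)))
  expect_gte(min_isi, 0.002 - 1e-12)
})

test_that("LFP generator produces the stated structure", {
  # modulation 0, noise 0: pure sinusoid with constant envelope
  tp <- default_theta_params(2, amplitude_uv = 15, mod_depth_uv = 0,
                             active_fraction = 1)
  l <- simulate_lfp(n_electrodes = 2, duration_s = 10, theta_params = tp,
                    pink_noise_rms_uv = 0, seed = 4)
  env <- Mod(orgMEA:::analytic_signal(l$data[1, ]))
  expect_lt(max(abs(env[500:9500] - 15)), 0.2)
  # noise-only channel stays under a 10 uV theta floor
  tp2 <- default_theta_params(2, active_fraction = 0.5)
  l2 <- simulate_lfp(n_electrodes = 2, duration_s = 20, theta_params = tp2,
                     pink_noise_rms_uv = 2, seed = 4)
  th <- band_filter(l2, "theta")
  expect_lt(mean(th$envelope[2, ] >= 10), 0.01)
  expect_gt(mean(th$envelope[1, ] >= 10), 0.95)
  # pink noise rms is calibrated
  pn <- orgMEA:::pink_noise(20000, 3.5)
  expect_equal(rms(pn), 3.5, tolerance = 1e-9)
})

test_that("von Mises thinning imposes recoverable phase coupling", {
  tp <- default_theta_params(2, active_fraction = 1)
  lfp <- simulate_lfp(n_electrodes = 2, duration_s = 120, theta_params = tp,
                      pink_noise_rms_uv = 0.5, seed = 21)
  th <- band_filter(lfp, "theta")
  sim <- simulate_spike_network(n_units = 3, duration_s = 120,
                                baseline_rate_hz = 15, burst_rate_per_min = 0,
                                seed = 22)
  coup <- data.frame(unit_id = c("1", "2"), mu_rad = c(0, 0), kappa = c(4, 0))
  out <- attach_phase_locked_spikes(sim$trains, th, coup, seed = 23)
  # kappa = 0: acceptance is uniform at 1, spikes unchanged
  expect_identical(out$spikes[["2"]], sim$trains$spikes[["2"]])
  # uncoupled unit untouched
  expect_identical(out$spikes[["3"]], sim$trains$spikes[["3"]])
  # kappa = 4: circular mean of spike phases within 10 degrees of target
  pl <- phase_locking(out, th, n_min = 30)
  row <- pl$table[pl$table$unit_id == "1", ]
  expect_gte(row$n, 200)
  expect_lt(abs(row$mu_deg), 10)
  expect_true(row$locked)
  expect_error(attach_phase_locked_spikes(sim$trains, th,
                                          data.frame(unit_id = "1", mu_rad = 0,
                                                     kappa = -1), seed = 1),
               "kappa")
})
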