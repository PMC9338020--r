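# Readers, writers and unit curation.

test_that("CSV spike tables round-trip and are sorted on load", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("unit_id,time_s", "1,0.10", "1,0.25", "2,0.30"), tmp)
  sts <- load_spike_trains(tmp, format = "csv")
  expect_equal(n_units(sts), 2L)
  expect_equal(sts$spikes[["1"]], c(0.10, 0.25))
  # unordered rows are accepted and stored sorted
  writeLines(c("unit_id,time_s", "1,0.25", "1,0.10"), tmp)
  sts2 <- load_spike_trains(tmp, format = "csv")
  expect_equal(sts2$spikes[["1"]], c(0.10, 0.25))
  # write/read round trip exact to 1 us
  set.seed(1)
  sts3 <- spike_train_set(list(u1 = sort(runif(50, 0, 10)),
                               u2 = sort(runif(30, 0, 10))),
                          positions = cbind(x = c(10, 20), y = c(5, 15)),
                          duration = 10)
  out <- tempfile(fileext = ".csv")
  write_spike_trains(sts3, out)
  back <- load_spike_trains(out, format = "csv", duration = 10)
  expect_equal(back$spikes$u1, sts3$spikes$u1, tolerance = 1e-6)
  expect_equal(unname(back$positions), unname(sts3$positions))
  expect_error(load_spike_trains(tempfile(), format = "csv"), "not found")
})

test_that("kilosort-style sample indices convert to seconds", {
  d <- tempfile()
  dir.create(d)
  writeLines(c("20000", "40000", "30000"), file.path(d, "spike_times.txt"))
  writeLines(c("3", "3", "7"), file.path(d, "spike_clusters.txt"))
  writeLines("sample_rate=20000", file.path(d, "params.txt"))
  sts <- load_spike_trains(d, format = "kilosort_dir")
  expect_equal(sts$spikes[["3"]], c(1.0, 2.0))
  expect_equal(sts$spikes[["7"]], 1.5)
})

test_that("spike train validation catches bad input", {
  expect_error(spike_train_set(list(a = c(0.2, 0.1))), "increasing")
  expect_error(spike_train_set(list(a = c(-1, 2))), "negative")
  expect_error(spike_train_set(list(a = c(1, 2)), duration = 1.5), "exceed")
  expect_error(spike_train_set(list(a = 1), positions = cbind(x = c(1, 2), y = c(1, 2))),
               "one row per unit")
})

test_that("LFP binary round trip preserves voltages and metadata", {
  set.seed(2)
  x <- lfp_set(matrix(rnorm(4 * 200, sd = 30), 4),
               fs = 1000, positions = cbind(x = 1:4 * 10, y = rep(0, 4)),
               band = "raw")
  p <- tempfile()
  write_lfp(x, p, dtype = "float32")
  y <- load_lfp(p)
  expect_equal(y$data, x$data, tolerance = 1e-6)   # float32 precision
  expect_equal(y$fs, 1000)
  expect_equal(unname(y$positions), unname(x$positions))
  # int16 with gain: stored value 100 reads back as 19.5 uV
  z <- lfp_set(matrix(c(19.5, 0, -19.5, 39), 1), fs = 1000)
  p2 <- tempfile()
  write_lfp(z, p2, dtype = "int16", gain_uv = 0.195)
  z2 <- load_lfp(p2)
  expect_equal(z2$data[1, 1], 19.5, tolerance = 1e-9)
  expect_error(lfp_set(matrix(0, 4, 10), fs = 1000,
                       positions = cbind(x = 1:3, y = 1:3)), "positions")
})

test_that("unit curation applies strict gates and is idempotent", {
  sts <- spike_train_set(list(a = seq(0.1, 9.9, by = 0.1),
                              b = seq(0.1, 9.9, by = 0.1),
                              c = seq(0.05, 9.95, by = 0.05)), duration = 10)
  q <- unit_quality(sts, snr = c(10, 4.9, 10))
  cur <- curate_units(sts, q)
  expect_setequal(cur$unit_ids, c("a", "c"))  # snr 4.9 < 5 removed
  expect_true("b" %in% attr(cur, "curation_log")$unit_id)
  # exactly at the thresholds: retained (gates are strictly above/below)
  q2 <- data.frame(unit_id = c("a", "b", "c"),
                   isi_violation_fraction = 0.3, firing_rate = 0.05, snr = 5)
  expect_setequal(curate_units(sts, q2)$unit_ids, c("a", "b", "c"))
  # idempotent
  cur2 <- curate_units(cur, q[q$unit_id %in% cur$unit_ids, ])
  expect_identical(cur2$spikes, cur$spikes)
  expect_error(curate_units(sts, data.frame()), "empty quality")
  expect_error(curate_units(sts, q[1:2, ]), "no quality record")
})
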