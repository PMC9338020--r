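# LFP extraction, band filtering, theta maps, averages and PSD.

make_tone <- function(freq, duration = 10, fs = 20000, amp = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amp * cos(2 * pi * freq * t)
}

test_that("LFP extraction preserves the passband and rejects the stopband", {
  x5 <- make_tone(5, duration = 4, amp = 30)
  raw <- lfp_set(rbind(x5, x5 + 12), fs = 20000)
  lfp <- extract_lfp(raw)
  expect_equal(lfp$fs, 1000)
  expect_equal(ncol(lfp$data), 4000)
  mid <- 1000:3000
  expect_lt(abs(max(lfp$data[1, mid]) - 30) / 30, 0.01)   # amplitude kept
  expect_lt(abs(mean(lfp$data[2, mid]) - 12), 0.2)        # DC preserved
  hi <- lfp_set(matrix(make_tone(5000, duration = 2, amp = 30), 1), fs = 20000)
  out <- extract_lfp(hi)
  expect_lt(rms(out$data[1, 500:1500]) / rms(hi$data[1, ]), 0.01)
  expect_error(extract_lfp(lfp_set(matrix(0, 1, 1000), fs = 1000)), ">= 2 kHz")
})

test_that("band filter is zero phase with the stated amplitude and phase convention", {
  t <- seq(0, 19.999, by = 1e-3)
  x <- lfp_set(matrix(20 * cos(2 * pi * 6 * t), 1), fs = 1000)
  bf <- band_filter(x, "theta")
  mid <- 4000:16000
  expect_lt(max(abs(bf$envelope[1, mid] - 20)) / 20, 0.02)
  # zero group delay: filtered peaks at the input peaks (within 1 sample)
  pk_in <- orgMEA:::find_peaks(x$data[1, mid], min_height = 19)
  pk_out <- orgMEA:::find_peaks(bf$lfp$data[1, mid], min_height = 19)
  expect_lte(max(abs(pk_in - pk_out)), 1)
  # phase 0 at the oscillation maxima
  expect_lt(max(abs(bf$phase[1, mid][pk_out])), 0.05)
  # broadband noise carries little theta power
  set.seed(6)
  wn <- lfp_set(matrix(rnorm(20000, sd = 10), 1), fs = 1000)
  bw <- band_filter(wn, "theta")
  expect_lt(rms(bw$envelope[1, 2000:18000]), 0.25 * rms(wn$data[1, ]))
  expect_error(band_filter(lfp_set(matrix(0, 1, 1000), fs = 100), "gamma"),
               "too low")
})

test_that("theta correlation map recovers identity, quarter-period lag and noise nulls", {
  t <- seq(0, 29.999, by = 1e-3)
  set.seed(9)
  base <- 20 * cos(2 * pi * 6 * t)
  x <- lfp_set(rbind(base, base, 20 * cos(2 * pi * 6 * t + pi / 2)), fs = 1000)
  bf <- band_filter(x, "theta")
  tm <- theta_correlation_map(bf, amplitude_floor_uv = 0)
  expect_equal(tm$pair_corr[1, 2], 1, tolerance = 1e-6)
  expect_equal(tm$pair_lag_ms[1, 2], 0)
  # quarter period of 6 Hz ~ 41.7 ms
  expect_lt(abs(abs(tm$pair_lag_ms[1, 3]) - 1000 / 6 / 4), 2)
  expect_gt(tm$pair_corr[1, 3], 0.99)
  # independent noise: correlations near zero, none reach 0.2
  wn <- lfp_set(matrix(rnorm(3 * 30000, sd = 10), 3), fs = 1000)
  bwn <- band_filter(wn, "theta")
  tm2 <- theta_correlation_map(bwn, amplitude_floor_uv = 0)
  others <- tm2$pair_corr[upper.tri(tm2$pair_corr)]
  expect_lt(max(abs(others)), 0.2)
  expect_error(theta_correlation_map(band_filter(lfp_set(matrix(rnorm(5000), 1),
                                                         fs = 1000), "theta")),
               "2 electrodes")
})

test_that("signal averaging keeps phase-consistent theta and cancels random anchors", {
  t <- seq(0, 59.999, by = 1e-3)
  x <- lfp_set(rbind(20 * cos(2 * pi * 6 * t),
                     20 * cos(2 * pi * 6 * t + pi / 3)), fs = 1000,
               positions = cbind(x = c(0, 35), y = c(0, 0)))
  bf <- band_filter(x, "theta")
  av <- signal_average_theta(bf, anchors = "seed_peaks", seed_electrode = 1)
  expect_gt(av$n_anchors, 100)
  expect_lt(abs(av$amplitude[1] - 20) / 20, 0.05)
  # fixed pi/3 offset recovered
  expect_lt(abs(abs(av$phase_offset[2]) - pi / 3), 0.05)
  # anchors at random phase: destructive interference
  set.seed(10)
  rand_anchors <- sort(runif(200, 1, 59))
  av2 <- signal_average_theta(bf, anchors = rand_anchors)
  expect_lt(av2$amplitude[1], 5)
  expect_error(signal_average_theta(bf, anchors = c(1, 2)), "at least 5")
})

test_that("phase spread is zero for identical burst phases and large for random ones", {
  t <- seq(0, 119.999, by = 1e-3)
  x <- lfp_set(matrix(20 * cos(2 * pi * 5 * t), 1), fs = 1000)
  bf <- band_filter(x, "theta")
  mk_cat <- function(peaks) {
    out <- data.frame(peak_times = peaks, starts = peaks - 0.2,
                      stops = peaks + 0.2, peak_amplitudes = 1)
    class(out) <- c("burst_catalog", "data.frame")
    out
  }
  # bursts at integer multiples of the 200 ms period: identical phases
  ps <- phase_spread(bf, mk_cat(seq(2, 118, by = 3)))
  expect_lt(max(ps$spread), 0.05)
  expect_equal(ps$qualifying, 1L)
  # random burst times: phases uniform, spread large everywhere
  set.seed(13)
  ps2 <- phase_spread(bf, mk_cat(sort(runif(40, 2, 118))))
  expect_gt(min(ps2$spread), 1)
  expect_error(phase_spread(bf, mk_cat(c(3, 6))), "at least 5")
  # circular std is invariant under global phase rotation
  cat_r <- mk_cat(sort(runif(40, 2, 118)))
  bf2 <- bf
  bf2$phase <- orgMEA:::wrap_angle(bf$phase + 1.1)
  expect_equal(phase_spread(bf2, cat_r)$spread,
               phase_spread(bf, cat_r)$spread, tolerance = 1e-9)
})

test_that("envelope threshold fractions split correctly at burst boundaries", {
  ns <- 60000
  env <- matrix(3, 2, ns)
  t <- (seq_len(ns) - 1) / 1000
  bursts <- data.frame(peak_times = c(10, 30, 50), starts = c(9, 29, 49),
                       stops = c(11, 31, 51), peak_amplitudes = 1)
  class(bursts) <- c("burst_catalog", "data.frame")
  inb <- (t >= 9 & t <= 11) | (t >= 29 & t <= 31) | (t >= 49 & t <= 51)
  env[1, inb] <- 6  # doubled inside bursts
  st <- envelope_threshold_stats(env, fs = 1000, catalog = bursts)
  f1 <- st$fractions[st$fractions$electrode == 1, ]
  expect_true(all(f1$burst >= f1$nonburst))
  expect_equal(st$n_burst_increased[["1.5"]], 1L)
  # constant envelope: never above 1.5x its own rms
  f2 <- st$fractions[st$fractions$electrode == 2 & st$fractions$k == 1.5, ]
  expect_equal(f2$overall, 0)
  # identical condition vs reference: percent change 0
  st2 <- envelope_threshold_stats(env, fs = 1000, catalog = bursts,
                                  reference_env = env)
  expect_true(all(st2$fractions$pct_change[is.finite(st2$fractions$pct_change)] == 0))
})

test_that("Welch PSD satisfies Parseval and resolves spectral shape", {
  t <- seq(0, 19.999, by = 1e-3)
  tone <- lfp_set(matrix(sqrt(2) * cos(2 * pi * 6 * t), 1), fs = 1000)
  ps <- compute_psd(tone, segment_s = 2)
  df <- ps$freq[2] - ps$freq[1]
  expect_equal(sum(ps$psd[1, ]) * df, 1, tolerance = 0.05)  # amp^2/2 = 1
  expect_equal(ps$freq[which.max(ps$psd[1, ])], 6)
  # 1/f noise: log-log slope near -1
  set.seed(14)
  pn <- lfp_set(matrix(orgMEA:::pink_noise(120000, 5), 1), fs = 1000)
  pp <- compute_psd(pn, segment_s = 2)
  sel <- pp$freq >= 1 & pp$freq <= 100
  slope <- stats::coef(stats::lm(log(pp$psd[1, sel]) ~ log(pp$freq[sel])))[2]
  expect_lt(abs(slope + 1), 0.2)
  # white noise: flat (slope near 0)
  wn <- lfp_set(matrix(rnorm(120000), 1), fs = 1000)
  pw <- compute_psd(wn, segment_s = 2)
  slope_w <- stats::coef(stats::lm(log(pw$psd[1, sel]) ~ log(pw$freq[sel])))[2]
  expect_lt(abs(slope_w), 0.1)
  expect_error(compute_psd(tone, segment_s = 15), "two segments")
})
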