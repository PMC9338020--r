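# Synthetic recordings with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# per-unit renewal firing (gamma-shaped ISIs) modulated by shared Gaussian
# population-burst envelopes, embedded directed connections realised as
# probabilistic spike transmission at a jittered ~5 ms latency, and LFP
# channels carrying burst-modulated theta oscillations with spatial phase
# offsets on top of 1/f noise.

.array_dims_um <- c(x = 3850, y = 2100)  # sensing area of the planar array

#' Random embedded connections for a simulated network
#'
#' Draws `n_edges` directed connections over disjoint unit pairs (so each
#' unit is endpoint of at most one edge and ground-truth directionality is
#' unambiguous).
#'
#' @param n_units number of units in the network.
#' @param n_edges number of connections; requires `2 * n_edges <= n_units`.
#' @param transmission_p per-spike transmission probability.
#' @param latency_mean_ms,latency_sd_ms transmission latency distribution.
#' @return data.frame with columns `source`, `target`,
#'   `transmission_probability`, `latency_mean_ms`, `latency_sd_ms`.
#' @export
sample_edges <- function(n_units, n_edges, transmission_p = 0.6,
                         latency_mean_ms = 5, latency_sd_ms = 2) {
  if (2 * n_edges > n_units)
    stopf("need at least 2 units per edge (%d edges, %d units)", n_edges, n_units)
  ids <- sample(n_units, 2L * n_edges)
  data.frame(source = as.character(ids[seq_len(n_edges)]),
             target = as.character(ids[n_edges + seq_len(n_edges)]),
             transmission_probability = transmission_p,
             latency_mean_ms = latency_mean_ms,
             latency_sd_ms = latency_sd_ms,
             stringsAsFactors = FALSE)
}

# Gaussian burst envelope (peak 1 per burst) evaluated on a time grid.
burst_envelope <- function(t, burst_times, burst_width_ms) {
  sigma <- burst_width_ms / 1000 / (2 * sqrt(2 * log(2)))  # width is FWHM
  env <- numeric(length(t))
  for (tb in burst_times) {
    lo <- max(1L, findInterval(tb - 5 * sigma, t))
    hi <- min(length(t), findInterval(tb + 5 * sigma, t) + 1L)
    idx <- lo:hi
    env[idx] <- env[idx] + exp(-0.5 * ((t[idx] - tb) / sigma)^2)
  }
  env
}

# Burst peak times: renewal draws with a hard 1 s minimum separation,
# matching the burst-detection contract downstream.
draw_burst_times <- function(duration_s, rate_per_min, min_sep_s = 1) {
  if (rate_per_min <= 0) return(numeric(0))
  mean_gap <- 60 / rate_per_min
  if (mean_gap <= min_sep_s)
    stopf("burst rate %.1f/min incompatible with %.1f s minimum separation",
          rate_per_min, min_sep_s)
  times <- numeric(0)
  t <- stats::rexp(1, 1 / mean_gap)
  while (t < duration_s) {
    times <- c(times, t)
    t <- t + min_sep_s + stats::rexp(1, 1 / (mean_gap - min_sep_s))
  }
  times
}

# Truncated-normal latency draws (> lower), by rejection with a floor.
rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower)
  guard <- 0L
  while (length(bad) && guard < 100L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
    guard <- guard + 1L
  }
  out[out <= lower] <- lower + abs(out[out <= lower] - lower)  # reflect stragglers
  out
}

#' Simulate a spiking network with embedded directed connections
#'
#' Each unit fires as a renewal process with gamma-shaped inter-spike
#' intervals (`renewal_shape = 1` gives a Poisson train; large shapes give
#' near-periodic trains), rate-modulated by a shared burst envelope of
#' Gaussian bumps (peak gain `burst_gain` relative to baseline, bump FWHM
#' `burst_width_ms`, bursts at least 1 s apart). For every spike of an edge's
#' source unit, a follower spike is injected into the target with the edge's
#' transmission probability at a latency drawn from a normal distribution
#' truncated above 0.5 ms. A 2 ms absolute refractory period is enforced per
#' unit by deleting the later spike of any closer pair. Injected followers do
#' not themselves transmit unless `chain = TRUE`.
#'
#' @param n_units number of units.
#' @param duration_s recording length, seconds.
#' @param baseline_rate_hz per-unit baseline firing rate.
#' @param renewal_shape gamma shape of the unit-rate renewal ISIs.
#' @param burst_rate_per_min population burst rate; 0 disables bursts.
#' @param burst_width_ms burst envelope FWHM.
#' @param burst_gain peak rate multiplier added during a burst (rate at the
#'   burst peak is `baseline * (1 + burst_gain)` per overlapping bump).
#' @param edges data.frame as from [sample_edges], or `NULL` for none.
#' @param chain allow injected follower spikes to transmit onward.
#' @param refractory_ms absolute refractory period enforced per unit by
#'   deleting the later spike of any closer pair; 0 disables it (giving an
#'   exact renewal process, e.g. homogeneous Poisson at shape 1).
#' @param seed mandatory RNG seed; the simulation is bit-reproducible for a
#'   fixed seed and leaves the caller's RNG state untouched.
#' @return list with `trains` (a [spike_train_set]) and `ground_truth`
#'   (edges, unit kinds, burst times).
#' @export
simulate_spike_network <- function(n_units = 50, duration_s = 300,
                                   baseline_rate_hz = 2, renewal_shape = 1,
                                   burst_rate_per_min = 6, burst_width_ms = 200,
                                   burst_gain = 4, edges = NULL,
                                   chain = FALSE, refractory_ms = 2, seed) {
  if (missing(seed)) stopf("'seed' is mandatory")
  stopifnot(n_units >= 1, duration_s > 0, baseline_rate_hz > 0, renewal_shape > 0,
            burst_rate_per_min >= 0, burst_width_ms > 0, burst_gain >= 0)
  ids <- as.character(seq_len(n_units))
  if (!is.null(edges)) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    unknown <- setdiff(c(edges$source, edges$target), ids)
    if (length(unknown))
      stopf("edges reference unknown unit(s): %s", paste(unknown, collapse = ", "))
    if (any(edges$transmission_probability < 0 | edges$transmission_probability > 1))
      stopf("transmission probabilities must lie in [0, 1]")
    if (any(edges$latency_mean_ms <= 0)) stopf("latency_mean_ms must be > 0")
  }
  with_seed(seed, {
    burst_times <- draw_burst_times(duration_s, burst_rate_per_min)
    # rate on a 1 ms grid; renewal sampling by time rescaling
    tg <- seq(0, duration_s, by = 0.001)
    env <- burst_envelope(tg, burst_times, burst_width_ms)
    lambda <- baseline_rate_hz * (1 + burst_gain * env)
    Lambda <- c(0, cumsum((lambda[-1] + lambda[-length(lambda)]) / 2 * diff(tg)))
    total <- Lambda[length(Lambda)]
    spikes <- vector("list", n_units)
    names(spikes) <- ids
    for (u in ids) {
      n_guess <- max(20L, ceiling(total + 6 * sqrt(total / renewal_shape)))
      isis <- stats::rgamma(n_guess, shape = renewal_shape, rate = renewal_shape)
      op_times <- cumsum(isis)
      while (op_times[length(op_times)] < total) {
        isis2 <- stats::rgamma(n_guess, shape = renewal_shape, rate = renewal_shape)
        op_times <- c(op_times, op_times[length(op_times)] + cumsum(isis2))
      }
      op_times <- op_times[op_times <= total]
      spikes[[u]] <- stats::approx(Lambda, tg, xout = op_times, ties = "ordered")$y
    }
    # probabilistic transmission along embedded edges
    if (!is.null(edges) && nrow(edges)) {
      injected <- stats::setNames(vector("list", n_units), ids)
      frontier <- spikes  # source spikes eligible to transmit
      repeat {
        new_frontier <- stats::setNames(vector("list", n_units), ids)
        any_new <- FALSE
        for (k in seq_len(nrow(edges))) {
          src <- edges$source[k]; tgt <- edges$target[k]
          s <- frontier[[src]]
          if (!length(s)) next
          go <- stats::runif(length(s)) < edges$transmission_probability[k]
          if (!any(go)) next
          lat <- rtrunc_norm(sum(go), edges$latency_mean_ms[k],
                             edges$latency_sd_ms[k], lower = 0.5) / 1000
          f <- s[go] + lat
          f <- f[f <= duration_s]
          if (length(f)) {
            injected[[tgt]] <- c(injected[[tgt]], f)
            new_frontier[[tgt]] <- c(new_frontier[[tgt]], f)
            any_new <- TRUE
          }
        }
        if (!chain || !any_new) break
        frontier <- new_frontier
      }
      for (u in ids) {
        if (length(injected[[u]]))
          spikes[[u]] <- sort(c(spikes[[u]], injected[[u]]))
      }
    }
    # absolute refractory period: delete the later spike of any closer pair
    if (refractory_ms > 0)
      spikes <- lapply(spikes, enforce_refractory,
                       refractory_s = refractory_ms / 1000)
    positions <- cbind(x = stats::runif(n_units, 0, .array_dims_um["x"]),
                       y = stats::runif(n_units, 0, .array_dims_um["y"]))
    kinds <- rep("background", n_units)
    names(kinds) <- ids
    if (!is.null(edges) && nrow(edges)) {
      kinds[unique(edges$source)] <- "driver"
      kinds[setdiff(unique(edges$target), unique(edges$source))] <- "follower"
    }
    trains <- spike_train_set(spikes, positions = positions,
                              duration = duration_s,
                              meta = list(generator = "simulate_spike_network",
                                          seed = seed))
    list(trains = trains,
         ground_truth = list(edges = edges, unit_kinds = kinds,
                             burst_times = burst_times,
                             burst_width_ms = burst_width_ms,
                             burst_gain = burst_gain,
                             baseline_rate_hz = baseline_rate_hz))
  })
}

enforce_refractory <- function(s, refractory_s = 0.002) {
  if (length(s) < 2L) return(s)
  keep <- logical(length(s))
  keep[1] <- TRUE
  last <- s[1]
  for (i in 2:length(s)) {
    if (s[i] - last >= refractory_s) {
      keep[i] <- TRUE
      last <- s[i]
    }
  }
  s[keep]
}

# 1/f-amplitude ("pink") noise via spectral shaping of white noise.
pink_noise <- function(n, rms_uv) {
  if (rms_uv <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)        # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  x <- x - mean(x)
  x * rms_uv / rms(x)
}

#' Default per-electrode theta parameters for the LFP generator
#'
#' The first `ceiling(active_fraction * n)` electrodes form the active region
#' and carry theta; the rest are noise-only (amplitude and modulation 0).
#' Phase offsets advance linearly across the active region.
#'
#' @param n_electrodes electrode count.
#' @param amplitude_uv baseline theta amplitude of active electrodes.
#' @param freq_hz theta frequency.
#' @param mod_depth_uv amplitude added at a burst-envelope peak.
#' @param phase_span_rad total phase advance across the active region.
#' @param active_fraction fraction of electrodes in the active region.
#' @return data.frame with one row per electrode.
#' @export
default_theta_params <- function(n_electrodes, amplitude_uv = 20, freq_hz = 6,
                                 mod_depth_uv = 20, phase_span_rad = pi / 2,
                                 active_fraction = 0.5) {
  n_active <- ceiling(active_fraction * n_electrodes)
  amp <- c(rep(amplitude_uv, n_active), rep(0, n_electrodes - n_active))
  mod <- c(rep(mod_depth_uv, n_active), rep(0, n_electrodes - n_active))
  phase <- numeric(n_electrodes)
  if (n_active > 1)
    phase[seq_len(n_active)] <- seq(0, phase_span_rad, length.out = n_active)
  data.frame(electrode = seq_len(n_electrodes), amplitude_uv = amp,
             freq_hz = freq_hz, phase_rad = phase, mod_depth_uv = mod)
}

#' Simulate LFP channels with burst-modulated theta and 1/f noise
#'
#' Each channel is `(A + D * env(t)) * cos(2 pi f t + phi)` plus pink noise
#' of the stated rms, where `env` is the Gaussian burst envelope (peak 1) at
#' `burst_times`. Electrodes with amplitude 0 carry noise only.
#'
#' @param n_electrodes electrode count.
#' @param duration_s recording length.
#' @param fs sampling rate, Hz (>= 250).
#' @param theta_params data.frame as from [default_theta_params]; `NULL` uses
#'   the defaults.
#' @param burst_times burst peak times, seconds.
#' @param burst_width_ms burst envelope FWHM.
#' @param pink_noise_rms_uv rms of the additive 1/f noise.
#' @param positions electrode positions; defaults to a grid spanning the
#'   3.85 mm x 2.1 mm array.
#' @param seed mandatory RNG seed.
#' @return an [lfp_set] (band `"raw"`) with the generator parameters in
#'   `$meta`-like attribute `"ground_truth"`.
#' @export
simulate_lfp <- function(n_electrodes = 16, duration_s = 60, fs = 1000,
                         theta_params = NULL, burst_times = numeric(0),
                         burst_width_ms = 200, pink_noise_rms_uv = 2,
                         positions = NULL, seed) {
  if (missing(seed)) stopf("'seed' is mandatory")
  if (fs < 250) stopf("'fs' must be >= 250 Hz")
  if (is.null(theta_params)) theta_params <- default_theta_params(n_electrodes)
  if (nrow(theta_params) != n_electrodes)
    stopf("theta_params must have one row per electrode")
  with_seed(seed, {
    t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
    env <- burst_envelope(t, burst_times, burst_width_ms)
    data <- matrix(0, nrow = n_electrodes, ncol = length(t))
    for (e in seq_len(n_electrodes)) {
      p <- theta_params[e, ]
      amp <- p$amplitude_uv + p$mod_depth_uv * env
      data[e, ] <- amp * cos(2 * pi * p$freq_hz * t + p$phase_rad) +
        pink_noise(length(t), pink_noise_rms_uv)
    }
    if (is.null(positions)) {
      nx <- ceiling(sqrt(n_electrodes))
      ny <- ceiling(n_electrodes / nx)
      grid <- expand.grid(x = seq(0, .array_dims_um["x"], length.out = nx),
                          y = seq(0, .array_dims_um["y"], length.out = ny))
      positions <- as.matrix(grid[seq_len(n_electrodes), ])
    }
    out <- lfp_set(data, fs = fs, positions = positions, band = "raw")
    attr(out, "ground_truth") <- list(theta_params = theta_params,
                                      burst_times = burst_times,
                                      burst_width_ms = burst_width_ms,
                                      pink_noise_rms_uv = pink_noise_rms_uv,
                                      seed = seed)
    out
  })
}

#' Impose von Mises spike-phase coupling by thinning
#'
#' For each coupled unit, spikes are kept with probability
#' `exp(kappa * (cos(phase - mu) - 1))`, the von Mises acceptance profile on
#' the local theta phase (phase read from the nearest electrode's phase trace
#' at the nearest sample). `kappa = 0` accepts every spike; uncoupled units
#' are untouched.
#'
#' @param trains a [spike_train_set].
#' @param theta a theta-band [band_lfp] (from [band_filter]) or an `lfp_set`
#'   with `band == "theta"`.
#' @param coupling data.frame with columns `unit_id`, `mu_rad`, `kappa`.
#' @param seed mandatory RNG seed.
#' @return thinned `spike_train_set`.
#' @export
attach_phase_locked_spikes <- function(trains, theta, coupling, seed) {
  if (missing(seed)) stopf("'seed' is mandatory")
  ph <- phase_matrix(theta)
  if (ph$band != "theta") stopf("'theta' must be theta-band data (got '%s')", ph$band)
  coupling <- as.data.frame(coupling, stringsAsFactors = FALSE)
  if (any(coupling$kappa < 0)) stopf("kappa must be >= 0")
  coupling$unit_id <- as.character(coupling$unit_id)
  pair <- nearest_electrode(trains, ph$positions)
  with_seed(seed, {
    spikes <- trains$spikes
    for (i in seq_len(nrow(coupling))) {
      u <- coupling$unit_id[i]
      if (!u %in% trains$unit_ids)
        stopf("coupling references unknown unit %s", u)
      s <- spikes[[u]]
      if (!length(s)) next
      e <- pair[u]
      idx <- pmin(pmax(round((s - ph$t0) * ph$fs) + 1L, 1L), ncol(ph$phase))
      th <- ph$phase[e, idx]
      acc <- exp(coupling$kappa[i] * (cos(th - coupling$mu_rad[i]) - 1))
      spikes[[u]] <- s[stats::runif(length(s)) < acc]
    }
    spikes <- spikes[lengths(spikes) >= 0]
    spike_train_set(spikes, positions = trains$positions,
                    duration = trains$duration,
                    meta = c(trains$meta, list(phase_coupling = coupling)))
  })
}

# Resolve a phase source: band_lfp objects carry phase; a theta lfp_set gets
# the analytic-signal phase computed on the fly.
phase_matrix <- function(theta) {
  if (inherits(theta, "band_lfp")) {
    list(phase = theta$phase, fs = theta$lfp$fs, t0 = theta$lfp$t0,
         positions = theta$lfp$positions, band = theta$band)
  } else if (inherits(theta, "lfp_set")) {
    ph <- t(apply(theta$data, 1, function(x) Arg(analytic_signal(x))))
    list(phase = ph, fs = theta$fs, t0 = theta$t0,
         positions = theta$positions, band = theta$band)
  } else stopf("'theta' must be a band_lfp or lfp_set")
}

# Map each unit to its nearest electrode (index); identity-ish fallback when
# geometry is missing.
nearest_electrode <- function(trains, electrode_positions) {
  n_e <- nrow(electrode_positions %||% matrix(numeric(0), 0, 2))
  if (is.null(trains$positions) || is.null(electrode_positions) || n_e == 0L) {
    idx <- ((seq_along(trains$unit_ids) - 1L) %% max(n_e, 1L)) + 1L
    return(stats::setNames(idx, trains$unit_ids))
  }
  up <- trains$positions
  idx <- vapply(seq_len(nrow(up)), function(i) {
    d2 <- (electrode_positions[, 1] - up[i, 1])^2 +
      (electrode_positions[, 2] - up[i, 2])^2
    which.min(d2)
  }, integer(1))
  stats::setNames(idx, trains$unit_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
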