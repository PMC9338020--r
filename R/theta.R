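# Theta correlation/lag maps, burst-anchored averages, phase spread and
# envelope statistics.

# Masked, Pearson-normalized cross-correlation of all electrode pairs via
# FFT. Returns, per pair, the maximum signed correlation over lags within
# +/- max_lag samples and the lag (samples) at that maximum; positive lag
# means the second electrode lags the first.
masked_xcorr_max <- function(data, valid, max_lag, min_overlap = 100L) {
  ne <- nrow(data)
  ns <- ncol(data)
  nfft <- stats::nextn(ns + max_lag + 1L, 2)
  Fm <- vector("list", ne); Fx <- vector("list", ne); Fxx <- vector("list", ne)
  for (e in seq_len(ne)) {
    m <- as.numeric(valid[e, ])
    xm <- data[e, ] * m
    Fm[[e]] <- stats::fft(c(m, numeric(nfft - ns)))
    Fx[[e]] <- stats::fft(c(xm, numeric(nfft - ns)))
    Fxx[[e]] <- stats::fft(c(xm * data[e, ], numeric(nfft - ns)))
  }
  lag_idx <- c(nfft - (max_lag:1) + 1L, 1L:(max_lag + 1L))  # lags -max..+max
  lags <- c(-(max_lag:1), 0:max_lag)
  xcor <- function(Fa, Fb) Re(stats::fft(Conj(Fa) * Fb, inverse = TRUE))[lag_idx] / nfft
  corr <- matrix(NA_real_, ne, ne)
  lag <- matrix(NA_real_, ne, ne)
  diag(corr) <- 1
  diag(lag) <- 0
  for (i in seq_len(ne - 1L)) {
    for (j in (i + 1L):ne) {
      n_l <- xcor(Fm[[i]], Fm[[j]])
      sx <- xcor(Fx[[i]], Fm[[j]])
      sy <- xcor(Fm[[i]], Fx[[j]])
      sxx <- xcor(Fxx[[i]], Fm[[j]])
      syy <- xcor(Fm[[i]], Fxx[[j]])
      sxy <- xcor(Fx[[i]], Fx[[j]])
      ok <- n_l >= min_overlap
      if (!any(ok)) next
      n_l[!ok] <- NA
      vx <- sxx - sx^2 / n_l
      vy <- syy - sy^2 / n_l
      r <- (sxy - sx * sy / n_l) / sqrt(pmax(vx, 0) * pmax(vy, 0))
      r[!is.finite(r)] <- NA
      if (all(is.na(r))) next
      k <- which.max(r)
      corr[i, j] <- corr[j, i] <- r[k]
      lag[i, j] <- lags[k]
      lag[j, i] <- -lags[k]
    }
  }
  list(corr = corr, lag = lag)
}

#' Theta correlation and lag map against a seed electrode
#'
#' Pairwise Pearson-normalized cross-correlation of the band-filtered traces
#' (maximum signed correlation over lags within +/- `max_lag_periods` band
#' periods), after masking samples whose envelope falls below
#' `amplitude_floor_uv` (electrodes with more than 90% masked samples are
#' dropped). The seed electrode maximizes the summed pairwise correlation;
#' the map reports each electrode's correlation with the seed, the lag (ms,
#' positive = lags the seed) and the equivalent phase offset at the band
#' center frequency. Optionally restricted to burst windows.
#'
#' @param theta a [band_lfp] (theta band).
#' @param amplitude_floor_uv envelope noise floor; samples below it are
#'   masked. 0 disables masking.
#' @param corr_threshold count electrodes at or above this correlation.
#' @param burst_windows optional [detect_bursts] catalog restricting the
#'   analysis to burst periods.
#' @param max_lag_periods lag search range in band-center periods.
#' @param min_overlap_s minimum unmasked overlap per pair and lag, seconds.
#' @return object of class `theta_map`: `seed`, `correlation`, `lag_ms`,
#'   `phase_offset`, `n_above_threshold`, `pair_corr` and `pair_lag_ms`
#'   matrices, `excluded` electrodes.
#' @export
theta_correlation_map <- function(theta, amplitude_floor_uv = 10,
                                  corr_threshold = 0.2, burst_windows = NULL,
                                  max_lag_periods = 2, min_overlap_s = 0.1) {
  stopifnot(inherits(theta, "band_lfp"))
  data <- theta$lfp$data
  ne <- nrow(data)
  if (ne < 2L) stopf("need at least 2 electrodes")
  fs <- theta$lfp$fs
  valid <- theta$envelope >= amplitude_floor_uv
  if (!is.null(burst_windows)) {
    t <- lfp_times(theta$lfp)
    inb <- rep(FALSE, length(t))
    for (i in seq_len(nrow(burst_windows)))
      inb <- inb | (t >= burst_windows$starts[i] & t <= burst_windows$stops[i])
    valid <- valid & matrix(inb, ne, length(t), byrow = TRUE)
  }
  frac_masked <- 1 - rowMeans(valid)
  excluded <- which(frac_masked > 0.9)
  keep <- setdiff(seq_len(ne), excluded)
  if (length(keep) < 2L)
    stopf("fewer than 2 electrodes survive the %g uV amplitude floor",
          amplitude_floor_uv)
  f0 <- mean(theta$range_hz)
  max_lag <- ceiling(max_lag_periods / f0 * fs)
  xc <- masked_xcorr_max(data[keep, , drop = FALSE],
                         valid[keep, , drop = FALSE], max_lag,
                         min_overlap = max(4L, round(min_overlap_s * fs)))
  summed <- rowSums(xc$corr, na.rm = TRUE) - 1  # exclude self-correlation
  seed_local <- which.max(summed)
  corr_seed <- xc$corr[seed_local, ]
  lag_seed <- xc$lag[seed_local, ] / fs * 1000
  full <- function(v) { out <- rep(NA_real_, ne); out[keep] <- v; out }
  structure(list(seed = keep[seed_local],
                 correlation = full(corr_seed),
                 lag_ms = full(lag_seed),
                 phase_offset = full(wrap_angle(2 * pi * f0 * lag_seed / 1000)),
                 n_above_threshold = sum(corr_seed >= corr_threshold, na.rm = TRUE),
                 corr_threshold = corr_threshold,
                 pair_corr = xc$corr, pair_lag_ms = xc$lag / fs * 1000,
                 electrodes_used = keep, excluded = excluded,
                 positions = theta$lfp$positions),
            class = "theta_map")
}

#' @export
print.theta_map <- function(x, ...) {
  cat(sprintf("theta_map: seed electrode %d; %d/%d electrodes >= %.2f correlation\n",
              x$seed, x$n_above_threshold, length(x$electrodes_used),
              x$corr_threshold))
  invisible(x)
}

#' Event-triggered theta signal averages
#'
#' Averages each electrode's band-filtered trace in a window centered on
#' anchor events: either the seed electrode's oscillation peaks (minimum
#' height `peak_min_uv`, minimum separation `peak_min_dist_ms`) or
#' population-burst peak times. Phase-consistent oscillations survive the
#' averaging (amplitude approaching the single-trial amplitude); anchors at
#' random phase average toward zero. The envelope of the averaged waveform
#' quantifies that phase consistency, and the phase at the window center
#' (relative to the seed's) gives the spatial phase-offset map. With
#' `spatial_average_um` set, signals are first averaged over electrodes
#' within a square window of that side length (the 5x5-grid neighborhood of
#' the dense array).
#'
#' @param theta a [band_lfp].
#' @param anchors `"seed_peaks"`, `"burst_peaks"`, or a numeric vector of
#'   anchor times (s). At least 5 anchors are required.
#' @param catalog [detect_bursts] catalog (for `"burst_peaks"`).
#' @param seed_electrode electrode index for `"seed_peaks"`; defaults to the
#'   electrode with the largest mean envelope.
#' @param window_ms full width of the averaging window.
#' @param peak_min_uv,peak_min_dist_ms seed-peak detection parameters.
#' @param spatial_average_um optional spatial pre-averaging window side (um).
#' @return object of class `theta_average`: `t_ms` (relative time),
#'   `waveforms` (electrodes x window samples), `amplitude` (uV, max of the
#'   averaged envelope), `phase_offset` (rad, at window center, relative to
#'   the reference electrode), `n_anchors`, `anchor_times`.
#' @export
signal_average_theta <- function(theta, anchors = c("seed_peaks", "burst_peaks"),
                                 catalog = NULL, seed_electrode = NULL,
                                 window_ms = 500, peak_min_uv = 10,
                                 peak_min_dist_ms = 100,
                                 spatial_average_um = NULL) {
  stopifnot(inherits(theta, "band_lfp"))
  fs <- theta$lfp$fs
  data <- theta$lfp$data
  if (!is.null(spatial_average_um)) {
    pos <- theta$lfp$positions
    if (is.null(pos)) stopf("spatial averaging needs electrode positions")
    half <- spatial_average_um / 2
    data <- t(vapply(seq_len(nrow(data)), function(e) {
      nb <- which(abs(pos[, "x"] - pos[e, "x"]) <= half &
                    abs(pos[, "y"] - pos[e, "y"]) <= half)
      colMeans(data[nb, , drop = FALSE])
    }, numeric(ncol(data))))
  }
  if (is.numeric(anchors)) {
    anchor_times <- anchors
    ref <- seed_electrode %||% 1L
  } else {
    anchors <- match.arg(anchors)
    if (anchors == "burst_peaks") {
      if (is.null(catalog)) stopf("burst_peaks anchors need a burst catalog")
      anchor_times <- catalog$peak_times
      ref <- seed_electrode %||% which.max(rowMeans(theta$envelope))
    } else {
      ref <- seed_electrode %||% which.max(rowMeans(theta$envelope))
      pk <- find_peaks(data[ref, ], min_height = peak_min_uv,
                       min_distance = max(1L, round(peak_min_dist_ms / 1000 * fs)))
      anchor_times <- lfp_times(theta$lfp)[pk]
    }
  }
  half_n <- round(window_ms / 2 / 1000 * fs)
  idx0 <- round((anchor_times - theta$lfp$t0) * fs) + 1L
  ok <- idx0 - half_n >= 1L & idx0 + half_n <= ncol(data)
  idx0 <- idx0[ok]
  if (length(idx0) < 5L)
    stopf("need at least 5 usable anchor events (got %d)", length(idx0))
  rel <- -half_n:half_n
  ne <- nrow(data)
  wav <- matrix(0, ne, length(rel))
  for (a in idx0) wav <- wav + data[, a + rel, drop = FALSE]
  wav <- wav / length(idx0)
  amp <- numeric(ne)
  ph <- numeric(ne)
  for (e in seq_len(ne)) {
    an <- analytic_signal(wav[e, ])
    amp[e] <- max(Mod(an))
    ph[e] <- Arg(an)[half_n + 1L]
  }
  structure(list(t_ms = rel / fs * 1000, waveforms = wav, amplitude = amp,
                 phase_offset = wrap_angle(ph - ph[ref]),
                 reference_electrode = ref,
                 n_anchors = length(idx0), anchor_times = anchor_times[ok]),
            class = "theta_average")
}

#' Theta phase spread around population-burst peaks
#'
#' For each electrode and each time offset relative to a burst peak, the
#' circular standard deviation `sqrt(-2 log R)` of the theta phase across
#' bursts. Electrodes whose spread drops below 1 rad within the window
#' qualify; their time of minimum spread and the contiguous sub-rad
#' ("coherent") window around it are reported, plus the histogram of
#' minimum-spread times across qualifying electrodes.
#'
#' @param theta a [band_lfp] with phase.
#' @param catalog a [detect_bursts] catalog with >= 5 bursts.
#' @param window_ms `c(start, stop)` relative to the burst peak.
#' @return object of class `phase_spread`: `t_ms`, `spread` (electrodes x
#'   offsets, radians), `min_spread_time_ms` (NA for non-qualifying
#'   electrodes), `coherent_window_ms` (electrodes x 2), `qualifying`.
#' @export
phase_spread <- function(theta, catalog, window_ms = c(-250, 500)) {
  stopifnot(inherits(theta, "band_lfp"))
  if (nrow(catalog) < 5L) stopf("need at least 5 bursts (got %d)", nrow(catalog))
  fs <- theta$lfp$fs
  rel <- seq(round(window_ms[1] / 1000 * fs), round(window_ms[2] / 1000 * fs))
  idx0 <- round((catalog$peak_times - theta$lfp$t0) * fs) + 1L
  ok <- idx0 + rel[1] >= 1L & idx0 + rel[length(rel)] <= ncol(theta$phase)
  idx0 <- idx0[ok]
  if (length(idx0) < 5L) stopf("fewer than 5 bursts fit inside the recording")
  ne <- nrow(theta$phase)
  spread <- matrix(NA_real_, ne, length(rel))
  for (e in seq_len(ne)) {
    phm <- vapply(idx0, function(a) theta$phase[e, a + rel], numeric(length(rel)))
    z <- exp(1i * phm)
    rbar <- Mod(rowMeans(z))
    spread[e, ] <- sqrt(-2 * log(pmax(rbar, .Machine$double.xmin)))
  }
  t_ms <- rel / fs * 1000
  min_t <- rep(NA_real_, ne)
  coh <- matrix(NA_real_, ne, 2)
  qual <- logical(ne)
  for (e in seq_len(ne)) {
    if (min(spread[e, ]) < 1) {
      qual[e] <- TRUE
      k <- which.min(spread[e, ])
      min_t[e] <- t_ms[k]
      lo <- k; while (lo > 1L && spread[e, lo - 1L] < 1) lo <- lo - 1L
      hi <- k; while (hi < length(t_ms) && spread[e, hi + 1L] < 1) hi <- hi + 1L
      coh[e, ] <- c(t_ms[lo], t_ms[hi])
    }
  }
  structure(list(t_ms = t_ms, spread = spread, min_spread_time_ms = min_t,
                 coherent_window_ms = coh, qualifying = which(qual),
                 n_bursts = length(idx0)),
            class = "phase_spread")
}

#' @export
print.phase_spread <- function(x, ...) {
  cat(sprintf("phase_spread: %d electrodes, %d bursts; %d electrodes reach < 1 rad\n",
              nrow(x$spread), x$n_bursts, length(x$qualifying)))
  invisible(x)
}

#' Envelope threshold statistics inside vs outside bursts
#'
#' For each electrode and each threshold multiple `k`, the fraction of time
#' the band envelope exceeds `k` times its rms, split into burst and
#' non-burst periods. The rms comes from `reference_env` when given (e.g. a
#' pharmacologically silenced recording of the same electrodes, the noise
#' floor); otherwise from the electrode's own envelope. Also counts
#' electrodes whose burst fraction exceeds the non-burst fraction by at
#' least 10% (relative), and the percent change of each fraction against the
#' reference condition's overall fraction.
#'
#' @param env envelope matrix (electrodes x samples, uV), or a [band_lfp].
#' @param fs sampling rate (taken from the `band_lfp` when given).
#' @param catalog a [detect_bursts] catalog on the same time base.
#' @param k_values threshold multiples of the rms.
#' @param reference_env optional reference envelope matrix for the rms and
#'   the percent-change comparison.
#' @param increase_frac relative increase defining the burst-enhanced count.
#' @return list with `fractions` (data.frame electrode, k, burst, nonburst,
#'   overall, reference, pct_change), `n_burst_increased` per k,
#'   `n_nonburst_increased` per k.
#' @export
envelope_threshold_stats <- function(env, fs = NULL, catalog,
                                     k_values = c(1, 1.5, 2),
                                     reference_env = NULL,
                                     increase_frac = 0.10) {
  if (inherits(env, "band_lfp")) {
    fs <- env$lfp$fs
    t0 <- env$lfp$t0
    env <- env$envelope
  } else t0 <- 0
  if (is.null(fs)) stopf("'fs' required when 'env' is a plain matrix")
  ne <- nrow(env)
  ns <- ncol(env)
  t <- t0 + (seq_len(ns) - 1L) / fs
  inb <- rep(FALSE, ns)
  for (i in seq_len(nrow(catalog)))
    inb <- inb | (t >= catalog$starts[i] & t <= catalog$stops[i])
  if (!any(inb) || all(inb))
    warnf("burst partition is degenerate (%d of %d samples in bursts)",
          sum(inb), ns)
  rows <- list()
  n_up <- stats::setNames(integer(length(k_values)), k_values)
  n_down <- n_up
  for (ki in seq_along(k_values)) {
    k <- k_values[ki]
    for (e in seq_len(ne)) {
      base <- if (!is.null(reference_env)) rms(reference_env[e, ]) else rms(env[e, ])
      thr <- k * base
      fb <- if (any(inb)) mean(env[e, inb] > thr) else NA_real_
      fn <- if (any(!inb)) mean(env[e, !inb] > thr) else NA_real_
      fo <- mean(env[e, ] > thr)
      fref <- if (!is.null(reference_env)) mean(reference_env[e, ] > thr) else NA_real_
      pct <- if (!is.null(reference_env) && isTRUE(fref > 0))
        100 * (fo - fref) / fref else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        electrode = e, k = k, burst = fb, nonburst = fn, overall = fo,
        reference = fref, pct_change = pct)
      if (is.finite(fb) && is.finite(fn)) {
        if ((fn == 0 && fb > 0) || (fn > 0 && (fb - fn) / fn >= increase_frac))
          n_up[ki] <- n_up[ki] + 1L
        if ((fb == 0 && fn > 0) || (fb > 0 && (fn - fb) / fb >= increase_frac))
          n_down[ki] <- n_down[ki] + 1L
      }
    }
  }
  list(fractions = do.call(rbind, rows),
       n_burst_increased = n_up, n_nonburst_increased = n_down,
       k_values = k_values)
}
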