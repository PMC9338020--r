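# Population firing rate, burst detection and burst-to-burst similarity.

#' Population firing rate
#'
#' Sums 1 ms-binned spike counts over all units, then applies the requested
#' smoothing: `"unit_ma5"` is a 5 ms moving average of the summed counts;
#' `"mua_smooth"` averages over a 20 ms sliding window and then smooths with
#' a 100 ms Gaussian kernel (truncated at +/- 4 sd, unit area). All kernels
#' have unit area, so the total spike count is conserved away from the
#' recording edges.
#'
#' @param trains a [spike_train_set].
#' @param mode smoothing mode.
#' @param bin_ms time-grid step (ms).
#' @return object of class `population_rate`: list with `t` (bin centers,
#'   seconds), `rate` (spikes per bin after smoothing), `smoothing_spec`,
#'   `bin_s`.
#' @export
population_rate <- function(trains, mode = c("unit_ma5", "mua_smooth"),
                            bin_ms = 1) {
  mode <- match.arg(mode)
  if (!sum(lengths(trains$spikes))) stopf("spike train set is empty")
  bin_s <- bin_ms / 1000
  n_bins <- ceiling(trains$duration / bin_s)
  all_times <- unlist(trains$spikes, use.names = FALSE)
  idx <- pmin(floor(all_times / bin_s) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  rate <- switch(mode,
    unit_ma5 = moving_average(counts, round(5 / bin_ms)),
    mua_smooth = conv_same(moving_average(counts, round(20 / bin_ms)),
                           gaussian_kernel(100 / bin_ms)))
  structure(list(t = (seq_len(n_bins) - 0.5) * bin_s, rate = rate,
                 smoothing_spec = mode, bin_s = bin_s),
            class = "population_rate")
}

#' @export
print.population_rate <- function(x, ...) {
  cat(sprintf("population_rate: %d bins of %g ms (%s), peak %.2f spikes/bin\n",
              length(x$rate), x$bin_s * 1000, x$smoothing_spec, max(x$rate)))
  invisible(x)
}

#' @export
plot.population_rate <- function(x, ...) {
  graphics::plot(x$t, x$rate, type = "l", xlab = "time (s)",
                 ylab = "population rate (spikes/bin)", ...)
  invisible(x)
}

#' Detect population bursts
#'
#' Burst peaks are local maxima of the population rate exceeding
#' `peak_factor` times its rms value, with a minimum peak separation of
#' `min_separation_s`. The rms is computed over the full trace (bursts
#' included) by default; set `exclude_bursts_from_rms = TRUE` for an
#' iterated estimate that masks detected bursts and re-detects. Burst extent
#' runs from the nearest time before the peak to the nearest time after it
#' where the rate falls below `(1 - edge_attenuation)` of the peak amplitude
#' (search limited to +/- `edge_search_s` around the peak).
#'
#' @param rate a [population_rate].
#' @param peak_factor threshold in rms multiples.
#' @param min_separation_s minimum distance between burst peaks (s).
#' @param edge_attenuation fractional attenuation defining burst edges.
#' @param edge_search_s half-width of the edge search window (s).
#' @param exclude_bursts_from_rms see above.
#' @return object of class `burst_catalog`: data.frame with `peak_times`,
#'   `starts`, `stops`, `peak_amplitudes`, plus attributes `rms` and
#'   `threshold`. Quiescent input yields an empty catalog.
#' @export
detect_bursts <- function(rate, peak_factor = 2.0, min_separation_s = 1.0,
                          edge_attenuation = 0.9, edge_search_s = 2,
                          exclude_bursts_from_rms = FALSE) {
  stopifnot(inherits(rate, "population_rate"))
  if (length(rate$rate) * rate$bin_s < min_separation_s)
    stopf("rate trace shorter than the minimum burst separation")
  rms_val <- rms(rate$rate)
  cat_for <- function(rms_use) {
    thr <- peak_factor * rms_use
    peaks <- find_peaks(rate$rate, min_height = thr,
                        min_distance = max(1L, round(min_separation_s / rate$bin_s)))
    burst_extents(rate, peaks, edge_attenuation, edge_search_s, rms_use, thr)
  }
  out <- cat_for(rms_val)
  if (exclude_bursts_from_rms && nrow(out)) {
    mask <- rep(TRUE, length(rate$rate))
    for (i in seq_len(nrow(out))) {
      lo <- max(1L, floor(out$starts[i] / rate$bin_s))
      hi <- min(length(mask), ceiling(out$stops[i] / rate$bin_s))
      mask[lo:hi] <- FALSE
    }
    if (any(mask)) out <- cat_for(rms(rate$rate[mask]))
  }
  out
}

burst_extents <- function(rate, peaks, edge_attenuation, edge_search_s,
                          rms_use, thr) {
  n <- length(rate$rate)
  half <- round(edge_search_s / rate$bin_s)
  rows <- lapply(peaks, function(p) {
    amp <- rate$rate[p]
    floor_level <- (1 - edge_attenuation) * amp
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    pre <- rate$rate[lo:p]
    below <- which(pre < floor_level)
    start <- if (length(below)) lo + max(below) - 1L else lo
    post <- rate$rate[p:hi]
    below <- which(post < floor_level)
    stop_ <- if (length(below)) p + min(below) - 1L else hi
    data.frame(peak_times = rate$t[p], starts = rate$t[start],
               stops = rate$t[stop_], peak_amplitudes = amp)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak_times = numeric(0), starts = numeric(0),
               stops = numeric(0), peak_amplitudes = numeric(0))
  attr(out, "rms") <- rms_use
  attr(out, "threshold") <- thr
  class(out) <- c("burst_catalog", "data.frame")
  out
}

#' @export
print.burst_catalog <- function(x, ...) {
  cat(sprintf("burst_catalog: %d bursts (threshold %.3f = %gx rms)\n",
              nrow(x), attr(x, "threshold"),
              attr(x, "threshold") / max(attr(x, "rms"), .Machine$double.eps)))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

# Population rate with the burst-similarity smoothing: 5 ms moving average
# followed by a 5 ms Gaussian kernel.
similarity_rate <- function(trains, bin_ms = 1) {
  pr <- population_rate(trains, mode = "unit_ma5", bin_ms = bin_ms)
  pr$rate <- conv_same(pr$rate, gaussian_kernel(5 / bin_ms))
  pr$smoothing_spec <- "ma5_gauss5"
  pr
}

# Per-burst windowed population-rate vectors (rows) on a common relative
# time grid; bursts whose window leaves the recording are dropped.
burst_vectors <- function(pr, catalog, window_ms) {
  bin_ms <- pr$bin_s * 1000
  rel <- seq(round(window_ms[1] / bin_ms), round(window_ms[2] / bin_ms))
  peak_idx <- round(catalog$peak_times / pr$bin_s + 0.5)
  ok <- peak_idx + rel[1] >= 1 & peak_idx + rel[length(rel)] <= length(pr$rate)
  mat <- t(vapply(peak_idx[ok], function(p) pr$rate[p + rel],
                  numeric(length(rel))))
  list(mat = mat, rel_ms = rel * bin_ms, used = which(ok))
}

#' Burst-to-burst similarity matrix
#'
#' For each burst, the population-rate vector (5 ms moving average plus 5 ms
#' Gaussian smoothing) over a window relative to the burst peak (default
#' -100 ms to +350 ms); for each burst pair, the mean absolute difference of
#' the two vectors. Lower values mean more similar (more stereotyped)
#' bursts.
#'
#' @param trains a [spike_train_set].
#' @param catalog a [detect_bursts] catalog with at least two usable bursts.
#' @param window_ms window relative to the burst peak, ms.
#' @return object of class `burst_similarity`: list with the symmetric
#'   `matrix` (zero diagonal), `window_ms`, `mean_over_pairs` and the burst
#'   indices `used`.
#' @export
burst_similarity <- function(trains, catalog, window_ms = c(-100, 350)) {
  pr <- similarity_rate(trains)
  bv <- burst_vectors(pr, catalog, window_ms)
  n <- nrow(bv$mat)
  if (n < 2L) stopf("need at least 2 bursts inside the recording (got %d)", n)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- mean(abs(bv$mat[i, ] - bv$mat[j, ]))
    }
  }
  structure(list(matrix = m, window_ms = window_ms,
                 mean_over_pairs = mean(m[upper.tri(m)]), used = bv$used),
            class = "burst_similarity")
}

#' @export
print.burst_similarity <- function(x, ...) {
  cat(sprintf("burst_similarity: %d bursts, window [%g, %g] ms, mean pair difference %.4f\n",
              nrow(x$matrix), x$window_ms[1], x$window_ms[2], x$mean_over_pairs))
  invisible(x)
}

#' Fractional burst-similarity change over a grid of windows
#'
#' For every combination of window start (default -200..0 ms, step 10) and
#' stop (0..500 ms, step 10) relative to the burst peak, computes the grand
#' mean burst-pair rate difference for each condition (rho_a, rho_b) and the
#' fractional difference `(rho_a - rho_b) / (rho_a + rho_b)`; cells with a
#' zero denominator are set to 0 with a warning. Positive cells mean more
#' burst-to-burst variability in condition a.
#'
#' @param trains_a,catalog_a condition a (e.g. control).
#' @param trains_b,catalog_b condition b (e.g. drug).
#' @param start_range_ms `c(from, to, step)` for window starts.
#' @param stop_range_ms `c(from, to, step)` for window stops.
#' @return list with `grid` (matrix, starts in rows), `starts_ms`,
#'   `stops_ms`, `mean_score`.
#' @export
fractional_change_grid <- function(trains_a, catalog_a, trains_b, catalog_b,
                                   start_range_ms = c(-200, 0, 10),
                                   stop_range_ms = c(0, 500, 10)) {
  starts <- seq(start_range_ms[1], start_range_ms[2], by = start_range_ms[3])
  stops <- seq(stop_range_ms[1], stop_range_ms[2], by = stop_range_ms[3])
  widest <- c(min(starts), max(stops))
  prep <- function(trains, catalog) {
    pr <- similarity_rate(trains)
    bv <- burst_vectors(pr, catalog, widest)
    if (nrow(bv$mat) < 2L) stopf("each condition needs >= 2 usable bursts")
    # cumulative |difference| sums per burst pair -> O(1) window means
    pairs <- utils::combn(nrow(bv$mat), 2)
    cs <- apply(pairs, 2, function(ij)
      cumsum(abs(bv$mat[ij[1], ] - bv$mat[ij[2], ])))
    list(cs = cs, rel_ms = bv$rel_ms)
  }
  a <- prep(trains_a, catalog_a)
  b <- prep(trains_b, catalog_b)
  window_mean <- function(pp, s, e) {
    i1 <- match(s, pp$rel_ms); i2 <- match(e, pp$rel_ms)
    tot <- pp$cs[i2, ] - (if (i1 > 1) pp$cs[i1 - 1, ] else 0)
    mean(tot) / (i2 - i1 + 1)
  }
  grid <- matrix(NA_real_, length(starts), length(stops),
                 dimnames = list(starts, stops))
  zero_cells <- 0L
  for (i in seq_along(starts)) {
    for (j in seq_along(stops)) {
      ra <- window_mean(a, starts[i], stops[j])
      rb <- window_mean(b, starts[i], stops[j])
      if (ra + rb == 0) {
        grid[i, j] <- 0
        zero_cells <- zero_cells + 1L
      } else grid[i, j] <- (ra - rb) / (ra + rb)
    }
  }
  if (zero_cells) warnf("%d grid cell(s) had zero total rate difference; set to 0", zero_cells)
  list(grid = grid, starts_ms = starts, stops_ms = stops,
       mean_score = mean(grid))
}

#' Percent change in total spike count between two recordings
#'
#' `100 * (n_a - n_b) / n_a`, with counts normalized to rates per second when
#' the recording durations differ.
#'
#' @param trains_a reference condition.
#' @param trains_b comparison condition.
#' @return percent reduction (positive when b has fewer spikes).
#' @export
spike_count_change <- function(trains_a, trains_b) {
  na <- sum(lengths(trains_a$spikes)) / trains_a$duration
  nb <- sum(lengths(trains_b$spikes)) / trains_b$duration
  if (na == 0) stopf("reference recording has no spikes; change undefined")
  100 * (na - nb) / na
}
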