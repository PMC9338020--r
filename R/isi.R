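# Per-unit interspike-interval statistics.

#' Per-unit ISI statistics with exponential-fit classification
#'
#' For each unit with at least `min_spikes` spikes inside the first
#' `window_s` seconds, computes the mean, standard deviation and coefficient
#' of variation (CV = sigma/mu) of its inter-spike intervals, after
#' restricting ISIs to `isi_range_ms` (the range filter is applied before all
#' further statistics; set `apply_range_filter = FALSE` for raw ISIs), and
#' classifies the ISI distribution as exponential via [fit_exponential_isi].
#'
#' @param trains a [spike_train_set].
#' @param min_spikes minimum spike count inside the selection window.
#' @param window_s selection window length (seconds); must not exceed the
#'   recording duration.
#' @param isi_range_ms two-element range of ISIs (ms) kept for analysis.
#' @param apply_range_filter apply the range filter before mu/sigma/CV and
#'   the fit.
#' @param fit also run the exponential fit per unit.
#' @param r2_threshold goodness-of-fit threshold for the exponential class.
#' @return data.frame (one row per qualifying unit) with columns `unit_id`,
#'   `n_isi`, `mu`, `sigma`, `cv`, and when `fit = TRUE` also `exp_a`,
#'   `exp_lambda`, `exp_r2`, `is_exponential`.
#' @export
compute_isi_stats <- function(trains, min_spikes = 30, window_s = 180,
                              isi_range_ms = c(8, 100),
                              apply_range_filter = TRUE, fit = TRUE,
                              r2_threshold = 0.9) {
  window_s <- min(window_s, trains$duration)
  rows <- lapply(trains$unit_ids, function(u) {
    s <- trains$spikes[[u]]
    if (sum(s <= window_s) < min_spikes) return(NULL)
    isis <- diff(s)
    if (apply_range_filter)
      isis <- isis[isis >= isi_range_ms[1] / 1000 & isis <= isi_range_ms[2] / 1000]
    if (length(isis) < 2L) return(NULL)
    mu <- mean(isis)
    sigma <- stats::sd(isis)
    out <- data.frame(unit_id = u, n_isi = length(isis), mu = mu,
                      sigma = sigma, cv = sigma / mu,
                      stringsAsFactors = FALSE)
    if (fit) {
      f <- fit_exponential_isi(isis, r2_threshold = r2_threshold)
      out$exp_a <- f$a
      out$exp_lambda <- f$lambda
      out$exp_r2 <- f$r2
      out$is_exponential <- f$is_exponential
    }
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(unit_id = character(0), n_isi = integer(0),
                      mu = numeric(0), sigma = numeric(0), cv = numeric(0))
    return(out)
  }
  do.call(rbind, rows)
}

#' Fit an exponential to a normalized ISI histogram
#'
#' Bins the ISIs at a width of 1/`bin_divisor` of the median ISI, normalizes
#' the bin counts to unit sum, and fits `a * exp(-lambda * x)` to the
#' (midpoint, normalized count) pairs by nonlinear least squares (start
#' values: `a` = maximum bin height, `lambda` = 1/mean ISI; at most
#' `max_iter` iterations). R-squared is `1 - RSS/TSS` over the binned values.
#' Degenerate input (fewer than two nonempty bins) or non-convergence yields
#' a failed fit, never an error.
#'
#' @param isis numeric vector of inter-spike intervals (seconds).
#' @param bin_divisor bin width = `median(isis) / bin_divisor`.
#' @param r2_threshold classification threshold on R-squared.
#' @param max_iter iteration cap for the least-squares optimizer.
#' @return list with `a`, `lambda`, `r2`, `converged`, `is_exponential`.
#' @export
fit_exponential_isi <- function(isis, bin_divisor = 15, r2_threshold = 0.9,
                                max_iter = 1000) {
  failed <- list(a = NA_real_, lambda = NA_real_, r2 = NA_real_,
                 converged = FALSE, is_exponential = FALSE)
  isis <- isis[is.finite(isis) & isis >= 0]
  if (length(isis) < 2L) return(failed)
  bw <- stats::median(isis) / bin_divisor
  if (bw <= 0 || max(isis) == min(isis)) return(failed)
  breaks <- seq(min(isis), max(isis) + bw, by = bw)
  counts <- graphics::hist(isis, breaks = breaks, plot = FALSE)$counts
  if (sum(counts > 0) < 2L) return(failed)
  y <- counts / sum(counts)
  x <- (breaks[-1] + breaks[-length(breaks)]) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-lambda * x),
                      start = list(a = max(y), lambda = 1 / mean(isis)),
                      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                                           ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  co <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  list(a = unname(co["a"]), lambda = unname(co["lambda"]), r2 = r2,
       converged = TRUE,
       is_exponential = isTRUE(r2 > r2_threshold))
}

#' Two-sample Kolmogorov-Smirnov comparison of ISI samples
#'
#' @param a,b numeric ISI samples (each of length >= 2).
#' @return list with `ks_statistic` and `p_value` (two-sided).
#' @export
compare_isi_distributions <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stopf("both samples need at least 2 values (got %d, %d)",
          length(a), length(b))
  ks <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value)
}
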