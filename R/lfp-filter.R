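# LFP extraction, band filtering, envelope/phase and Welch spectra.

#' Standard oscillatory band definitions
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-50 Hz.
#' @return data.frame with `name`, `low`, `high` (Hz).
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(0.5, 4, 8, 13, 30),
             high = c(4, 8, 13, 30, 50), stringsAsFactors = FALSE)
}

band_range <- function(band) {
  bd <- band_definitions()
  i <- match(band, bd$name)
  if (is.na(i)) stopf("unknown band '%s'", band)
  c(bd$low[i], bd$high[i])
}

#' Extract the LFP component from wide-band voltage traces
#'
#' Zero-phase (forward-backward) low-pass Butterworth filter at `cutoff` Hz,
#' followed by decimation to `fs_out`; the native sampling rate must be an
#' integer multiple of `fs_out` and at least twice the cutoff.
#'
#' @param raw an [lfp_set] at native sampling rate (>= 2 kHz).
#' @param cutoff low-pass corner frequency, Hz.
#' @param order Butterworth order (halved effective roll-off is doubled by
#'   the bidirectional pass).
#' @param fs_out output sampling rate, Hz.
#' @return an `lfp_set` with `band = "lfp"`.
#' @export
extract_lfp <- function(raw, cutoff = 500, order = 4, fs_out = 1000) {
  stopifnot(inherits(raw, "lfp_set"))
  if (raw$fs < 2000) stopf("native sampling rate must be >= 2 kHz (got %g)", raw$fs)
  if (raw$fs < 2 * cutoff)
    stopf("sampling rate %g Hz cannot represent a %g Hz cutoff", raw$fs, cutoff)
  dec <- raw$fs / fs_out
  if (abs(dec - round(dec)) > 1e-9)
    stopf("fs (%g) must be an integer multiple of fs_out (%g)", raw$fs, fs_out)
  dec <- as.integer(round(dec))
  bf <- signal::butter(order, cutoff / (raw$fs / 2), type = "low")
  filt <- t(apply(raw$data, 1, function(ch)
    signal::filtfilt(bf, ch)))
  keep <- seq(1L, ncol(filt), by = dec)
  lfp_set(filt[, keep, drop = FALSE], fs = fs_out,
          positions = raw$positions, band = "lfp", t0 = raw$t0)
}

#' Band-pass filter an LFP and extract envelope and phase
#'
#' Zero-phase FIR band-pass (windowed-sinc design, Hamming window, order
#' `3 * fs / low` rounded to even, applied forward-backward), then the
#' analytic signal per electrode: envelope in uV and instantaneous phase in
#' radians, with 0 at the oscillation peak (angle of the analytic signal of
#' a cosine) and range (-pi, pi].
#'
#' @param lfp an [lfp_set] (typically `band = "lfp"` at 1 kHz).
#' @param band band name (see [band_definitions]) or a two-element numeric
#'   range in Hz.
#' @param order FIR order override.
#' @return object of class `band_lfp`: `lfp` (the filtered `lfp_set`),
#'   `envelope` and `phase` matrices (electrodes x samples), `band`,
#'   `range_hz`.
#' @export
band_filter <- function(lfp, band = "theta", order = NULL) {
  stopifnot(inherits(lfp, "lfp_set"))
  if (is.character(band)) {
    rng <- band_range(band)
    label <- band
  } else {
    rng <- as.numeric(band)
    label <- "lfp"
  }
  if (lfp$fs < 4 * rng[2])
    stopf("sampling rate %g Hz too low for the %g-%g Hz band", lfp$fs, rng[1], rng[2])
  if (is.null(order)) order <- 2L * ceiling(3 * lfp$fs / rng[1] / 2)
  if (order >= ncol(lfp$data))
    order <- 2L * floor((ncol(lfp$data) - 2L) / 6L)  # short traces: shrink
  b <- signal::fir1(order, rng / (lfp$fs / 2), type = "pass")
  nch <- nrow(lfp$data)
  filt <- matrix(0, nch, ncol(lfp$data))
  env <- matrix(0, nch, ncol(lfp$data))
  ph <- matrix(0, nch, ncol(lfp$data))
  for (e in seq_len(nch)) {
    x <- signal::filtfilt(b, lfp$data[e, ])
    a <- analytic_signal(x)
    filt[e, ] <- x
    env[e, ] <- Mod(a)
    ph[e, ] <- Arg(a)
  }
  out_lfp <- lfp_set(filt, fs = lfp$fs, positions = lfp$positions,
                     band = if (label %in% .lfp_bands) label else "lfp",
                     t0 = lfp$t0)
  structure(list(lfp = out_lfp, envelope = env, phase = ph,
                 band = label, range_hz = rng, fir_order = order),
            class = "band_lfp")
}

#' @export
print.band_lfp <- function(x, ...) {
  cat(sprintf("band_lfp: %s band (%.1f-%.1f Hz), %d electrodes x %d samples @ %g Hz\n",
              x$band, x$range_hz[1], x$range_hz[2],
              nrow(x$lfp$data), ncol(x$lfp$data), x$lfp$fs))
  invisible(x)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram (Hamming window, `segment_s` segments with
#' fractional `overlap`), scaled to uV^2/Hz so that the integral over
#' frequency recovers the signal variance.
#'
#' @param lfp an [lfp_set] or `band_lfp`.
#' @param segment_s window length, seconds.
#' @param overlap fractional overlap in \[0, 1).
#' @return list with `freq` (Hz) and `psd` (electrodes x frequencies,
#'   uV^2/Hz).
#' @export
compute_psd <- function(lfp, segment_s = 0.5, overlap = 0.25) {
  if (inherits(lfp, "band_lfp")) lfp <- lfp$lfp
  stopifnot(inherits(lfp, "lfp_set"))
  nseg_len <- round(segment_s * lfp$fs)
  if (ncol(lfp$data) < 2 * nseg_len)
    stopf("recording must cover at least two segments of %g s", segment_s)
  w <- welch_segments(ncol(lfp$data), nseg_len, overlap)
  win <- hamming_window(nseg_len)
  U <- sum(win^2)
  nf <- nseg_len %/% 2 + 1
  psd <- matrix(0, nrow(lfp$data), nf)
  for (e in seq_len(nrow(lfp$data))) {
    acc <- numeric(nf)
    for (s in w) {
      seg <- lfp$data[e, s:(s + nseg_len - 1L)]
      X <- stats::fft((seg - mean(seg)) * win)[1:nf]
      acc <- acc + Mod(X)^2
    }
    p <- acc / length(w) / (U * lfp$fs)
    # one-sided: double all bins except DC (and Nyquist for even lengths)
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    if (nseg_len %% 2 == 1) p[nf] <- 2 * p[nf]
    psd[e, ] <- p
  }
  list(freq = (0:(nf - 1)) * lfp$fs / nseg_len, psd = psd,
       segment_s = segment_s, overlap = overlap, n_segments = length(w))
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

welch_segments <- function(n_samples, seg_len, overlap) {
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n_samples - seg_len + 1L, by = step)
  as.list(starts)
}
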