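# Shared numerical helpers.

#' Root mean square
#'
#' @param x numeric vector.
#' @param na.rm drop missing values first.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  sqrt(mean(x^2))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so internal Monte-Carlo tables do not perturb user-level
#' reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Centered moving average with zero padding; kernel length k (odd enforced).
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k < 1L) stopf("moving average window must be >= 1")
  if (k == 1L) return(x)
  kern <- rep(1 / k, k)
  conv_same(x, kern)
}

# Unit-area Gaussian kernel, sd in samples, truncated at +/- 4 sd.
gaussian_kernel <- function(sd_samples) {
  if (sd_samples <= 0) return(1)
  half <- max(1L, ceiling(4 * sd_samples))
  g <- exp(-0.5 * ((-half:half) / sd_samples)^2)
  g / sum(g)
}

# 'same'-size linear convolution with zero padding (mass-conserving in the
# interior: sum(conv_same(x, k)) == sum(x) when x's support is >= 4 sd from
# the edges and sum(k) == 1). FFT-based with power-of-two padding.
conv_same <- function(x, kern) {
  n <- length(x)
  m <- length(kern)
  nfft <- stats::nextn(n + m - 1L, 2)
  full <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                          stats::fft(c(kern, numeric(nfft - m))),
                        inverse = TRUE)) / nfft
  start <- (m - 1L) %/% 2L + 1L
  out <- full[start:(start + n - 1L)]
  out[abs(out) < max(abs(out)) * 1e-12] <- 0  # FFT round-off outside support
  out
}

# --- circular statistics -----------------------------------------------------

#' Circular mean, resultant length and circular standard deviation
#'
#' @param theta angles in radians.
#' @return list with `mu` (mean angle, radians in (-pi, pi]), `r` (mean
#'   resultant length in \[0, 1\]) and `sd` (circular standard deviation
#'   `sqrt(-2 log r)`).
#' @export
circ_stats <- function(theta) {
  theta <- theta[is.finite(theta)]
  n <- length(theta)
  if (n == 0L) return(list(mu = NA_real_, r = NA_real_, sd = NA_real_, n = 0L))
  z <- sum(exp(1i * theta))
  r <- Mod(z) / n
  list(mu = Arg(z), r = r, sd = sqrt(-2 * log(max(r, .Machine$double.xmin))), n = n)
}

wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # map -pi to pi so the range is (-pi, pi]
  w[w == -pi] <- pi
  w
}

# --- peak finding ------------------------------------------------------------

# Local maxima above `min_height`, greedily enforcing `min_distance` (in
# samples) in order of decreasing amplitude -- the usual findpeaks semantics.
find_peaks <- function(x, min_height = -Inf, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  idx <- idx[x[idx] >= min_height]
  if (length(idx) <= 1L || min_distance <= 1L) return(sort(idx))
  idx <- idx[order(x[idx], decreasing = TRUE)]
  keep <- logical(length(idx))
  taken <- rep(FALSE, n)
  for (i in seq_along(idx)) {
    p <- idx[i]
    if (!taken[p]) {
      keep[i] <- TRUE
      lo <- max(1L, p - min_distance + 1L)
      hi <- min(n, p + min_distance - 1L)
      taken[lo:hi] <- TRUE
    }
  }
  sort(idx[keep])
}

# Analytic signal via FFT; x real vector. Returns complex vector whose
# modulus is the envelope and argument the instantaneous phase (0 at a
# local maximum of an in-band oscillation).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
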