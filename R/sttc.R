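# Spike time tiling coefficient.

#' Spike time tiling coefficient (STTC)
#'
#' Firing-rate-robust pairwise spike correlation:
#' `STTC = 1/2 * ((P_A - T_B)/(1 - P_A*T_B) + (P_B - T_A)/(1 - P_B*T_A))`,
#' where `T_X` is the fraction of the recording tiled by windows of +/-
#' `delta_t` around X's spikes (windows clipped to `[0, duration]`, overlaps
#' merged) and `P_X` is the fraction of X's spikes that fall within
#' `delta_t` of any spike of the other train. The value lies in `[-1, 1]`
#' and is symmetric in its arguments. A term with a zero denominator
#' (possible only when one train tiles the whole recording and the other has
#' perfect coincidence) contributes 0.
#'
#' @param spikes_a,spikes_b sorted spike-time vectors (seconds).
#' @param delta_t_ms coincidence half-window, ms.
#' @param duration_s recording duration, seconds.
#' @return the STTC, or `NA` (flagged, not an error) when either train is
#'   empty.
#' @export
compute_sttc <- function(spikes_a, spikes_b, delta_t_ms = 20, duration_s) {
  if (!is_scalar_num(duration_s) || duration_s <= 0) stopf("'duration_s' must be > 0")
  if (delta_t_ms <= 0) stopf("'delta_t_ms' must be > 0")
  if (!length(spikes_a) || !length(spikes_b)) return(NA_real_)
  dt <- delta_t_ms / 1000
  ta <- tiled_fraction(spikes_a, dt, duration_s)
  tb <- tiled_fraction(spikes_b, dt, duration_s)
  pa <- prop_within(spikes_a, spikes_b, dt)
  pb <- prop_within(spikes_b, spikes_a, dt)
  0.5 * (sttc_term(pa, tb) + sttc_term(pb, ta))
}

sttc_term <- function(p, t) {
  den <- 1 - p * t
  if (den == 0) return(0)
  (p - t) / den
}

# Fraction of [0, duration] covered by the union of +/- dt windows.
tiled_fraction <- function(spikes, dt, duration) {
  starts <- pmax(spikes - dt, 0)
  ends <- pmin(spikes + dt, duration)
  ce <- cummax(c(-Inf, ends[-length(ends)]))
  sum(pmax(0, ends - pmax(starts, ce))) / duration
}

# Fraction of a's spikes with a spike of b within dt (binary search on the
# sorted b).
prop_within <- function(a, b, dt) {
  idx <- findInterval(a, b)
  d_prev <- ifelse(idx >= 1L, a - b[pmax(idx, 1L)], Inf)
  d_next <- ifelse(idx < length(b), b[pmin(idx + 1L, length(b))] - a, Inf)
  mean(pmin(d_prev, d_next) <= dt)
}

#' Pairwise STTC matrix for a spike train set
#'
#' @param trains a [spike_train_set].
#' @param delta_t_ms coincidence half-window, ms.
#' @return symmetric matrix (units x units) with `NA` diagonal and `NA` for
#'   pairs involving an empty train.
#' @export
sttc_matrix <- function(trains, delta_t_ms = 20) {
  ids <- trains$unit_ids
  n <- length(ids)
  dur <- trains$duration
  dt <- delta_t_ms / 1000
  tiles <- vapply(trains$spikes, function(s)
    if (length(s)) tiled_fraction(s, dt, dur) else NA_real_, numeric(1))
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    a <- trains$spikes[[i]]
    if (!length(a)) next
    for (j in (i + 1L):n) {
      b <- trains$spikes[[j]]
      if (!length(b)) next
      pa <- prop_within(a, b, dt)
      pb <- prop_within(b, a, dt)
      m[i, j] <- m[j, i] <- 0.5 * (sttc_term(pa, tiles[j]) + sttc_term(pb, tiles[i]))
    }
  }
  m
}
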