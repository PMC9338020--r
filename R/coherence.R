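# Imaginary coherence and coherent-pocket detection.

#' Imaginary coherence matrix
#'
#' Welch cross-spectra (Hamming windows of `window_s` seconds, fractional
#' `overlap`) give the coherency `C_xy(f) = S_xy / sqrt(S_xx * S_yy)`; the
#' connectivity value per electrode pair is the absolute imaginary part of
#' the coherency averaged over the frequency bins of the band. Zero-lag
#' (volume-conducted) coupling has purely real coherency, so a channel and
#' any scaled copy of itself score exactly 0. Regional strength per
#' electrode is the row mean of Fisher-Z (atanh) transformed values,
#' back-transformed.
#'
#' @param lfp a [band_lfp] (band taken from it) or an [lfp_set] plus `band`.
#' @param band band name or numeric range (Hz) when `lfp` is an `lfp_set`.
#' @param window_s Welch window length, seconds.
#' @param overlap fractional overlap.
#' @param signed keep the signed imaginary part (its absolute value is taken
#'   after averaging instead of before).
#' @return object of class `coherence_matrix`: `values` (electrodes x
#'   electrodes, symmetric, zero diagonal), `regional_strength`, `band`,
#'   `freq_bins`, `flagged` (zero-variance electrodes, NA rows).
#' @export
imaginary_coherence <- function(lfp, band = "theta", window_s = 0.5,
                                overlap = 0.25, signed = FALSE) {
  if (inherits(lfp, "band_lfp")) {
    rng <- lfp$range_hz
    band <- lfp$band
    lfp <- lfp$lfp
  } else {
    rng <- if (is.character(band)) band_range(band) else as.numeric(band)
  }
  stopifnot(inherits(lfp, "lfp_set"))
  seg_len <- round(window_s * lfp$fs)
  segs <- welch_segments(ncol(lfp$data), seg_len, overlap)
  if (length(segs) < 4L)
    stopf("recording must cover at least 4 windows of %g s", window_s)
  win <- hamming_window(seg_len)
  nf <- seg_len %/% 2 + 1
  freq <- (0:(nf - 1)) * lfp$fs / seg_len
  bins <- which(freq >= rng[1] & freq <= rng[2])
  if (!length(bins)) stopf("no frequency bins inside %g-%g Hz", rng[1], rng[2])
  ne <- nrow(lfp$data)
  flagged <- which(apply(lfp$data, 1, stats::sd) == 0)
  # segment FFTs: electrodes x segments x bins
  X <- array(0i, dim = c(ne, length(segs), length(bins)))
  for (e in seq_len(ne)) {
    for (s in seq_along(segs)) {
      seg <- lfp$data[e, segs[[s]]:(segs[[s]] + seg_len - 1L)]
      X[e, s, ] <- stats::fft((seg - mean(seg)) * win)[bins]
    }
  }
  auto <- matrix(0, ne, length(bins))
  for (e in seq_len(ne)) auto[e, ] <- colMeans(Mod(X[e, , , drop = FALSE][1, , ])^2)
  eps <- max(auto) * 1e-14
  vals <- matrix(0, ne, ne)
  for (i in seq_len(ne - 1L)) {
    for (j in (i + 1L):ne) {
      sxy <- colMeans(X[i, , ] * Conj(X[j, , ]))
      den <- sqrt(auto[i, ] * auto[j, ])
      coh <- ifelse(den > eps, Im(sxy) / den, 0)
      v <- if (signed) abs(mean(coh)) else mean(abs(coh))
      vals[i, j] <- vals[j, i] <- v
    }
  }
  if (length(flagged)) vals[flagged, ] <- vals[, flagged] <- NA_real_
  diag(vals) <- 0
  z <- atanh(pmin(vals, 1 - 1e-12))
  regional <- tanh(rowMeans(z, na.rm = TRUE) * ne / pmax(ne - 1, 1))
  structure(list(values = vals, regional_strength = regional, band = band,
                 range_hz = rng, freq_bins = freq[bins], window_s = window_s,
                 overlap = overlap, flagged = flagged),
            class = "coherence_matrix")
}

#' @export
print.coherence_matrix <- function(x, ...) {
  cat(sprintf("coherence_matrix: %d electrodes, %s band (%.1f-%.1f Hz), mean |imag coh| %.3f\n",
              nrow(x$values), x$band, x$range_hz[1], x$range_hz[2],
              mean(x$values[upper.tri(x$values)], na.rm = TRUE)))
  invisible(x)
}

#' Detect spatially coherent electrode pockets
#'
#' Thresholds the coherence matrix at its `percentile`-th percentile
#' (off-diagonal values), selects hub electrodes with more than
#' `min_connections` supra-threshold connections (rescaled to the electrode
#' count when none qualifies at the nominal value), and clusters the hubs
#' and their neighbors by k-means on their thresholded connection-profile
#' rows (squared Euclidean distance). k is chosen from `k_range` by average
#' silhouette width. The coherence inside the tightest cluster is compared
#' against its coherence to the remaining electrodes with a Wilcoxon rank-sum
#' test.
#'
#' @param cm a [imaginary_coherence] result.
#' @param percentile binarization percentile (0-100).
#' @param min_connections hub degree threshold (nominal, for a 1020-electrode
#'   array; auto-scaled when no node qualifies).
#' @param k_range candidate cluster counts.
#' @param seed RNG seed for k-means restarts.
#' @return object of class `coherent_pockets`: `clusters` (membership over
#'   the clustered electrodes), `pocket` (electrode indices of the tightest
#'   cluster), `hubs`, `k`, `silhouette`, `rank_sum_p`, `threshold`; or an
#'   empty result (with a warning) when nothing passes.
#' @export
coherent_pockets <- function(cm, percentile = 90, min_connections = 200,
                             k_range = 2:6, seed = 1L) {
  stopifnot(inherits(cm, "coherence_matrix"))
  v <- cm$values
  off <- v[upper.tri(v)]
  thr <- stats::quantile(off, percentile / 100, na.rm = TRUE, names = FALSE)
  adj <- !is.na(v) & v > thr
  diag(adj) <- FALSE
  if (!any(adj)) {
    warnf("no coherence value exceeds the %gth percentile threshold", percentile)
    return(structure(list(clusters = integer(0), pocket = integer(0),
                          hubs = integer(0), k = NA_integer_,
                          silhouette = NA_real_, rank_sum_p = NA_real_,
                          threshold = thr), class = "coherent_pockets"))
  }
  deg <- rowSums(adj)
  ne <- nrow(v)
  hubs <- which(deg > min_connections)
  if (!length(hubs)) {
    scaled <- max(1, round(min_connections * ne / 1020))
    warnf("no electrode exceeds %d connections; rescaling the hub threshold to %d for %d electrodes",
          min_connections, scaled, ne)
    hubs <- which(deg > scaled)
  }
  if (!length(hubs)) {
    warnf("no hub electrodes found")
    return(structure(list(clusters = integer(0), pocket = integer(0),
                          hubs = integer(0), k = NA_integer_,
                          silhouette = NA_real_, rank_sum_p = NA_real_,
                          threshold = thr), class = "coherent_pockets"))
  }
  members <- sort(unique(c(hubs, which(colSums(adj[hubs, , drop = FALSE]) > 0))))
  feat <- adj[members, , drop = FALSE] * 1
  best <- NULL
  with_seed(seed, {
    for (k in k_range) {
      if (k >= length(members)) next
      km <- tryCatch(stats::kmeans(feat, centers = k, nstart = 10, iter.max = 50),
                     error = function(e) NULL)
      if (is.null(km) || length(unique(km$cluster)) < 2L) next
      sil <- cluster::silhouette(km$cluster, stats::dist(feat)^2)
      avg <- mean(sil[, "sil_width"])
      if (is.null(best) || avg > best$sil) best <- list(km = km, k = k, sil = avg)
    }
  })
  if (is.null(best)) {
    warnf("k-means produced no valid clustering over k in [%d, %d]",
          min(k_range), max(k_range))
    return(structure(list(clusters = integer(0), pocket = integer(0),
                          hubs = hubs, k = NA_integer_, silhouette = NA_real_,
                          rank_sum_p = NA_real_, threshold = thr),
                     class = "coherent_pockets"))
  }
  # tightest cluster: highest mean within-cluster coherence
  within_mean <- vapply(seq_len(best$k), function(cl) {
    el <- members[best$km$cluster == cl]
    if (length(el) < 2L) return(-Inf)
    w <- v[el, el]
    mean(w[upper.tri(w)], na.rm = TRUE)
  }, numeric(1))
  pocket_cl <- which.max(within_mean)
  pocket <- members[best$km$cluster == pocket_cl]
  rest <- setdiff(seq_len(ne), pocket)
  w_in <- v[pocket, pocket][upper.tri(diag(length(pocket)))]
  w_out <- as.vector(v[pocket, rest])
  p <- if (length(w_in) >= 2 && length(w_out) >= 2)
    suppressWarnings(stats::wilcox.test(w_in, w_out)$p.value) else NA_real_
  structure(list(clusters = stats::setNames(best$km$cluster, members),
                 pocket = pocket, hubs = hubs, k = best$k,
                 silhouette = best$sil, rank_sum_p = p, threshold = thr,
                 members = members),
            class = "coherent_pockets")
}

#' @export
print.coherent_pockets <- function(x, ...) {
  if (!length(x$pocket)) {
    cat("coherent_pockets: empty result\n")
  } else {
    cat(sprintf("coherent_pockets: %d hubs, k = %d (silhouette %.2f), pocket of %d electrodes (rank-sum p = %.3g)\n",
                length(x$hubs), x$k, x$silhouette, length(x$pocket), x$rank_sum_p))
  }
  invisible(x)
}

#' Overlap between two electrode site sets
#'
#' @param site_set_a,site_set_b electrode index/id vectors over the same
#'   array.
#' @return list with `jaccard` (`|a & b| / |a | b|`) and `directional`
#'   (`|a & b| / |a|`).
#' @export
overlap_fraction <- function(site_set_a, site_set_b) {
  a <- unique(site_set_a)
  b <- unique(site_set_b)
  if (!length(a) && !length(b)) stopf("overlap of two empty sets is undefined")
  list(jaccard = length(intersect(a, b)) / length(union(a, b)),
       directional = if (length(a)) length(intersect(a, b)) / length(a) else NA_real_)
}
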