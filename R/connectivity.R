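# Latency-gated directed functional connectivity from pairwise STTC.

#' Pairwise spike-time latency statistics
#'
#' For each spike of `spikes_a`, the signed latency (ms) to the nearest spike
#' of `spikes_b` is collected when it lies within `+/- window_ms` (positive
#' latency = b fires after a). The summary holds the mean latency, the full
#' width at half maximum (FWHM) of the 1 ms latency histogram (linear
#' interpolation at half the modal bin height), and a dip test of the latency
#' sample: a multimodal latency distribution (dip p < `dip_alpha`) marks the
#' pair as bidirectional rather than a single directed connection.
#'
#' @param spikes_a,spikes_b sorted spike-time vectors (seconds), nonempty.
#' @param window_ms latency window half-width.
#' @param hist_bin_ms histogram bin for the FWHM estimate.
#' @param min_latencies pairs with fewer matched latencies are marked
#'   unconnectable.
#' @param dip_alpha unimodality threshold on the dip p-value.
#' @param dip_boot Monte-Carlo replicates for the dip test.
#' @param dip_method dip p-value method (see [dip_test]).
#' @return list of class `pair_latency`: `latencies` (ms), `n`,
#'   `mean_latency`, `fwhm`, `dip_p`, `unimodal`, `connectable`.
#' @export
pair_latencies <- function(spikes_a, spikes_b, window_ms = 20,
                           hist_bin_ms = 1, min_latencies = 10,
                           dip_alpha = 0.1, dip_boot = 2000,
                           dip_method = "interpolate") {
  if (!length(spikes_a) || !length(spikes_b))
    stopf("both spike trains must be nonempty")
  lat <- nearest_latencies_ms(spikes_a, spikes_b)
  lat <- lat[abs(lat) <= window_ms]
  out <- list(latencies = lat, n = length(lat),
              mean_latency = NA_real_, fwhm = NA_real_,
              dip_p = NA_real_, unimodal = NA, connectable = FALSE)
  class(out) <- "pair_latency"
  if (length(lat) < max(min_latencies, 4L)) return(out)
  out$mean_latency <- mean(lat)
  out$fwhm <- fwhm_from_histogram(lat, window_ms, hist_bin_ms)
  if (diff(range(lat)) < hist_bin_ms) {
    # the whole sample sits inside one histogram bin: trivially unimodal
    # (sub-resolution float jitter would otherwise feed the dip test noise)
    out$dip_p <- 1
    out$unimodal <- TRUE
  } else {
    dt <- dip_test(lat, n_boot = dip_boot, method = dip_method)
    out$dip_p <- dt$p_value
    out$unimodal <- dt$p_value >= dip_alpha
  }
  out$connectable <- TRUE
  out
}

# Signed latency (ms) from each spike of a to its nearest spike of b.
nearest_latencies_ms <- function(a, b) {
  idx <- findInterval(a, b)
  d_prev <- ifelse(idx >= 1L, a - b[pmax(idx, 1L)], Inf)
  d_next <- ifelse(idx < length(b), b[pmin(idx + 1L, length(b))] - a, Inf)
  lat_s <- ifelse(d_prev <= d_next, -d_prev, d_next)  # signed: b after a > 0
  lat_s * 1000
}

# FWHM of the binned latency histogram by linear interpolation at half the
# modal bin height; single-occupied-bin samples get one bin width.
fwhm_from_histogram <- function(lat, window_ms, bin_ms) {
  breaks <- seq(-window_ms - bin_ms / 2, window_ms + bin_ms / 2, by = bin_ms)
  h <- graphics::hist(lat, breaks = breaks, plot = FALSE)
  y <- h$counts
  mids <- h$mids
  pk <- which.max(y)
  half <- y[pk] / 2
  # walk left from the peak to the half-height crossing
  left <- mids[pk] - bin_ms / 2
  for (i in pk:1) {
    if (y[i] < half) {
      left <- mids[i] + (mids[i + 1] - mids[i]) * (half - y[i]) / (y[i + 1] - y[i])
      break
    }
    if (i == 1) left <- mids[1] - bin_ms / 2
  }
  right <- mids[pk] + bin_ms / 2
  for (i in pk:length(y)) {
    if (y[i] < half) {
      right <- mids[i - 1] + (mids[i] - mids[i - 1]) * (y[i - 1] - half) / (y[i - 1] - y[i])
      break
    }
    if (i == length(y)) right <- mids[length(y)] + bin_ms / 2
  }
  max(right - left, 0)
}

#' Build the latency-gated directed connectivity graph
#'
#' Candidate edges are unit pairs whose STTC (at `delta_t_ms`) reaches
#' `sttc_threshold`; a pair is kept only when its latency distribution is
#' unimodal (dip p >= `dip_alpha`), its FWHM is at most `fwhm_max_ms`, and at
#' least `min_latencies` latencies were matched. Direction follows the sign
#' of the mean latency (a -> b when b lags a on average). Bimodal
#' (bidirectional) pairs are excluded and counted. Node classes follow the
#' normalized degree imbalance: sender when
#' `(D_out - D_in)/(D_out + D_in) > class_threshold`, receiver for the
#' mirrored inequality, broker otherwise (including isolated nodes with no
#' edges). Components are computed ignoring direction.
#'
#' With `gate_order = "gate_first"` the latency gates are evaluated for every
#' pair (so the count of excluded bimodal pairs covers every pair); with
#' `"threshold_first"` latencies are only computed for pairs already above
#' the STTC threshold -- the retained edges are identical, only the excluded
#' counts and runtime differ.
#'
#' @param trains a [spike_train_set] with at least 2 units.
#' @param sttc_threshold lower bound on edge strength.
#' @param delta_t_ms STTC coincidence half-window.
#' @param class_threshold sender/receiver imbalance threshold.
#' @param fwhm_max_ms latency-width gate.
#' @param dip_alpha unimodality gate on the dip p-value.
#' @param min_latencies minimum matched latencies per pair.
#' @param gate_order `"gate_first"` or `"threshold_first"`.
#' @param dip_boot Monte-Carlo replicates per dip test.
#' @return object of class `connectivity_graph`: `edges` (data.frame source,
#'   target, sttc, mean_latency_ms, fwhm_ms, dip_p), `nodes` (data.frame
#'   unit_id, x, y, d_in, d_out, class), `largest_component`,
#'   `second_component`, `edge_density`, `n_bimodal_excluded`, and the
#'   parameters used.
#' @export
build_graph <- function(trains, sttc_threshold = 0.35, delta_t_ms = 20,
                        class_threshold = 0.8, fwhm_max_ms = 15,
                        dip_alpha = 0.1, min_latencies = 10,
                        gate_order = c("gate_first", "threshold_first"),
                        dip_boot = 2000) {
  gate_order <- match.arg(gate_order)
  ids <- trains$unit_ids
  n <- length(ids)
  if (n < 2L) stopf("need at least 2 units")
  sttc <- sttc_matrix(trains, delta_t_ms = delta_t_ms)
  edges <- list()
  n_bimodal <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sttc[i, j]
      if (is.na(s)) next
      if (gate_order == "threshold_first" && s < sttc_threshold) next
      pl <- pair_latencies(trains$spikes[[i]], trains$spikes[[j]],
                           window_ms = delta_t_ms, min_latencies = min_latencies,
                           dip_alpha = dip_alpha, dip_boot = dip_boot)
      if (!pl$connectable) next
      if (!pl$unimodal) {
        n_bimodal <- n_bimodal + 1L
        next
      }
      if (pl$fwhm > fwhm_max_ms) next
      if (s < sttc_threshold) next
      # positive mean latency: j lags i, so the edge points i -> j
      fwd <- pl$mean_latency >= 0
      edges[[length(edges) + 1L]] <- data.frame(
        source = if (fwd) ids[i] else ids[j],
        target = if (fwd) ids[j] else ids[i],
        sttc = s, mean_latency_ms = abs(pl$mean_latency),
        fwhm_ms = pl$fwhm, dip_p = pl$dip_p, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0), sttc = numeric(0),
               mean_latency_ms = numeric(0), fwhm_ms = numeric(0),
               dip_p = numeric(0), stringsAsFactors = FALSE)
  graph_from_edges(trains, edges, class_threshold = class_threshold,
                   n_bimodal_excluded = n_bimodal,
                   params = list(sttc_threshold = sttc_threshold,
                                 delta_t_ms = delta_t_ms,
                                 class_threshold = class_threshold,
                                 fwhm_max_ms = fwhm_max_ms,
                                 dip_alpha = dip_alpha,
                                 min_latencies = min_latencies,
                                 gate_order = gate_order))
}

# Assemble node table, classes and components from an edge list.
graph_from_edges <- function(trains, edges, class_threshold = 0.8,
                             n_bimodal_excluded = NA_integer_, params = list()) {
  ids <- trains$unit_ids
  n <- length(ids)
  d_out <- table(factor(edges$source, levels = ids))
  d_in <- table(factor(edges$target, levels = ids))
  d_out <- as.integer(d_out); d_in <- as.integer(d_in)
  imb <- ifelse(d_in + d_out > 0, (d_out - d_in) / (d_out + d_in), 0)
  cls <- ifelse(imb > class_threshold, "sender",
                ifelse(-imb > class_threshold, "receiver", "broker"))
  nodes <- data.frame(unit_id = ids,
                      x = if (!is.null(trains$positions)) trains$positions[, "x"] else NA_real_,
                      y = if (!is.null(trains$positions)) trains$positions[, "y"] else NA_real_,
                      d_in = d_in, d_out = d_out, class = cls,
                      row.names = NULL, stringsAsFactors = FALSE)
  comp <- list(largest = character(0), second = character(0))
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                       directed = FALSE, vertices = ids)
    cm <- igraph::components(g)
    ord <- order(cm$csize, decreasing = TRUE)
    comp$largest <- ids[cm$membership == ord[1]]
    if (length(ord) > 1L) comp$second <- ids[cm$membership == ord[2]]
  }
  structure(list(edges = edges, nodes = nodes,
                 largest_component = comp$largest,
                 second_component = comp$second,
                 edge_density = nrow(edges) / (n * (n - 1) / 2),
                 n_bimodal_excluded = n_bimodal_excluded,
                 params = params),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf(paste0("connectivity_graph: %d nodes, %d directed edges ",
                     "(density %.3f)\n"),
              nrow(x$nodes), nrow(x$edges), x$edge_density))
  cat(sprintf("  classes: %d sender / %d broker / %d receiver; largest component %d nodes\n",
              sum(x$nodes$class == "sender"), sum(x$nodes$class == "broker"),
              sum(x$nodes$class == "receiver"), length(x$largest_component)))
  invisible(x)
}

#' Write a connectivity graph as edge/node CSV tables
#' @param graph a `connectivity_graph`.
#' @param edge_path,node_path output files.
#' @export
write_graph_tables <- function(graph, edge_path, node_path) {
  utils::write.csv(graph$edges, edge_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(graph$nodes, node_path, row.names = FALSE, quote = FALSE)
  invisible(c(edge_path, node_path))
}

# --- null models -------------------------------------------------------------

#' Surrogate null models for edge strength and node classes
#'
#' `mode = "burst_shuffle"` permutes the unit labels of spikes within each
#' burst (and, by default, within each inter-burst gap), preserving the 1 ms
#' population spike count vector exactly, then recomputes the pairwise STTC
#' distribution; the fraction of null STTC values below `sttc_threshold`
#' estimates how well the threshold suppresses spurious edges.
#' `mode = "edge_swap"` rewires the built graph's undirected topology by
#' degree-preserving double edge swaps (`swap_factor` times as many swaps as
#' edges), reassigns each edge's direction uniformly at random, and reports
#' sender/receiver counts per replicate.
#'
#' @param trains a [spike_train_set] (burst_shuffle).
#' @param catalog a [detect_bursts] catalog with >= 1 burst (burst_shuffle).
#' @param graph a [build_graph] result (edge_swap).
#' @param mode `"burst_shuffle"` or `"edge_swap"`.
#' @param n_reps surrogate replicates (>= 1).
#' @param delta_t_ms,sttc_threshold STTC parameters (burst_shuffle).
#' @param shuffle_gaps also permute labels between bursts (burst_shuffle).
#' @param class_threshold node-class threshold (edge_swap).
#' @param swap_factor double-swaps per edge (edge_swap).
#' @param seed mandatory RNG seed.
#' @return for burst_shuffle: list with `null_sttc` (vector over all pairs
#'   and replicates), `quantiles`, `frac_below_threshold`; for edge_swap:
#'   list with `sender_counts`, `receiver_counts`, `broker_counts` per
#'   replicate.
#' @export
null_threshold <- function(trains = NULL, catalog = NULL, graph = NULL,
                           mode = c("burst_shuffle", "edge_swap"),
                           n_reps = 20, delta_t_ms = 20, sttc_threshold = 0.35,
                           shuffle_gaps = TRUE, class_threshold = 0.8,
                           swap_factor = 10, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stopf("'seed' is mandatory")
  if (!is_count(n_reps)) stopf("'n_reps' must be a positive integer")
  if (mode == "burst_shuffle") {
    if (is.null(trains)) stopf("burst_shuffle requires 'trains'")
    if (is.null(catalog) || nrow(catalog) < 1L)
      stopf("burst_shuffle requires a catalog with at least one burst")
    with_seed(seed, {
      vals <- unlist(lapply(seq_len(n_reps), function(r) {
        sh <- shuffle_unit_labels(trains, catalog, shuffle_gaps = shuffle_gaps)
        m <- sttc_matrix(sh, delta_t_ms = delta_t_ms)
        m[upper.tri(m)]
      }))
      vals <- vals[!is.na(vals)]
      list(mode = "burst_shuffle", null_sttc = vals,
           quantiles = stats::quantile(vals, c(0.5, 0.9, 0.95, 0.99)),
           frac_below_threshold = mean(vals < sttc_threshold),
           sttc_threshold = sttc_threshold, n_reps = n_reps, seed = seed)
    })
  } else {
    if (is.null(graph)) stopf("edge_swap requires 'graph'")
    if (!nrow(graph$edges)) stopf("edge_swap requires a graph with edges")
    ids <- graph$nodes$unit_id
    g0 <- igraph::graph_from_data_frame(graph$edges[, c("source", "target")],
                                        directed = FALSE, vertices = ids)
    n_e <- igraph::ecount(g0)
    with_seed(seed, {
      reps <- lapply(seq_len(n_reps), function(r) {
        g1 <- igraph::rewire(g0, igraph::keeping_degseq(niter = swap_factor * n_e))
        el <- igraph::as_edgelist(g1)
        flip <- stats::runif(nrow(el)) < 0.5
        src <- ifelse(flip, el[, 2], el[, 1])
        tgt <- ifelse(flip, el[, 1], el[, 2])
        d_out <- as.integer(table(factor(src, levels = ids)))
        d_in <- as.integer(table(factor(tgt, levels = ids)))
        imb <- ifelse(d_in + d_out > 0, (d_out - d_in) / (d_out + d_in), 0)
        c(sender = sum(imb > class_threshold),
          receiver = sum(-imb > class_threshold),
          broker = sum(abs(imb) <= class_threshold))
      })
      reps <- do.call(rbind, reps)
      list(mode = "edge_swap",
           sender_counts = reps[, "sender"],
           receiver_counts = reps[, "receiver"],
           broker_counts = reps[, "broker"],
           n_reps = n_reps, seed = seed)
    })
  }
}

#' Permute unit labels of spikes within bursts (and gaps)
#'
#' Every spike keeps its time; the unit labels of all spikes falling inside
#' one burst (or one inter-burst gap, when `shuffle_gaps`) are permuted
#' jointly, so the 1 ms-binned population spike count vector is preserved
#' exactly while pairwise timing structure is destroyed.
#'
#' @param trains a [spike_train_set].
#' @param catalog a [detect_bursts] catalog.
#' @param shuffle_gaps permute the inter-burst segments too.
#' @return a new `spike_train_set` (duplicate spike times within 0.1 ms per
#'   unit are jittered off by deletion-free refractory handling: labels are a
#'   permutation, so per-unit times may collide; collisions are kept).
#' @export
shuffle_unit_labels <- function(trains, catalog, shuffle_gaps = TRUE) {
  tab <- as.data.frame(trains)[, c("unit_id", "time_s")]
  bounds <- sort(unique(c(0, catalog$starts, catalog$stops, trains$duration)))
  seg <- findInterval(tab$time_s, bounds, rightmost.closed = TRUE)
  in_burst <- rep(FALSE, length(bounds))
  for (i in seq_len(nrow(catalog))) {
    k <- findInterval((catalog$starts[i] + catalog$stops[i]) / 2, bounds)
    in_burst[k] <- TRUE
  }
  for (s in unique(seg)) {
    if (!in_burst[s] && !shuffle_gaps) next
    idx <- which(seg == s)
    tab$unit_id[idx] <- sample(tab$unit_id[idx])
  }
  spikes <- split(tab$time_s, factor(tab$unit_id, levels = trains$unit_ids))
  spikes <- lapply(spikes, function(s) unique(sort(s)))  # drop exact-tie collisions
  spike_train_set(spikes, positions = trains$positions,
                  duration = trains$duration,
                  meta = c(trains$meta, list(surrogate = "burst_shuffle")),
                  sort_times = TRUE)
}
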