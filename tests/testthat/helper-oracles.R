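# Independent oracles, deliberately written with different algorithms than
# the package implementations.

# Brute-force STTC: tiling fraction via explicit interval merging in a loop,
# coincidence fraction via an O(n^2) all-pairs distance scan.
sttc_oracle <- function(a, b, delta_t_ms, duration_s) {
  dt <- delta_t_ms / 1000
  tile <- function(s) {
    iv <- cbind(pmax(s - dt, 0), pmin(s + dt, duration_s))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    total <- 0
    cur <- iv[1, ]
    if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
      if (iv[i, 1] <= cur[2]) {
        cur[2] <- max(cur[2], iv[i, 2])
      } else {
        total <- total + (cur[2] - cur[1])
        cur <- iv[i, ]
      }
    }
    (total + cur[2] - cur[1]) / duration_s
  }
  prop <- function(s, o) mean(vapply(s, function(t) any(abs(o - t) <= dt), logical(1)))
  ta <- tile(a); tb <- tile(b)
  pa <- prop(a, b); pb <- prop(b, a)
  term <- function(p, t) if (1 - p * t == 0) 0 else (p - t) / (1 - p * t)
  0.5 * (term(pa, tb) + term(pb, ta))
}

# Quick Poisson spike train on [0, duration].
poisson_train <- function(rate_hz, duration_s) {
  n <- stats::rpois(1, rate_hz * duration_s)
  sort(stats::runif(n, 0, duration_s))
}

# Cached study-scale simulation with embedded edges, shared across test
# files (helpers are sourced once per session).
.fixture_cache <- new.env(parent = emptyenv())

recovery_fixture <- function() {
  if (is.null(.fixture_cache$recovery)) {
    set.seed(404)
    edges <- sample_edges(50, 10, transmission_p = 0.6,
                          latency_mean_ms = 5, latency_sd_ms = 2)
    sim <- simulate_spike_network(n_units = 50, duration_s = 300,
                                  baseline_rate_hz = 2, edges = edges,
                                  seed = 42)
    .fixture_cache$recovery <- list(sim = sim, edges = edges)
  }
  .fixture_cache$recovery
}

recovery_graph <- function() {
  if (is.null(.fixture_cache$recovery_graph)) {
    fx <- recovery_fixture()
    .fixture_cache$recovery_graph <- build_graph(fx$sim$trains)
  }
  .fixture_cache$recovery_graph
}

edge_key <- function(e) paste(e$source, e$target, sep = "->")
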