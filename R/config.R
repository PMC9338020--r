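# Run configuration: every tunable of the analysis with its default value.

#' Default analysis configuration
#'
#' Returns the nested list of every numeric parameter used by the pipeline,
#' at its default value. Any subset can be overridden via `...` (named lists
#' are merged recursively). The configuration round-trips through YAML
#' ([write_config] / [read_config]) without loss.
#'
#' @param ... named overrides, e.g. `analysis_config(connectivity = list(sttc_threshold = 0.4))`.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    curation = list(isi_violation_max = 0.3, rate_min_hz = 0.05, snr_min = 5,
                    refractory_ms = 1.5),
    isi = list(min_spikes = 30, window_s = 180, isi_range_ms = c(8, 100),
               bin_rule_divisor = 15, r2_threshold = 0.9,
               apply_range_filter = TRUE),
    bursts = list(peak_factor = 2.0, min_separation_s = 1.0,
                  edge_attenuation = 0.9, edge_search_s = 2,
                  similarity_window_ms = c(-100, 350),
                  grid_start_ms = c(-200, 0, 10), grid_stop_ms = c(0, 500, 10)),
    connectivity = list(delta_t_ms = 20, sttc_threshold = 0.35,
                        latency_window_ms = 20, latency_bin_ms = 1,
                        fwhm_max_ms = 15, dip_alpha = 0.1, dip_boot = 2000,
                        min_latencies = 10, class_threshold = 0.8,
                        gate_order = "gate_first",
                        edge_bin = 0.05, edge_range = c(0.35, 1.0),
                        swap_factor = 10),
    lfp = list(lowpass_hz = 500, butter_order = 4, fs_out = 1000,
               bands = list(delta = c(0.5, 4), theta = c(4, 8),
                            alpha = c(8, 13), beta = c(13, 30),
                            gamma = c(30, 50)),
               amplitude_floor_uv = 10, corr_threshold = 0.2,
               peak_min_uv = 10, peak_min_dist_ms = 100,
               average_window_ms = 500, spread_window_ms = c(-250, 500),
               envelope_k = c(1, 1.5, 2)),
    coherence = list(window_s = 0.5, overlap = 0.25, percentile = 90,
                     min_connections = 200, k_range = c(2, 6)),
    phase_lock = list(n_min = 30, alpha = 0.05),
    seed = 1L
  )
  override <- list(...)
  cfg <- merge_config(cfg, override)
  class(cfg) <- c("analysis_config", "list")
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) && !is.null(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Write a configuration to YAML
#' @param cfg an `analysis_config`.
#' @param path output file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' Values absent from the file fall back to [analysis_config] defaults.
#' @param path YAML file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  cfg <- merge_config(unclass(analysis_config()), raw)
  class(cfg) <- c("analysis_config", "list")
  cfg
}
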