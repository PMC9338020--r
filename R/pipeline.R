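# Configuration-driven orchestration of the full analysis.

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- input (load from disk or
#' simulate), curation, ISI statistics, population rate + bursts,
#' connectivity (graph, null model, edge-distribution fits), and when LFP
#' data is present the theta stages (band filter, correlation map, phase
#' spread, imaginary coherence, phase locking) -- writing each stage's
#' result tables to `output_dir` and returning a manifest. Reruns with the
#' same configuration and seed produce byte-identical result tables.
#'
#' @param config an [analysis_config], a path to a YAML config, or a list of
#'   overrides. Input selection: `config$input$spike_csv` (path) or
#'   `config$input$synthetic` (list of [simulate_spike_network] arguments);
#'   optional `config$input$lfp` (path for [load_lfp]) or
#'   `config$input$synthetic_lfp` (list of [simulate_lfp] arguments).
#' @param output_dir directory for result tables (created if needed).
#' @param seed overrides `config$seed`.
#' @param quality optional unit-quality table for curation (default: derived
#'   from the spike trains via [unit_quality]).
#' @return object of class `run_manifest`: config snapshot, seed, stage
#'   list, output paths with md5 hashes.
#' @export
run_pipeline <- function(config = analysis_config(), output_dir, seed = NULL,
                         quality = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "analysis_config"))
    config <- do.call(analysis_config, config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) stopf("config is missing the required field 'seed'")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  stages <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(output_dir, paste0(name, ".csv"))
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[[length(paths) + 1L]] <<- p
    p
  }
  emit_json <- function(x, name) {
    p <- file.path(output_dir, paste0(name, ".json"))
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = 10, pretty = TRUE)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  # --- input stage -----------------------------------------------------------
  inp <- config$input
  if (is.null(inp)) stopf("config is missing the required field 'input'")
  ground_truth <- NULL
  if (!is.null(inp$spike_csv)) {
    trains <- load_spike_trains(inp$spike_csv, format = "csv")
  } else if (!is.null(inp$synthetic)) {
    args <- inp$synthetic
    args$seed <- config$seed
    sim <- do.call(simulate_spike_network, args)
    trains <- sim$trains
    ground_truth <- sim$ground_truth
    emit_json(list(edges = ground_truth$edges,
                   burst_times = ground_truth$burst_times), "ground_truth")
  } else stopf("config$input needs either 'spike_csv' or 'synthetic'")
  stages <- c(stages, "input")

  lfp <- NULL
  if (!is.null(inp$lfp)) {
    lfp <- load_lfp(inp$lfp)
  } else if (!is.null(inp$synthetic_lfp)) {
    args <- inp$synthetic_lfp
    args$seed <- config$seed + 1L
    if (is.null(args$burst_times) && !is.null(ground_truth))
      args$burst_times <- ground_truth$burst_times
    lfp <- do.call(simulate_lfp, args)
  }

  # --- curation --------------------------------------------------------------
  cur <- config$curation
  if (is.null(quality))
    quality <- unit_quality(trains, refractory_ms = cur$refractory_ms)
  trains <- curate_units(trains, quality,
                         isi_violation_max = cur$isi_violation_max,
                         rate_min = cur$rate_min_hz, snr_min = cur$snr_min)
  emit_csv(summary(trains), "units")
  stages <- c(stages, "curation")

  # --- ISI statistics --------------------------------------------------------
  isi_cfg <- config$isi
  isi <- compute_isi_stats(trains, min_spikes = isi_cfg$min_spikes,
                           window_s = isi_cfg$window_s,
                           isi_range_ms = isi_cfg$isi_range_ms,
                           apply_range_filter = isi_cfg$apply_range_filter,
                           r2_threshold = isi_cfg$r2_threshold)
  emit_csv(isi, "isi_stats")
  stages <- c(stages, "isi")

  # --- population rate and bursts -------------------------------------------
  b <- config$bursts
  pr <- population_rate(trains, mode = "mua_smooth")
  catalog <- detect_bursts(pr, peak_factor = b$peak_factor,
                           min_separation_s = b$min_separation_s,
                           edge_attenuation = b$edge_attenuation,
                           edge_search_s = b$edge_search_s)
  emit_csv(as.data.frame(catalog), "bursts")
  if (nrow(catalog) >= 2L) {
    bs <- burst_similarity(trains, catalog, window_ms = b$similarity_window_ms)
    emit_json(list(mean_over_pairs = bs$mean_over_pairs,
                   window_ms = bs$window_ms, n_bursts = nrow(bs$matrix)),
              "burst_similarity")
  }
  stages <- c(stages, "bursts")

  # --- connectivity ----------------------------------------------------------
  cc <- config$connectivity
  graph <- build_graph(trains, sttc_threshold = cc$sttc_threshold,
                       delta_t_ms = cc$delta_t_ms,
                       class_threshold = cc$class_threshold,
                       fwhm_max_ms = cc$fwhm_max_ms,
                       dip_alpha = cc$dip_alpha,
                       min_latencies = cc$min_latencies,
                       gate_order = cc$gate_order,
                       dip_boot = cc$dip_boot)
  emit_csv(graph$edges, "edges")
  emit_csv(graph$nodes, "nodes")
  emit_json(list(edge_density = graph$edge_density,
                 largest_component = graph$largest_component,
                 second_component = graph$second_component,
                 n_bimodal_excluded = graph$n_bimodal_excluded,
                 class_fractions = as.list(table(graph$nodes$class) / nrow(graph$nodes))),
            "graph_summary")
  if (nrow(catalog) >= 1L) {
    nul <- null_threshold(trains = trains, catalog = catalog,
                          mode = "burst_shuffle", n_reps = 5,
                          delta_t_ms = cc$delta_t_ms,
                          sttc_threshold = cc$sttc_threshold,
                          seed = config$seed + 2L)
    emit_json(list(frac_below_threshold = nul$frac_below_threshold,
                   quantiles = as.list(nul$quantiles)), "null_threshold")
  }
  if (nrow(graph$edges) >= 10L) {
    ef <- fit_edge_distributions(graph$edges$sttc, bin = cc$edge_bin,
                                 range = cc$edge_range)
    emit_json(list(best = ef$best,
                   aic = lapply(ef$fits, function(f)
                     if (isTRUE(f$converged)) f$aic else NA)), "edge_fits")
  }
  stages <- c(stages, "connectivity")

  # --- LFP stages ------------------------------------------------------------
  theta <- NULL
  if (!is.null(lfp)) {
    lf <- config$lfp
    if (lfp$fs >= 2000) lfp <- extract_lfp(lfp, cutoff = lf$lowpass_hz,
                                           order = lf$butter_order,
                                           fs_out = lf$fs_out)
    theta <- band_filter(lfp, "theta")
    tm <- theta_correlation_map(theta, amplitude_floor_uv = lf$amplitude_floor_uv,
                                corr_threshold = lf$corr_threshold)
    emit_csv(data.frame(electrode = seq_along(tm$correlation),
                        correlation = tm$correlation, lag_ms = tm$lag_ms,
                        phase_offset = tm$phase_offset), "theta_map")
    if (nrow(catalog) >= 5L) {
      ps <- phase_spread(theta, catalog, window_ms = lf$spread_window_ms)
      emit_csv(data.frame(electrode = seq_len(nrow(ps$spread)),
                          min_spread_time_ms = ps$min_spread_time_ms),
               "phase_spread")
      es <- envelope_threshold_stats(theta, catalog = catalog,
                                     k_values = lf$envelope_k)
      emit_csv(es$fractions, "envelope_stats")
    }
    co <- config$coherence
    cm <- imaginary_coherence(theta, window_s = co$window_s,
                              overlap = co$overlap)
    emit_csv(data.frame(electrode = seq_along(cm$regional_strength),
                        regional_strength = cm$regional_strength),
             "imaginary_coherence")
    pl <- phase_locking(trains, theta, n_min = config$phase_lock$n_min,
                        alpha = config$phase_lock$alpha)
    emit_csv(pl$table, "phase_locking")
    emit_json(list(locked_fraction = pl$locked_fraction), "phase_lock_summary")
    stages <- c(stages, "lfp")
  }

  cfg_path <- file.path(output_dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(package_version = as.character(utils::packageVersion("orgMEA")),
                   seed = config$seed, stages = stages,
                   outputs = stats::setNames(as.list(unname(tools::md5sum(paths))),
                                             basename(paths)),
                   config_path = cfg_path, output_dir = output_dir)
  class(manifest) <- "run_manifest"
  emit_json(manifest[c("package_version", "seed", "stages", "outputs")],
            "manifest")
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: seed %d, stages: %s\n  %d output files in %s\n",
              x$seed, paste(x$stages, collapse = " -> "),
              length(x$outputs), x$output_dir))
  invisible(x)
}

#' Contrast two pipeline runs (e.g. control vs drug)
#'
#' Assembles the condition contrasts, each delegated to its module: the KS
#' test between ISI CV distributions and between pooled ISIs, the
#' fractional-change grid of burst similarity, shared/silenced/induced edge
#' sets with the edge-density change, and the gamma-fit fractional
#' difference when both conditions have enough edges.
#'
#' @param trains_a,trains_b curated spike trains per condition (shared unit
#'   identity space).
#' @param config an [analysis_config].
#' @param graph_a,graph_b optional prebuilt graphs (rebuilt when `NULL`).
#' @param catalog_a,catalog_b optional prebuilt burst catalogs.
#' @return list of class `condition_contrast` with elements `isi_cv_ks`,
#'   `isi_pooled_ks`, `cv_shift`, `burst_grid`, `edge_sets`,
#'   `edge_density_change_pct`, `spike_count_change_pct`, `gamma_fractional`.
#' @export
compare_conditions <- function(trains_a, trains_b, config = analysis_config(),
                               graph_a = NULL, graph_b = NULL,
                               catalog_a = NULL, catalog_b = NULL) {
  if (!identical(sort(trains_a$unit_ids), sort(trains_b$unit_ids))) {
    extra <- c(setdiff(trains_a$unit_ids, trains_b$unit_ids),
               setdiff(trains_b$unit_ids, trains_a$unit_ids))
    stopf("unit identities differ between conditions: %s",
          paste(extra, collapse = ", "))
  }
  isi_cfg <- config$isi
  isi_a <- compute_isi_stats(trains_a, min_spikes = isi_cfg$min_spikes,
                             window_s = isi_cfg$window_s,
                             isi_range_ms = isi_cfg$isi_range_ms, fit = FALSE)
  isi_b <- compute_isi_stats(trains_b, min_spikes = isi_cfg$min_spikes,
                             window_s = isi_cfg$window_s,
                             isi_range_ms = isi_cfg$isi_range_ms, fit = FALSE)
  out <- list()
  out$isi_cv_ks <- if (nrow(isi_a) >= 2 && nrow(isi_b) >= 2)
    compare_isi_distributions(isi_a$cv, isi_b$cv) else NULL
  pooled_a <- unlist(lapply(trains_a$spikes, diff))
  pooled_b <- unlist(lapply(trains_b$spikes, diff))
  out$isi_pooled_ks <- compare_isi_distributions(pooled_a, pooled_b)
  out$cv_shift <- if (nrow(isi_a) && nrow(isi_b))
    mean(isi_b$cv) - mean(isi_a$cv) else NA_real_
  out$spike_count_change_pct <- spike_count_change(trains_a, trains_b)
  b <- config$bursts
  if (is.null(catalog_a))
    catalog_a <- detect_bursts(population_rate(trains_a, "mua_smooth"),
                               b$peak_factor, b$min_separation_s,
                               b$edge_attenuation)
  if (is.null(catalog_b))
    catalog_b <- detect_bursts(population_rate(trains_b, "mua_smooth"),
                               b$peak_factor, b$min_separation_s,
                               b$edge_attenuation)
  out$burst_grid <- if (nrow(catalog_a) >= 2 && nrow(catalog_b) >= 2)
    fractional_change_grid(trains_a, catalog_a, trains_b, catalog_b,
                           start_range_ms = b$grid_start_ms,
                           stop_range_ms = b$grid_stop_ms) else NULL
  cc <- config$connectivity
  if (is.null(graph_a))
    graph_a <- build_graph(trains_a, sttc_threshold = cc$sttc_threshold,
                           delta_t_ms = cc$delta_t_ms, dip_boot = cc$dip_boot)
  if (is.null(graph_b))
    graph_b <- build_graph(trains_b, sttc_threshold = cc$sttc_threshold,
                           delta_t_ms = cc$delta_t_ms, dip_boot = cc$dip_boot)
  out$edge_sets <- compare_edge_sets(graph_a, graph_b)
  out$edge_density_change_pct <- out$edge_sets$edge_density_change
  out$gamma_fractional <- if (nrow(graph_a$edges) >= 10 && nrow(graph_b$edges) >= 10) {
    fa <- fit_edge_distributions(graph_a$edges$sttc, bin = cc$edge_bin,
                                 range = cc$edge_range)
    fb <- fit_edge_distributions(graph_b$edges$sttc, bin = cc$edge_bin,
                                 range = cc$edge_range)
    tryCatch(edge_fit_fractional_difference(fa, fb), error = function(e) NULL)
  } else NULL
  class(out) <- "condition_contrast"
  out
}

#' @export
print.condition_contrast <- function(x, ...) {
  cat("condition_contrast:\n")
  if (!is.null(x$isi_cv_ks))
    cat(sprintf("  ISI CV KS: D = %.3f, p = %.3g (mean CV shift %+.3f)\n",
                x$isi_cv_ks$ks_statistic, x$isi_cv_ks$p_value, x$cv_shift))
  cat(sprintf("  spike count change: %+.1f%%\n", -x$spike_count_change_pct))
  if (!is.null(x$burst_grid))
    cat(sprintf("  burst-similarity grid mean score: %+.3f\n",
                x$burst_grid$mean_score))
  if (!is.null(x$edge_sets))
    cat(sprintf("  edges: %.0f%% shared / %.0f%% silenced / %.0f%% induced; density change %+.1f%%\n",
                100 * x$edge_sets$fractions["shared"],
                100 * x$edge_sets$fractions["silenced"],
                100 * x$edge_sets$fractions["induced"],
                x$edge_density_change_pct))
  invisible(x)
}
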