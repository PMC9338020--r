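# Spike-train container, readers/writers and unit curation.

#' Construct a spike train set
#'
#' The central spiking container of the package: one sorted spike-time vector
#' per unit, plus the electrode position each unit was assigned to on the
#' array. Times are seconds (float) everywhere; sample indices appear only at
#' I/O boundaries.
#'
#' @param spikes named list of numeric vectors, one per unit, spike times in
#'   seconds. Names are the unit ids.
#' @param positions numeric matrix (or data.frame) with one row per unit and
#'   columns `x`, `y` in micrometres (origin at the array corner, x along the
#'   long 3.85 mm axis). May be `NULL` if geometry is unknown.
#' @param duration recording duration in seconds; inferred as the maximum
#'   spike time when `NULL`.
#' @param meta free-form provenance list.
#' @param sort_times sort each unit's spike times instead of erroring on
#'   unordered input.
#' @return object of class `spike_train_set`.
#' @examples
#' sts <- spike_train_set(list(u1 = c(0.1, 0.25), u2 = 0.3))
#' n_units(sts)
#' @export
spike_train_set <- function(spikes, positions = NULL, duration = NULL,
                            meta = list(), sort_times = FALSE) {
  if (!is.list(spikes) || length(spikes) == 0L)
    stopf("'spikes' must be a nonempty list of numeric spike-time vectors")
  if (is.null(names(spikes)) || anyDuplicated(names(spikes)))
    stopf("unit ids (names of 'spikes') must be present and unique")
  spikes <- lapply(spikes, as.numeric)
  if (sort_times) spikes <- lapply(spikes, sort)
  for (id in names(spikes)) {
    s <- spikes[[id]]
    if (length(s) && any(!is.finite(s))) stopf("unit %s: non-finite spike times", id)
    if (length(s) && any(s < 0)) stopf("unit %s: negative spike times", id)
    if (is.unsorted(s, strictly = TRUE) && length(s) > 1L)
      stopf("unit %s: spike times must be strictly increasing (use sort_times = TRUE)", id)
  }
  if (is.null(duration)) {
    duration <- max(c(0, unlist(spikes, use.names = FALSE)))
  }
  if (!is_scalar_num(duration) || duration <= 0)
    stopf("'duration' must be a positive scalar")
  too_late <- vapply(spikes, function(s) length(s) > 0 && max(s) > duration, logical(1))
  if (any(too_late))
    stopf("spike times exceed duration for unit(s): %s",
          paste(names(spikes)[too_late], collapse = ", "))
  if (!is.null(positions)) {
    positions <- as.matrix(positions[, c("x", "y"), drop = FALSE])
    storage.mode(positions) <- "double"
    if (nrow(positions) != length(spikes))
      stopf("'positions' must have one row per unit (%d != %d)",
            nrow(positions), length(spikes))
    if (any(!is.finite(positions))) stopf("unit positions must be finite")
    rownames(positions) <- names(spikes)
  }
  structure(list(unit_ids = names(spikes), spikes = spikes,
                 positions = positions, duration = duration, meta = meta),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("spike_train_set: %d units, %.1f s, %d spikes total\n",
              length(x$spikes), x$duration,
              sum(lengths(x$spikes))))
  invisible(x)
}

#' @export
summary.spike_train_set <- function(object, ...) {
  n <- lengths(object$spikes)
  out <- data.frame(unit_id = object$unit_ids,
                    n_spikes = as.integer(n),
                    firing_rate_hz = n / object$duration,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(object$positions)) {
    out$x_um <- object$positions[, "x"]
    out$y_um <- object$positions[, "y"]
  }
  out
}

#' Number of units in a spike train set
#' @param x a `spike_train_set`.
#' @export
n_units <- function(x) length(x$spikes)

#' Convert a spike train set to a long data frame
#'
#' @param x a `spike_train_set`.
#' @param ... unused.
#' @return data.frame with columns `unit_id`, `time_s` and, when geometry is
#'   available, `x_um`, `y_um`.
#' @export
as.data.frame.spike_train_set <- function(x, ...) {
  n <- lengths(x$spikes)
  out <- data.frame(unit_id = rep(x$unit_ids, n),
                    time_s = unlist(x$spikes, use.names = FALSE),
                    stringsAsFactors = FALSE)
  if (!is.null(x$positions)) {
    out$x_um <- rep(x$positions[, "x"], n)
    out$y_um <- rep(x$positions[, "y"], n)
  }
  out
}

#' Subset a spike train set by unit
#' @param x a `spike_train_set`.
#' @param unit_ids character vector of unit ids to keep.
#' @export
subset_units <- function(x, unit_ids) {
  unit_ids <- as.character(unit_ids)
  missing <- setdiff(unit_ids, x$unit_ids)
  if (length(missing))
    stopf("unknown unit id(s): %s", paste(missing, collapse = ", "))
  spike_train_set(x$spikes[unit_ids],
                  positions = if (!is.null(x$positions)) x$positions[unit_ids, , drop = FALSE],
                  duration = x$duration, meta = x$meta)
}

#' Load spike trains from disk
#'
#' Reads either a flat CSV spike table (columns `unit_id`, `time_s` and
#' optionally `x_um`, `y_um`) or a Kilosort-style directory holding the text
#' export of the sorter's arrays: `spike_times.txt` (sample indices, one per
#' line), `spike_clusters.txt` (cluster id per spike), `channel_positions.txt`
#' (x y per channel, micrometres) and `params.txt` containing
#' `sample_rate=<Hz>`. Sample indices are converted to seconds; unordered CSV
#' rows are accepted and stored sorted.
#'
#' @param path file (csv) or directory (kilosort_dir).
#' @param format `"csv"` or `"kilosort_dir"`.
#' @param duration recording duration in seconds; inferred from the data when
#'   `NULL`.
#' @return a [spike_train_set].
#' @export
load_spike_trains <- function(path, format = c("csv", "kilosort_dir"),
                              duration = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) stopf("spike table not found: %s", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("unit_id", "time_s") %in% names(tab)))
      stopf("csv %s must have columns unit_id, time_s", path)
    spikes <- split(tab$time_s, as.character(tab$unit_id))
    positions <- NULL
    if (all(c("x_um", "y_um") %in% names(tab))) {
      pos <- unique(tab[, c("unit_id", "x_um", "y_um")])
      pos <- pos[match(names(spikes), as.character(pos$unit_id)), ]
      positions <- cbind(x = pos$x_um, y = pos$y_um)
    }
    spike_train_set(spikes, positions = positions, duration = duration,
                    meta = list(source = path, format = "csv"),
                    sort_times = TRUE)
  } else {
    req <- c("spike_times.txt", "spike_clusters.txt", "params.txt")
    for (f in req) {
      if (!file.exists(file.path(path, f)))
        stopf("kilosort-style directory %s is missing %s", path, f)
    }
    params <- readLines(file.path(path, "params.txt"), warn = FALSE)
    fs_line <- grep("^\\s*sample_rate\\s*=", params, value = TRUE)
    if (!length(fs_line)) stopf("params.txt lacks a sample_rate entry")
    fs <- as.numeric(sub(".*=", "", fs_line[1]))
    if (!is_scalar_num(fs) || fs <= 0) stopf("invalid sample_rate in params.txt")
    st <- scan(file.path(path, "spike_times.txt"), quiet = TRUE)
    cl <- scan(file.path(path, "spike_clusters.txt"), quiet = TRUE)
    if (length(st) != length(cl))
      stopf("spike_times and spike_clusters differ in length (%d vs %d)",
            length(st), length(cl))
    spikes <- split(st / fs, as.character(cl))
    positions <- NULL
    cp_file <- file.path(path, "channel_positions.txt")
    if (file.exists(cp_file)) {
      cp <- as.matrix(utils::read.table(cp_file))
      colnames(cp) <- c("x", "y")
      # units are placed at their primary channel when a cluster->channel map
      # (cluster_channels.txt: cluster id, channel index 1-based) is present
      cc_file <- file.path(path, "cluster_channels.txt")
      if (file.exists(cc_file)) {
        cc <- utils::read.table(cc_file)
        ch <- cc[[2]][match(names(spikes), as.character(cc[[1]]))]
        if (!anyNA(ch)) positions <- cp[ch, , drop = FALSE]
      }
    }
    spike_train_set(spikes, positions = positions, duration = duration,
                    meta = list(source = path, format = "kilosort_dir", fs = fs),
                    sort_times = TRUE)
  }
}

#' Write a spike train set to CSV
#'
#' Inverse of [load_spike_trains] for the CSV layout; times are written with
#' microsecond precision so a write/read round trip is lossless at 1 us.
#'
#' @param x a `spike_train_set`.
#' @param path output file.
#' @export
write_spike_trains <- function(x, path) {
  tab <- as.data.frame(x)
  tab$time_s <- sprintf("%.6f", tab$time_s)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- curation ----------------------------------------------------------------

#' Compute per-unit quality records from spike times
#'
#' The inter-spike-interval (ISI) violation fraction is the fraction of ISIs
#' shorter than `refractory_ms` (default 1.5 ms, an explicit package constant;
#' the refractory window is exposed rather than fixed because curation
#' pipelines differ on it). The signal-to-noise ratio cannot be derived from
#' spike times alone and must be supplied (per unit or scalar).
#'
#' @param trains a [spike_train_set].
#' @param snr numeric scalar or per-unit vector of waveform signal-to-noise
#'   ratios; defaults to `Inf` (no SNR information).
#' @param refractory_ms refractory window for the violation fraction.
#' @return data.frame with columns `unit_id`, `isi_violation_fraction`,
#'   `firing_rate`, `snr`.
#' @export
unit_quality <- function(trains, snr = Inf, refractory_ms = 1.5) {
  n <- lengths(trains$spikes)
  viol <- vapply(trains$spikes, function(s) {
    if (length(s) < 2L) return(0)
    mean(diff(s) < refractory_ms / 1000)
  }, numeric(1))
  snr <- rep_len(snr, length(n))
  data.frame(unit_id = trains$unit_ids,
             isi_violation_fraction = unname(viol),
             firing_rate = unname(n) / trains$duration,
             snr = snr, row.names = NULL, stringsAsFactors = FALSE)
}

#' Curate units by quality thresholds
#'
#' Applies the standard automatic post-sorting gates: a unit is removed when
#' its ISI violation fraction is strictly above `isi_violation_max`, its mean
#' firing rate strictly below `rate_min`, or its signal-to-noise ratio
#' strictly below `snr_min`; units exactly at a threshold are retained.
#' Idempotent: curating an already-curated set changes nothing.
#'
#' @param trains a [spike_train_set].
#' @param quality data.frame as returned by [unit_quality]; every unit must
#'   have a record.
#' @param isi_violation_max,rate_min,snr_min gate values.
#' @return curated `spike_train_set`; the removal log (unit id and reasons) is
#'   attached as attribute `"curation_log"`.
#' @export
curate_units <- function(trains, quality, isi_violation_max = 0.3,
                         rate_min = 0.05, snr_min = 5) {
  if (is.null(quality) || nrow(as.data.frame(quality)) == 0L)
    stopf("every unit needs a quality record; got an empty quality table")
  quality <- as.data.frame(quality)
  need <- c("unit_id", "isi_violation_fraction", "firing_rate", "snr")
  if (!all(need %in% names(quality)))
    stopf("quality table must have columns %s", paste(need, collapse = ", "))
  if (any(quality$isi_violation_fraction < 0) || any(quality$firing_rate < 0) ||
      any(quality$snr < 0))
    stopf("quality metrics must be non-negative")
  idx <- match(trains$unit_ids, as.character(quality$unit_id))
  if (anyNA(idx))
    stopf("no quality record for unit(s): %s",
          paste(trains$unit_ids[is.na(idx)], collapse = ", "))
  q <- quality[idx, ]
  fail_isi <- q$isi_violation_fraction > isi_violation_max
  fail_rate <- q$firing_rate < rate_min
  fail_snr <- q$snr < snr_min
  removed <- fail_isi | fail_rate | fail_snr
  log <- data.frame(unit_id = trains$unit_ids[removed],
                    isi_violation = fail_isi[removed],
                    low_rate = fail_rate[removed],
                    low_snr = fail_snr[removed],
                    row.names = NULL, stringsAsFactors = FALSE)
  keep <- trains$unit_ids[!removed]
  if (!length(keep)) stopf("curation removed every unit")
  out <- subset_units(trains, keep)
  attr(out, "curation_log") <- log
  out
}
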