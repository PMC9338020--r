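# LFP container and raw-binary I/O.

.lfp_bands <- c("raw", "lfp", "delta", "theta", "alpha", "beta", "gamma")

#' Construct an LFP set
#'
#' Extracellular voltage container: an electrodes x samples matrix in
#' microvolts with its sampling rate, electrode geometry and band label.
#'
#' @param data numeric matrix, electrodes in rows, samples in columns (uV).
#' @param fs sampling rate in Hz.
#' @param positions matrix/data.frame with columns `x`, `y` (um), one row per
#'   electrode.
#' @param band one of `"raw"`, `"lfp"`, `"delta"`, `"theta"`, `"alpha"`,
#'   `"beta"`, `"gamma"`.
#' @param t0 time of the first sample, seconds.
#' @return object of class `lfp_set`.
#' @export
lfp_set <- function(data, fs, positions = NULL, band = "raw", t0 = 0) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is_scalar_num(fs) || fs <= 0) stopf("'fs' must be a positive scalar (Hz)")
  band <- match.arg(band, .lfp_bands)
  if (!is.null(positions)) {
    positions <- as.matrix(as.data.frame(positions)[, c("x", "y")])
    storage.mode(positions) <- "double"
    if (nrow(positions) != nrow(data))
      stopf("positions has %d rows for %d electrodes", nrow(positions), nrow(data))
    if (any(!is.finite(positions))) stopf("electrode positions must be finite")
  }
  structure(list(data = data, fs = fs, positions = positions,
                 band = band, t0 = t0),
            class = "lfp_set")
}

#' @export
print.lfp_set <- function(x, ...) {
  cat(sprintf("lfp_set: %d electrodes x %d samples @ %g Hz (%.2f s), band '%s'\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$band))
  invisible(x)
}

#' Time axis of an LFP set
#' @param x an `lfp_set`.
#' @export
lfp_times <- function(x) x$t0 + (seq_len(ncol(x$data)) - 1L) / x$fs

#' Load an LFP matrix from raw binary with a JSON sidecar
#'
#' Reads little-endian `int16` or `float32` sample data stored
#' electrode-major (all samples of electrode 1, then electrode 2, ...), with
#' a sidecar file `<path>.json` describing the layout:
#' `{"n_electrodes", "n_samples", "dtype", "fs", "gain_uv", "band", "t0",
#' "positions": [[x, y], ...]}`. Integer samples are scaled by `gain_uv`
#' (uV per bit) to microvolts.
#'
#' @param path binary data file; `paste0(path, ".json")` must exist.
#' @param fs_in override the sidecar sampling rate (Hz), optional.
#' @param layout override the sidecar electrode-position table, optional.
#' @return an [lfp_set].
#' @export
load_lfp <- function(path, fs_in = NULL, layout = NULL) {
  if (!file.exists(path)) stopf("LFP data file not found: %s", path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stopf("sidecar metadata not found: %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("n_electrodes", "n_samples", "dtype")
  if (!all(need %in% names(meta)))
    stopf("sidecar %s must define %s", meta_path, paste(need, collapse = ", "))
  ne <- as.integer(meta$n_electrodes)
  ns <- as.integer(meta$n_samples)
  dtype <- match.arg(meta$dtype, c("int16", "float32"))
  n_total <- ne * ns
  raw <- if (dtype == "int16") {
    readBin(path, "integer", n = n_total + 1L, size = 2L, signed = TRUE,
            endian = "little")
  } else {
    readBin(path, "double", n = n_total + 1L, size = 4L, endian = "little")
  }
  if (length(raw) != n_total)
    stopf("expected %d samples (%d x %d) in %s, found %d",
          n_total, ne, ns, path, length(raw))
  gain <- if (!is.null(meta$gain_uv)) as.numeric(meta$gain_uv) else 1
  data <- matrix(as.numeric(raw) * gain, nrow = ne, ncol = ns, byrow = TRUE)
  fs <- if (!is.null(fs_in)) fs_in else as.numeric(meta$fs)
  positions <- layout
  if (is.null(positions) && !is.null(meta$positions)) {
    positions <- matrix(unlist(meta$positions), ncol = 2, byrow = !is.matrix(meta$positions))
    if (is.matrix(meta$positions)) positions <- meta$positions
    colnames(positions) <- c("x", "y")
  }
  band <- if (!is.null(meta$band)) meta$band else "raw"
  t0 <- if (!is.null(meta$t0)) as.numeric(meta$t0) else 0
  lfp_set(data, fs = fs, positions = positions, band = band, t0 = t0)
}

#' Write an LFP set as raw binary plus JSON sidecar
#'
#' Inverse of [load_lfp]. `float32` storage round-trips voltages to single
#' precision; `int16` requires a `gain_uv` quantisation step.
#'
#' @param x an `lfp_set`.
#' @param path output binary file; `<path>.json` is written alongside.
#' @param dtype `"float32"` (default) or `"int16"`.
#' @param gain_uv uV-per-bit scale used for `int16`.
#' @export
write_lfp <- function(x, path, dtype = c("float32", "int16"), gain_uv = 0.195) {
  dtype <- match.arg(dtype)
  vals <- as.vector(t(x$data))
  con <- file(path, "wb")
  on.exit(close(con))
  if (dtype == "int16") {
    writeBin(as.integer(round(vals / gain_uv)), con, size = 2L, endian = "little")
  } else {
    gain_uv <- 1
    writeBin(vals, con, size = 4L, endian = "little")
  }
  meta <- list(n_electrodes = nrow(x$data), n_samples = ncol(x$data),
               dtype = dtype, fs = x$fs, gain_uv = gain_uv,
               band = x$band, t0 = x$t0)
  if (!is.null(x$positions)) meta$positions <- unname(as.matrix(x$positions))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
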