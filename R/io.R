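# Trace, model, and event-table input/output.
#
# Delimited text is the primary trace format here: no HDF5 bindings are
# available in this R installation, so the HDF5 layout used by acquisition
# pipelines is out of scope. A minimal Axon ABF v1 reader (float32 or int16
# single-channel data) is provided for instrument files.

#' Read a recording trace from a file
#'
#' Text files hold one sample per line (optionally a second column, which is
#' ignored as a time axis), with metadata in `# key: value` header comments
#' (`sampling_rate_hz`, `units`, `polarity`). An explicit `sampling_rate`
#' argument overrides the header; if neither is present the read fails naming
#' the missing field. Files ending in `.abf` are parsed as Axon ABF v1.
#'
#' @param path file path.
#' @param format "auto" (by extension), "text", or "abf".
#' @param sampling_rate sampling rate in Hz, overriding file metadata.
#' @param units,polarity defaults when the file carries no metadata.
#' @return a `mini_trace`.
#' @export
read_trace <- function(path, format = c("auto", "text", "abf"),
                       sampling_rate = NULL, units = "pA",
                       polarity = "negative") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.abf$", path, ignore.case = TRUE)) "abf" else "text"
  if (format == "abf") return(read_abf(path, polarity = polarity))
  header <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  meta <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  rate <- sampling_rate %||%
    (if (!is.null(meta$sampling_rate_hz)) as.numeric(meta$sampling_rate_hz)
     else NULL)
  if (is.null(rate))
    stop("sampling rate not found: provide a `sampling_rate` argument or a '# sampling_rate_hz: <Hz>' header line")
  dat <- utils::read.table(path, comment.char = "#")
  samples <- dat[[ncol(dat)]]
  trace(samples, rate,
        units = meta$units %||% units,
        polarity = meta$polarity %||% polarity)
}

#' Write a trace as delimited text
#'
#' One sample per line, preceded by `#` header comments carrying the sampling
#' rate, units, and polarity so [read_trace()] round-trips without extra
#' arguments. Values are written with full precision (%.17g).
#'
#' @param x a `mini_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "mini_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz: %.10g", x$sampling_rate),
               sprintf("# units: %s", x$units),
               sprintf("# polarity: %s", x$polarity),
               sprintf("%.17g", x$samples)), con)
  invisible(path)
}

# --- minimal ABF v1 support ------------------------------------------------
# Only the subset needed to round-trip single-channel gap-free data:
# signature "ABF ", float data (nDataFormat = 1) or int16 with a scale
# factor, sampling interval from fADCSampleInterval (us per channel).

ABF_OFF <- list(version = 4, acq_length = 10, data_ptr = 40,
                data_format = 100, n_channels = 120, sample_interval = 122,
                instrument_scale = 922)

#' Read an Axon ABF v1 file (minimal subset)
#'
#' Supports single-channel gap-free recordings with float32 data, or int16
#' data scaled by the first instrument scale factor. Anything else errors
#' with the unsupported field named.
#'
#' @param path .abf file path.
#' @param units,polarity trace metadata (ABF1 unit strings are not parsed).
#' @return a `mini_trace`.
#' @export
read_abf <- function(path, units = "pA", polarity = "negative") {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (sig != "ABF ")
    stop("not an ABF v1 file (signature != 'ABF '); ABF2 is unsupported")
  hdr <- readBin(con, "raw", 6144 - 4)
  rd <- function(off, what, size, n = 1)
    readBin(hdr[(off - 4 + 1):length(hdr)], what, n = n, size = size,
            endian = "little")
  acq_len <- rd(ABF_OFF$acq_length, "integer", 4)
  data_ptr <- rd(ABF_OFF$data_ptr, "integer", 4)
  fmt <- rd(ABF_OFF$data_format, "integer", 2)
  n_ch <- rd(ABF_OFF$n_channels, "integer", 2)
  interval_us <- rd(ABF_OFF$sample_interval, "double", 4)
  if (n_ch != 1)
    stop(sprintf("only single-channel ABF files are supported (nADCNumChannels = %d)", n_ch))
  seek(con, data_ptr * 512)
  if (fmt == 1) {
    samples <- readBin(con, "double", n = acq_len, size = 4, endian = "little")
  } else if (fmt == 0) {
    scale <- rd(ABF_OFF$instrument_scale, "double", 4)
    raw16 <- readBin(con, "integer", n = acq_len, size = 2, endian = "little")
    samples <- raw16 * scale
  } else stop(sprintf("unsupported nDataFormat = %d", fmt))
  trace(samples, 1e6 / interval_us, units = units, polarity = polarity)
}

#' Write a synthetic Axon ABF v1 file
#'
#' Emits the minimal ABF1 structure [read_abf()] parses (float32 data,
#' single channel). Intended for tests and interchange of generated data;
#' files written here are synthetic stand-ins, not acquisition output.
#'
#' @param x a `mini_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abf_synthetic <- function(x, path) {
  stopifnot(inherits(x, "mini_trace"))
  hdr <- raw(6144)
  put <- function(hdr, off, val, what, size) {
    b <- writeBin(val, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <- b
    hdr
  }
  hdr[1:4] <- charToRaw("ABF ")
  hdr <- put(hdr, ABF_OFF$version, 1.83, "double", 4)
  hdr <- put(hdr, ABF_OFF$acq_length, as.integer(length(x$samples)), "integer", 4)
  hdr <- put(hdr, ABF_OFF$data_ptr, 12L, "integer", 4)   # 12 * 512 = 6144
  hdr <- put(hdr, ABF_OFF$data_format, 1L, "integer", 2)
  hdr <- put(hdr, ABF_OFF$n_channels, 1L, "integer", 2)
  hdr <- put(hdr, ABF_OFF$sample_interval, 1e6 / x$sampling_rate, "double", 4)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.numeric(x$samples), con, size = 4, endian = "little")
  invisible(path)
}

# --- event tables ----------------------------------------------------------

#' Write event and summary tables as CSV
#'
#' The event table has columns event_idx, position_s, amplitude,
#' rise_10_90_ms, half_decay_ms, charge, score; the per-recording summary is
#' written alongside with a `_summary.csv` suffix.
#'
#' @param events per-event data.frame (from [quantify_events()]).
#' @param summary one-row summary (from [summarize_recording()]), or NULL.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, summary = NULL, path) {
  cols <- c("event_idx", "position_s", "amplitude", "rise_10_90_ms",
            "half_decay_ms", "charge", "score")
  for (cl in setdiff(cols, names(events))) events[[cl]] <- NA_real_
  utils::write.csv(format(events[, cols], digits = 17, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary)) {
    spath <- sub("\\.csv$", "", path)
    utils::write.csv(summary, paste0(spath, "_summary.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_event_table <- function(path) {
  utils::read.csv(path)
}

# --- model persistence -----------------------------------------------------

#' Save a classifier to disk
#'
#' The model (architecture, parameter tensors, history) is stored as a single
#' serialized RDS container; a human-readable JSON sidecar (`<path>.json`)
#' records the architecture, training configuration, and seed.
#'
#' @param model an `event_classifier`.
#' @param path output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "event_classifier"))
  saveRDS(model, path)
  sidecar <- list(format_version = 1L,
                  spec = unclass(model$spec),
                  config = if (!is.null(model$config)) unclass(model$config),
                  seed = model$seed, frozen = model$frozen,
                  trained = model$trained,
                  n_parameters = count_parameters(model),
                  n_trainable = count_parameters(model, trainable_only = TRUE))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a classifier saved with [save_model()]
#'
#' @param path model path.
#' @return an `event_classifier`; a missing JSON sidecar gives a warning,
#'   a format-version mismatch an error.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "event_classifier"))
    stop("file does not contain an event_classifier")
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    warning("model sidecar JSON missing; provenance defaults assumed")
  } else {
    sc <- jsonlite::read_json(sidecar_path)
    if (!identical(as.integer(sc$format_version), 1L))
      stop(sprintf("unsupported model format version: %s", sc$format_version))
  }
  model
}

#' Export training history as delimited text
#'
#' @param model a trained `event_classifier`.
#' @param path output path (tab-separated: epoch, loss, accuracy, val_loss,
#'   val_accuracy).
#' @return `path`, invisibly.
#' @export
write_history <- function(model, path) {
  if (is.null(model$history)) stop("model has no training history")
  utils::write.table(model$history, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
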