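#' Multichannel extracellular recording
#'
#' Container for a channels-by-samples voltage matrix in microvolts together
#' with its sampling rate and channel labels. All pipeline stages operate on
#' this object or on single channels extracted from it.
#'
#' @param samples numeric matrix, channels x samples, in microvolts (uV).
#'   A plain vector is treated as a single channel.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param channel_ids optional character labels, one per channel. Defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param t0 time of the first sample in seconds (default 0). Sample `i`
#'   (1-based) is at time `t0 + (i - 1) / sampling_rate`.
#'
#' @return An object of class `"recording"`.
#' @export
recording <- function(samples, sampling_rate, channel_ids = NULL, t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples: must be a numeric channels x samples matrix")
  if (!all(is.finite(samples)))
    stop("samples: recording contains non-finite values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0)
    stop("sampling_rate: must be a single positive number (Hz)")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_ids) != nrow(samples))
    stop("channel_ids: length must equal the number of channels")
  rownames(samples) <- channel_ids
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_ids = as.character(channel_ids), t0 = t0),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.3f s, t0 = %g s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate, x$t0))
  invisible(x)
}

#' @rdname recording
#' @param x a `recording`.
#' @export
n_channels <- function(x) nrow(x$samples)

#' @rdname recording
#' @export
n_samples <- function(x) ncol(x$samples)

#' @rdname recording
#' @export
rec_duration <- function(x) ncol(x$samples) / x$sampling_rate

#' Extract one channel as a numeric vector
#'
#' @param rec a [recording()].
#' @param channel channel id (character) or index.
#' @return numeric vector of voltages (uV).
#' @export
channel_signal <- function(rec, channel) {
  if (is.character(channel)) {
    i <- match(channel, rec$channel_ids)
    if (is.na(i)) stop("unknown channel id: ", channel)
  } else i <- channel
  rec$samples[i, ]
}

#' Cut a time slice out of a recording
#'
#' The slice is half-open, `[start, end)`, in seconds relative to the
#' recording clock (i.e. including `t0`).
#'
#' @param rec a [recording()].
#' @param start,end slice boundaries in seconds.
#' @return a `recording` whose `t0` is `start`.
#' @export
slice_recording <- function(rec, start, end) {
  fs <- rec$sampling_rate
  i0 <- floor((start - rec$t0) * fs) + 1
  i1 <- ceiling((end - rec$t0) * fs)
  i0 <- max(1L, as.integer(i0)); i1 <- min(ncol(rec$samples), as.integer(i1))
  if (i1 < i0) stop("empty slice: [", start, ", ", end, ")")
  recording(rec$samples[, i0:i1, drop = FALSE], fs, rec$channel_ids,
            t0 = rec$t0 + (i0 - 1) / fs)
}

#' Laser on/off segment table
#'
#' Describes the three-part recording protocol: a laser-free reference part,
#' the laser-on (two-photon imaging) part, and a second laser-free part.
#' Segments are half-open intervals `[start, end)` in seconds; empty parts
#' are dropped (e.g. when the laser is on from the very beginning).
#'
#' @param laser_on_interval numeric `c(start, end)` of the laser-on part, in
#'   seconds.
#' @param duration total recording duration in seconds.
#' @param t0 recording start time in seconds (default 0).
#' @return data.frame with columns `kind` (`laser_off_pre`, `laser_on`,
#'   `laser_off_post`), `start`, `end`.
#' @export
segment_labels <- function(laser_on_interval, duration, t0 = 0) {
  s <- laser_on_interval[1]; e <- laser_on_interval[2]
  if (!(t0 <= s && s < e && e <= t0 + duration))
    stop("laser_on_interval: need t0 <= start < end <= t0 + duration")
  seg <- data.frame(
    kind  = c("laser_off_pre", "laser_on", "laser_off_post"),
    start = c(t0, s, e),
    end   = c(s, e, t0 + duration),
    stringsAsFactors = FALSE)
  seg[seg$end > seg$start, , drop = FALSE]
}

#' Segment membership of time points
#'
#' @param times numeric vector of times in seconds.
#' @param segments a [segment_labels()] table.
#' @return character vector, the `kind` of the segment containing each time
#'   (half-open intervals), or `NA` outside all segments.
#' @export
segment_of <- function(times, segments) {
  out <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(segments)))
    out[times >= segments$start[i] & times < segments$end[i]] <- segments$kind[i]
  out
}

#' Read / write recordings as flat binary plus JSON sidecar
#'
#' The on-disk format is a float32 little-endian channel-major flat binary
#' file (`<stem>.dat`: all samples of channel 1, then channel 2, ...) with a
#' JSON sidecar (`<stem>.json`) holding `sampling_rate_hz`, `n_channels`,
#' `n_samples`, `units` (must be `"uV"`; no implicit unit conversion is
#' performed), `duration_s`, `t0_s` and `channel_ids`. Write-then-read
#' round-trips are exact for float32 data.
#'
#' @param rec a [recording()].
#' @param path path to the `.dat` file (or a stem; `.dat` is appended when
#'   missing). The sidecar lives next to it with extension `.json`.
#' @return `read_recording` returns a [recording()]; `write_recording`
#'   returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!grepl("\\.dat$", path)) path <- paste0(path, ".dat")
  side <- sub("\\.dat$", ".json", path)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$samples)), con, size = 4L, endian = "little")
  meta <- list(
    sampling_rate_hz = rec$sampling_rate,
    n_channels = nrow(rec$samples),
    n_samples = ncol(rec$samples),
    units = "uV",
    duration_s = ncol(rec$samples) / rec$sampling_rate,
    t0_s = rec$t0,
    channel_ids = rec$channel_ids)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!grepl("\\.dat$", path)) path <- paste0(path, ".dat")
  side <- sub("\\.dat$", ".json", path)
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  need <- c("sampling_rate_hz", "n_channels", "n_samples", "units")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("sidecar missing metadata field(s): ",
                         paste(miss, collapse = ", "))
  if (!identical(meta$units, "uV"))
    stop("sidecar units is '", meta$units, "', expected 'uV' (no implicit conversion)")
  nexp <- meta$n_channels * meta$n_samples
  if (file.size(path) != 4 * nexp)
    stop("binary length mismatch: ", file.size(path), " bytes but sidecar implies ",
         4 * nexp)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = nexp, size = 4L, endian = "little")
  m <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
  t0 <- if (!is.null(meta$t0_s)) as.numeric(meta$t0_s) else 0
  ids <- if (!is.null(meta$channel_ids)) meta$channel_ids else NULL
  recording(m, as.numeric(meta$sampling_rate_hz), ids, t0 = t0)
}
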