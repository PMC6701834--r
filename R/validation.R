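#' Per-minute spike stability report
#'
#' For every unit and every non-overlapping 60 s bin of the recording, the
#' mean and standard error of the mean (SEM = SD / sqrt(n)) of each of the
#' three spike features, plus the spike count. Stable means across minutes
#' -- in particular across the laser on/off transitions -- show that the
#' filtering does not corrupt the sorted waveforms; stable counts show
#' that the laser artifact does not inject false-positive spikes into the
#' clusters.
#'
#' @param spike_times spike times in seconds.
#' @param labels unit labels per spike (or a `"cluster_set"`).
#' @param features data.frame from [extract_features()], rows matching
#'   `spike_times`.
#' @param duration recording duration in seconds.
#' @param segments optional [segment_labels()] table; each minute is
#'   labeled by the segment containing its midpoint.
#' @param units unit ids to report on (default: those present in
#'   `labels`; pass explicitly to include units with zero spikes).
#' @param t0 recording start time in seconds.
#' @return object of class `"stability_report"`: `minutes` (per unit x
#'   minute: `n`, mean and SEM of each feature -- `NA` means for empty
#'   minutes), `counts` (unit x minute matrix), `minute_segments`, and the
#'   raw `data` used (times, labels, features).
#' @export
stability_report <- function(spike_times, labels, features, duration,
                             segments = NULL, units = NULL, t0 = 0) {
  if (inherits(labels, "cluster_set")) labels <- labels$labels
  stopifnot(length(spike_times) == length(labels),
            length(spike_times) == nrow(features))
  n_min <- max(1L, ceiling((duration - 1e-9) / 60))
  minute <- pmin(floor((spike_times - t0) / 60) + 1L, n_min)
  if (is.null(units)) units <- sort(unique(labels))
  feats <- c("v_trough", "v_pre5", "v_post5")
  rows <- list()
  for (u in units) for (mi in seq_len(n_min)) {
    idx <- labels == u & minute == mi
    n <- sum(idx)
    stats <- lapply(feats, function(fn) {
      v <- features[[fn]][idx]
      if (n == 0) c(NA_real_, NA_real_)
      else c(mean(v), if (n > 1) sd(v) / sqrt(n) else NA_real_)
    })
    rows[[length(rows) + 1L]] <- data.frame(
      unit = u, minute = mi, n = n,
      mean_v_trough = stats[[1]][1], sem_v_trough = stats[[1]][2],
      mean_v_pre5 = stats[[2]][1], sem_v_pre5 = stats[[2]][2],
      mean_v_post5 = stats[[3]][1], sem_v_post5 = stats[[3]][2])
  }
  minutes <- do.call(rbind, rows)
  counts <- matrix(minutes$n, nrow = length(units), byrow = TRUE,
                   dimnames = list(paste0("unit", units),
                                   paste0("min", seq_len(n_min))))
  mid <- t0 + (seq_len(n_min) - 0.5) * 60
  minute_segments <- if (!is.null(segments)) segment_of(mid, segments)
  else rep(NA_character_, n_min)
  structure(list(minutes = minutes, counts = counts,
                 minute_segments = minute_segments,
                 data = data.frame(time_s = spike_times, unit = labels, features),
                 duration = duration, t0 = t0),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d unit(s) x %d minute(s), %d spikes\n",
              nrow(x$counts), ncol(x$counts), nrow(x$data)))
  invisible(x)
}

#' Histogram of spike occurrence within the laser artifact period
#'
#' Each spike within the laser-on segment is assigned a phase: the time
#' elapsed since the nearest preceding frame start, as a fraction of the
#' frame period. When only the period is known (e.g. `1 / D_F` from the
#' fitted comb), phases are computed relative to `t_ref` instead of true
#' frame clock times. A flat histogram indicates firing unrelated to the
#' laser; structure indicates phase-locked modulation (or residual
#' artifact spikes).
#'
#' @param spike_times spike times in seconds.
#' @param frame_start_times frame onset times in seconds (preferred).
#' @param frame_period frame period in seconds (used when
#'   `frame_start_times` is NULL).
#' @param n_bins number of phase bins (default 20).
#' @param segment optional `c(start, end)` restriction in seconds (the
#'   laser-on segment).
#' @param t_ref phase origin when only `frame_period` is given.
#' @return object of class `"phase_histogram"`: `edges` (seconds within
#'   `[0, period)`), `counts` (sums to the number of spikes used),
#'   `phases`, `period`.
#' @export
laser_phase_histogram <- function(spike_times, frame_start_times = NULL,
                                  frame_period = NULL, n_bins = 20,
                                  segment = NULL, t_ref = 0) {
  t <- sort(spike_times)
  if (!is.null(segment)) t <- t[t >= segment[1] & t < segment[2]]
  if (!is.null(frame_start_times)) {
    fstart <- sort(frame_start_times)
    if (!is.null(segment))
      fstart <- fstart[fstart >= segment[1] & fstart < segment[2]]
    if (!length(fstart)) stop("no frame starts within the laser-on segment")
    period <- if (length(fstart) > 1) median(diff(fstart)) else frame_period
    if (is.null(period)) stop("frame_period required with a single frame start")
    pos <- findInterval(t, fstart)
    t <- t[pos >= 1]; pos <- pos[pos >= 1]
    phase <- ((t - fstart[pos]) / period) %% 1
  } else {
    if (is.null(frame_period)) stop("need frame_start_times or frame_period")
    period <- frame_period
    phase <- ((t - t_ref) / period) %% 1
  }
  bin <- pmin(floor(phase * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(edges = (0:n_bins) / n_bins * period, counts = counts,
                 phases = phase, period = period, n_bins = n_bins),
            class = "phase_histogram")
}

#' Chi-square test of phase-histogram uniformity
#'
#' @param ph a `"phase_histogram"`.
#' @return p-value of the chi-square goodness-of-fit test against the
#'   uniform distribution over phase bins.
#' @export
phase_uniformity_test <- function(ph) {
  if (sum(ph$counts) == 0) stop("empty phase histogram")
  suppressWarnings(chisq.test(ph$counts)$p.value)
}

#' Laser-on versus laser-off comparison
#'
#' Summarizes, per unit: the firing rate in each condition and their ratio
#' (laser-on over pooled laser-off), and the difference of each feature
#' mean between conditions expressed in pooled-SEM units
#' (`|m_on - m_off| / sqrt(sem_on^2 + sem_off^2)`). Optionally compares
#' autocorrelograms between conditions (maximum absolute difference of the
#' rate-normalized histograms). Missing segments yield a partial report
#' with a warning.
#'
#' @param report a [stability_report()] (its raw `data` is used).
#' @param segments a [segment_labels()] table.
#' @param acg compute the autocorrelogram comparison (default TRUE).
#' @param bin_width,max_lag autocorrelogram parameters.
#' @return object of class `"condition_compare"`: data.frame `units` with
#'   per-unit rates, `rate_ratio` and feature differences
#'   (`d_v_trough`, ... in pooled SEMs), plus `acg_max_diff` when
#'   computed.
#' @export
condition_compare <- function(report, segments, acg = TRUE,
                              bin_width = 0.001, max_lag = 0.05) {
  stopifnot(inherits(report, "stability_report"))
  d <- report$data
  d$segment <- segment_of(d$time_s, segments)
  have <- intersect(c("laser_off_pre", "laser_on", "laser_off_post"),
                    segments$kind)
  missing_seg <- setdiff(c("laser_off_pre", "laser_on", "laser_off_post"), have)
  if (length(missing_seg))
    warning("missing segment(s): ", paste(missing_seg, collapse = ", "),
            "; returning a partial report")
  seg_dur <- function(kind) {
    s <- segments[segments$kind %in% kind, , drop = FALSE]
    sum(s$end - s$start)
  }
  off_kinds <- intersect(c("laser_off_pre", "laser_off_post"), have)
  feats <- c("v_trough", "v_pre5", "v_post5")
  units <- sort(unique(d$unit))
  rows <- lapply(units, function(u) {
    don <- d[d$unit == u & d$segment == "laser_on", , drop = FALSE]
    doff <- d[d$unit == u & d$segment %in% off_kinds, , drop = FALSE]
    rate_on <- if ("laser_on" %in% have) nrow(don) / seg_dur("laser_on") else NA
    rate_off <- if (length(off_kinds)) nrow(doff) / seg_dur(off_kinds) else NA
    out <- data.frame(unit = u, n_on = nrow(don), n_off = nrow(doff),
                      rate_on = rate_on, rate_off = rate_off,
                      rate_ratio = rate_on / rate_off)
    for (fn in feats) {
      m_on <- mean(don[[fn]]); m_off <- mean(doff[[fn]])
      sem_on <- sd(don[[fn]]) / sqrt(nrow(don))
      sem_off <- sd(doff[[fn]]) / sqrt(nrow(doff))
      out[[paste0("d_", fn)]] <- abs(m_on - m_off) / sqrt(sem_on^2 + sem_off^2)
    }
    if (acg && nrow(don) >= 2 && nrow(doff) >= 2) {
      a_on <- autocorrelogram(don$time_s, bin_width, max_lag)
      a_off <- autocorrelogram(doff$time_s, bin_width, max_lag)
      norm <- function(a) if (sum(a$counts) > 0) a$counts / sum(a$counts) else a$counts
      out$acg_max_diff <- max(abs(norm(a_on) - norm(a_off)))
    } else out$acg_max_diff <- NA_real_
    out
  })
  structure(list(units = do.call(rbind, rows), segments = segments,
                 missing_segments = missing_seg),
            class = "condition_compare")
}

#' @export
print.condition_compare <- function(x, ...) {
  cat("<condition_compare>\n")
  print(x$units, row.names = FALSE)
  invisible(x)
}
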