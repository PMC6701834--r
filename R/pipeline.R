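#' End-to-end artifact filtering of a contaminated recording
#'
#' The full filtering chain: band-pass the recording into the SUA band,
#' fit one custom-set comb filter per channel on the laser-on segment, and
#' apply each channel's comb to all segments (filtered independently), so
#' that spikes are equally distorted with and without laser noise.
#'
#' @param rec a raw [recording()].
#' @param laser_on_interval `c(start, end)` seconds of the laser-on part.
#' @param config a [fit_config()].
#' @param verbose log per-stage timings.
#' @return list: `recording` (filtered), `specs` (per-channel comb specs),
#'   `segments` (the [segment_labels()] table), `bandpassed` (the
#'   band-passed but not comb-filtered recording).
#' @export
filter_recording <- function(rec, laser_on_interval, config = fit_config(),
                             verbose = FALSE) {
  segs <- segment_labels(laser_on_interval, rec_duration(rec), t0 = rec$t0)
  bp <- log_stage("band-pass 300-3000 Hz", bandpass_sua(rec), verbose)
  specs <- log_stage("comb fit",
                     fit_comb_filters(bp, config, segment = laser_on_interval,
                                      verbose = verbose), verbose)
  filt <- log_stage("comb apply", apply_comb_filter(bp, specs, segments = segs),
                    verbose)
  list(recording = filt, specs = specs, segments = segs, bandpassed = bp)
}

#' Detect, featurize and cluster spikes on every channel
#'
#' @param rec a filtered [recording()].
#' @param detection a [detection_config()].
#' @param n_units units per channel for [cluster_spikes()].
#' @return named list per channel: `events`, `features`, `clusters`.
#' @export
sort_recording <- function(rec, detection = detection_config(), n_units = 2) {
  out <- lapply(seq_along(rec$channel_ids), function(i) {
    ev <- detect_spikes(rec$samples[i, ], rec$sampling_rate, detection)
    fe <- if (nrow(ev$events)) extract_features(ev) else
      data.frame(v_trough = numeric(0), v_pre5 = numeric(0), v_post5 = numeric(0))
    cl <- if (nrow(ev$events) >= 10 * n_units)
      cluster_spikes(fe, n_units, waveforms = ev$waveforms) else NULL
    list(events = ev, features = fe, clusters = cl)
  })
  names(out) <- rec$channel_ids
  out
}

# minimal structured logging: stage name + elapsed seconds
log_stage <- function(name, expr, verbose = TRUE) {
  t0 <- Sys.time()
  r <- force(expr)
  if (verbose)
    message(sprintf("[%s] %s: %.1f s", format(Sys.time(), "%H:%M:%S"), name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  r
}

#' Match detected spikes against ground-truth spike times
#'
#' Greedy one-to-one matching within a tolerance; used to score detection
#' recall and precision on synthetic recordings.
#'
#' @param detected detected spike times in seconds.
#' @param truth ground-truth spike times in seconds.
#' @param tol matching tolerance in seconds (default 0.5 ms).
#' @return list: `recall`, `precision`, `n_matched`.
#' @export
match_spike_times <- function(detected, truth, tol = 0.0005) {
  detected <- sort(detected); truth <- sort(truth)
  used <- logical(length(detected))
  matched <- 0L
  for (tt in truth) {
    lo <- findInterval(tt - tol, detected) + 1L
    hi <- findInterval(tt + tol, detected)
    if (hi >= lo) {
      cand <- lo:hi
      cand <- cand[!used[cand]]
      if (length(cand)) {
        used[cand[which.min(abs(detected[cand] - tt))]] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  list(recall = if (length(truth)) matched / length(truth) else NA_real_,
       precision = if (length(detected)) sum(used) / length(detected) else NA_real_,
       n_matched = matched)
}
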