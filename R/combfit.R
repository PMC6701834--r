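#' Magnitude spectrum estimate
#'
#' `compute_spectrum` applies a plain FFT to the signal and returns the
#' one-sided magnitude spectrum (`|X(f)|`, unscaled, so Parseval's theorem
#' holds exactly on the two-sided reconstruction). The frequency resolution
#' is one over the analyzed duration; at least 2 s of signal are required
#' so that the +/-3 Hz band-stop cutoffs can be resolved (resolution <=
#' 0.5 Hz).
#'
#' `spectrum_estimate` builds the container directly, which is convenient
#' for constructing synthetic spectra.
#'
#' @param freqs strictly increasing frequency grid in Hz.
#' @param magnitude `|X(f)|` values on that grid.
#' @param resolution grid step in Hz.
#' @return object of class `"spectrum_estimate"`.
#' @export
spectrum_estimate <- function(freqs, magnitude, resolution) {
  if (length(freqs) != length(magnitude))
    stop("freqs and magnitude must have equal length")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  structure(list(freqs = freqs, magnitude = magnitude, resolution = resolution),
            class = "spectrum_estimate")
}

#' @rdname spectrum_estimate
#' @param x numeric signal vector (uV).
#' @param sampling_rate Hz.
#' @param band optional `c(f_low, f_high)` restriction in Hz.
#' @export
compute_spectrum <- function(x, sampling_rate, band = NULL) {
  n <- length(x)
  if (n / sampling_rate < 2)
    stop("signal too short for spectrum estimation: need at least 2 s (got ",
         signif(n / sampling_rate, 4), " s)")
  X <- Mod(fft(x))
  half <- floor(n / 2) + 1L
  sp <- spectrum_estimate(freqs = (seq_len(half) - 1) * sampling_rate / n,
                          magnitude = X[seq_len(half)],
                          resolution = sampling_rate / n)
  if (!is.null(band)) sp <- restrict_spectrum(sp, band) else sp
}

#' @rdname spectrum_estimate
#' @param spec a `"spectrum_estimate"`.
#' @export
restrict_spectrum <- function(spec, band) {
  keep <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(keep)) stop("band (", band[1], ", ", band[2], ") Hz is empty on this grid")
  spectrum_estimate(spec$freqs[keep], spec$magnitude[keep], spec$resolution)
}

#' Detect the periodic artifact peaks of a spectrum
#'
#' A bin is a peak when it is a local maximum, exceeds `floor_mult` times
#' the median in-band magnitude (robust prominence floor against the
#' broadband background), and is the largest value within
#' `+/- min_separation` Hz (which suppresses spectral-leakage sidelobes of
#' strong lines: any skirt value is dominated by points closer to the line
#' within its own window).
#'
#' @param spec a [spectrum_estimate()].
#' @param band `c(f_low, f_high)` Hz; the analysis band.
#' @param floor_mult prominence floor as a multiple of the median in-band
#'   magnitude.
#' @param min_separation Hz; must be well below the harmonic spacing.
#' @return data.frame with columns `freq`, `magnitude`.
#' @export
detect_spectral_peaks <- function(spec, band = c(300, 3000), floor_mult = 5,
                                  min_separation = 2) {
  sp <- restrict_spectrum(spec, band)
  m <- sp$magnitude; f <- sp$freqs; nb <- length(m)
  if (nb < 3) return(data.frame(freq = numeric(0), magnitude = numeric(0)))
  floorv <- floor_mult * median(m)
  cand <- which(m[-c(1, nb)] > m[-c(nb - 1, nb)] & m[-c(1, nb)] > m[-c(1, 2)]) + 1L
  cand <- cand[m[cand] > floorv]
  w <- max(1L, round(min_separation / sp$resolution))
  keep <- vapply(cand, function(i) {
    lo <- max(1L, i - w); hi <- min(nb, i + w)
    m[i] >= max(m[lo:hi])
  }, logical(1))
  cand <- cand[keep]
  data.frame(freq = f[cand], magnitude = m[cand])
}

#' Estimate the comb spacing D_F from the artifact harmonic series
#'
#' The laser artifact produces spectral peaks located periodically; the
#' spacing between neighboring peaks equals the imaging frame rate
#' (found to be 15.5 Hz for the resonant scanner this models). The
#' estimate is the median spacing of consecutive detected peaks among the
#' strongest `n_top` of them; restricting to the strongest peaks makes the
#' estimate robust both to occasional missing harmonics and to weak
#' incidental local maxima (spike-train and noise structure) that the
#' prominence floor lets through between the true harmonics. The spacings
#' must be mutually consistent, otherwise no periodic artifact is declared
#' -- which is what makes a clean recording come back with an empty comb.
#'
#' @inheritParams detect_spectral_peaks
#' @param n_top number of strongest peaks used for the spacing estimate.
#' @return the spacing D_F in Hz.
#' @export
estimate_comb_spacing <- function(spec, band = c(300, 3000), floor_mult = 5,
                                  min_separation = 2, n_top = 20) {
  pk <- detect_spectral_peaks(spec, band, floor_mult, min_separation)
  if (nrow(pk) < 5)
    stop("no periodic artifact detected: found ", nrow(pk),
         " prominent peaks in (", band[1], ", ", band[2], ") Hz, need >= 5")
  top <- head(pk[order(pk$magnitude, decreasing = TRUE), ], n_top)
  spacings <- diff(sort(top$freq))
  d <- median(spacings)
  tol <- max(2 * spec$resolution, 0.05 * d)
  if (mean(abs(spacings - d) <= tol) < 0.6)
    stop("no periodic artifact detected: prominent peaks are not regularly spaced")
  d
}

#' Configuration of the comb-filter parameter-setting algorithm
#'
#' @param amplitude_threshold termination threshold in uV: the algorithm
#'   stops once the period-folded residual artifact amplitude drops below
#'   it (default 40).
#' @param neighbor_fraction a neighboring peak is covered while its height
#'   exceeds this fraction of the module's center peak (default 0.15,
#'   strict inequality).
#' @param halfwidth band-stop cutoff distance from each peak in Hz
#'   (default 3, giving 6 Hz wide rejected bands).
#' @param band analysis band in Hz (default `c(300, 3000)`).
#' @param max_modules hard cap on the number of modules (termination
#'   guarantee).
#' @return object of class `"fit_config"`.
#' @export
fit_config <- function(amplitude_threshold = 40, neighbor_fraction = 0.15,
                       halfwidth = 3, band = c(300, 3000), max_modules = 50) {
  if (amplitude_threshold <= 0) stop("amplitude_threshold: must be > 0")
  if (!(neighbor_fraction > 0 && neighbor_fraction < 1))
    stop("neighbor_fraction: must be in (0, 1)")
  if (halfwidth <= 0) stop("halfwidth: must be > 0")
  if (!(band[1] > 0 && band[1] < band[2])) stop("band: need 0 < f_low < f_high")
  if (max_modules < 1) stop("max_modules: must be >= 1")
  structure(list(amplitude_threshold = amplitude_threshold,
                 neighbor_fraction = neighbor_fraction, halfwidth = halfwidth,
                 band = band, max_modules = as.integer(max_modules)),
            class = "fit_config")
}

# highest-magnitude bin within +/- one resolution bin of a nominal frequency
measured_peak <- function(spec, nominal) {
  idx <- which(abs(spec$freqs - nominal) <= spec$resolution + 1e-9)
  if (!length(idx)) return(NULL)
  i <- idx[which.max(spec$magnitude[idx])]
  list(freq = spec$freqs[i], magnitude = spec$magnitude[i])
}

#' Build one comb-filter module around the strongest spectral peak
#'
#' The frequency of the global in-band maximum becomes the module's center
#' frequency `f_peak`. Neighbors are scanned outward at `f_peak + n * D_F`
#' (the peak value is the maximum magnitude within one resolution bin of
#' the nominal position, so each element is centred on the measured peak,
#' not the arithmetic one); the scan continues on each side while the
#' neighbor height strictly exceeds `neighbor_fraction` of the center
#' height, and stops at the first sub-threshold neighbor or at the band
#' edge. Every covered peak receives a band-stop element spanning
#' `[f - halfwidth, f + halfwidth]` Hz.
#'
#' @param spec a [spectrum_estimate()] of the current residual, restricted
#'   (or restrictable) to the analysis band.
#' @param D_F comb spacing in Hz, from [estimate_comb_spacing()].
#' @param config a [fit_config()].
#' @return object of class `"filter_module"`: `f_peak`, `N_F`, and the
#'   list of [bandstop_spec()] `elements` ordered by frequency.
#' @export
build_filter_module <- function(spec, D_F, config = fit_config()) {
  sp <- restrict_spectrum(spec, config$band)
  i0 <- which.max(sp$magnitude)
  f_peak <- sp$freqs[i0]; v0 <- sp$magnitude[i0]
  centers <- f_peak
  for (dir in c(-1, 1)) {
    n <- 1
    repeat {
      nominal <- f_peak + dir * n * D_F
      if (nominal < config$band[1] || nominal > config$band[2]) break
      pk <- measured_peak(sp, nominal)
      if (is.null(pk) || !(pk$magnitude > config$neighbor_fraction * v0)) break
      centers <- c(centers, pk$freq)
      n <- n + 1
    }
  }
  centers <- sort(centers)
  elements <- lapply(centers, function(f)
    bandstop_spec(f - config$halfwidth, f + config$halfwidth))
  structure(list(f_peak = f_peak, N_F = length(elements), elements = elements),
            class = "filter_module")
}

#' @export
print.filter_module <- function(x, ...) {
  cat(sprintf("<filter_module> f_peak = %.3f Hz, N_F = %d elements (%.1f - %.1f Hz)\n",
              x$f_peak, x$N_F, x$elements[[1]]$f_low,
              x$elements[[x$N_F]]$f_high))
  invisible(x)
}

#' Time-domain amplitude of the periodic artifact by period folding
#'
#' Folds the signal into one artifact period (`sampling_rate / D_F`
#' samples, usually non-integer, handled by phase binning) and takes the
#' median across periods within each phase bin. By default there is one
#' phase bin per sample of the period, so the folded waveform keeps the
#' full temporal resolution of the recording; coarser binning would smear
#' sub-millisecond periodic residuals and understate their amplitude. The
#' returned value is the maximum absolute value of the folded waveform:
#' coherent periodic content survives the folding while spikes and noise
#' average away as 1/sqrt(n periods). This is the quantity the
#' parameter-setting loop compares against its 40 uV termination
#' threshold.
#'
#' @param x signal vector (uV).
#' @param D_F artifact fundamental spacing in Hz.
#' @param sampling_rate Hz.
#' @param n_phase_bins phase bins per period; default one per sample
#'   (`round(sampling_rate / D_F)`).
#' @return folded residual amplitude in uV.
#' @export
measure_periodic_amplitude <- function(x, D_F, sampling_rate, n_phase_bins = NULL) {
  P <- sampling_rate / D_F
  if (length(x) / P < 20)
    stop("signal too short: need >= 20 artifact periods, got ",
         signif(length(x) / P, 3))
  if (is.null(n_phase_bins)) n_phase_bins <- max(1L, round(P))
  phase <- ((seq_along(x) - 1) %% P) / P
  bin <- pmin(floor(phase * n_phase_bins) + 1L, n_phase_bins)
  folded <- vapply(split(x, bin), median, numeric(1))
  max(abs(folded))
}

#' Fit a custom-set comb filter to one contaminated channel
#'
#' The parameter-setting algorithm. The input must already be band-pass
#' filtered to the analysis band (see [bandpass_sua()]). The comb spacing
#' `D_F` is estimated once from the initial spectrum and then frozen. Each
#' cycle then: (1) applies the comb built so far (empty at first, leaving
#' the data unchanged); (2) measures the folded periodic residual
#' amplitude and finalizes the filter if it is below
#' `amplitude_threshold`; (3) otherwise recomputes the spectrum of the
#' residual, builds one new module around its highest in-band peak with
#' [build_filter_module()], appends it, and repeats. The comb is applied
#' incrementally (only the new module is applied to the running residual),
#' which is equivalent to re-applying the full cascade because zero-phase
#' LTI elements commute.
#'
#' @param x band-passed signal vector (uV).
#' @param sampling_rate Hz.
#' @param config a [fit_config()].
#' @param channel_id optional label stored in the result.
#' @param verbose print per-cycle residual amplitudes.
#' @return object of class `"comb_filter_spec"`: `channel_id`, `D_F`,
#'   `N_M`, `modules`, the per-cycle `residual_history` (uV) and the final
#'   `residual_amplitude`. If `max_modules` is reached, or the residual
#'   stops decreasing (< 1% improvement over 3 cycles), a condition of
#'   class `"comb_fit_error"` is signalled carrying the partial spec and
#'   the final residual amplitude.
#' @export
fit_comb_filter <- function(x, sampling_rate, config = fit_config(),
                            channel_id = NULL, verbose = FALSE) {
  spec0 <- compute_spectrum(x, sampling_rate)
  D_F <- tryCatch(estimate_comb_spacing(spec0, config$band),
                  error = function(e) NA_real_)
  if (is.na(D_F)) {
    # no periodic artifact in the spectrum: nothing to remove, empty comb
    return(structure(
      list(channel_id = channel_id, D_F = NA_real_, N_M = 0L,
           modules = list(), residual_amplitude = NA_real_,
           residual_history = numeric(0)),
      class = "comb_filter_spec"))
  }
  period <- sampling_rate / D_F
  residual <- x
  modules <- list()
  history <- numeric(0)
  mk_spec <- function(amp) structure(
    list(channel_id = channel_id, D_F = D_F, N_M = length(modules),
         modules = modules, residual_amplitude = amp,
         residual_history = history),
    class = "comb_filter_spec")
  fail <- function(amp, why) {
    cond <- structure(
      class = c("comb_fit_error", "error", "condition"),
      list(message = paste0("comb fit did not converge (", why,
                            "): residual ", signif(amp, 4), " uV after ",
                            length(modules), " modules"),
           call = sys.call(-1), partial_spec = mk_spec(amp),
           residual_amplitude = amp))
    stop(cond)
  }
  repeat {
    amp <- measure_periodic_amplitude(residual, D_F, sampling_rate)
    history <- c(history, amp)
    if (verbose)
      message(sprintf("cycle %d: residual %.2f uV (%d modules)",
                      length(history), amp, length(modules)))
    if (amp < config$amplitude_threshold) return(mk_spec(amp))
    if (length(modules) >= config$max_modules) fail(amp, "max_modules reached")
    if (length(history) >= 4 &&
        amp > 0.99 * history[length(history) - 3])
      fail(amp, "residual stalled")
    sp <- compute_spectrum(residual, sampling_rate, band = config$band)
    mod <- build_filter_module(sp, D_F, config)
    modules[[length(modules) + 1L]] <- mod
    for (el in mod$elements) {
      filt <- design_bandstop(el, sampling_rate)
      residual <- zero_phase_apply(filt, residual, pad = "periodic", period = period)
    }
  }
}

#' @export
print.comb_filter_spec <- function(x, ...) {
  nel <- sum(vapply(x$modules, `[[`, integer(1), "N_F"))
  cat(sprintf("<comb_filter_spec>%s D_F = %.4g Hz, N_M = %d modules, %d elements, residual %.2f uV\n",
              if (!is.null(x$channel_id)) paste0(" [", x$channel_id, "]") else "",
              x$D_F, x$N_M, nel, x$residual_amplitude))
  invisible(x)
}

#' Fit comb filters for every channel of a recording
#'
#' Convenience wrapper around [fit_comb_filter()]: optionally slices out
#' the laser-on segment, band-passes nothing (the recording must already
#' be band-passed), and fits one comb per channel. The laser noise couples
#' differently into each electrode, so each channel gets its own filter.
#'
#' @param rec a band-passed [recording()].
#' @param config a [fit_config()].
#' @param segment optional `c(start, end)` seconds (e.g. the laser-on
#'   interval) to fit on.
#' @param verbose print progress.
#' @return named list of `"comb_filter_spec"`, one per channel id.
#' @export
fit_comb_filters <- function(rec, config = fit_config(), segment = NULL,
                             verbose = FALSE) {
  r <- if (!is.null(segment)) slice_recording(rec, segment[1], segment[2]) else rec
  specs <- lapply(seq_along(r$channel_ids), function(i) {
    if (verbose) message("fitting channel ", r$channel_ids[i])
    fit_comb_filter(r$samples[i, ], r$sampling_rate, config,
                    channel_id = r$channel_ids[i], verbose = verbose)
  })
  names(specs) <- r$channel_ids
  specs
}

# zero-phase cascade of all elements of one comb spec over a vector;
# filters may be passed in pre-designed to avoid repeated design work
comb_apply_vector <- function(x, spec, sampling_rate, filters = NULL) {
  if (spec$N_M == 0L) return(x)
  period <- sampling_rate / spec$D_F
  if (is.null(filters)) filters <- design_comb_filters(spec, sampling_rate)
  for (filt in filters)
    x <- zero_phase_apply(filt, x, pad = "periodic", period = period)
  x
}

design_comb_filters <- function(spec, sampling_rate) {
  unlist(lapply(spec$modules, function(mod)
    lapply(mod$elements, design_bandstop, sampling_rate = sampling_rate)),
    recursive = FALSE)
}

#' Apply fitted comb filters to a recording
#'
#' Zero-phase cascade of every band-stop element of every module, per
#' channel. The same comb must also be applied to the laser-free segments
#' so that spike waveforms are distorted equally in both conditions and
#' their features remain comparable; passing `segments` filters each
#' segment independently, which keeps the laser on/off transitions from
#' ringing into either side.
#'
#' @param rec a [recording()] (already band-passed).
#' @param specs a single `"comb_filter_spec"` (applied to all channels) or
#'   a named list with one spec per channel id.
#' @param segments optional [segment_labels()] table; when supplied each
#'   segment is filtered separately.
#' @return the filtered [recording()].
#' @export
apply_comb_filter <- function(rec, specs, segments = NULL) {
  if (inherits(specs, "comb_filter_spec"))
    specs <- stats::setNames(rep(list(specs), length(rec$channel_ids)),
                             rec$channel_ids)
  miss <- setdiff(rec$channel_ids, names(specs))
  if (length(miss))
    stop("missing comb filter spec for channel(s): ", paste(miss, collapse = ", "))
  out <- rec
  fs <- rec$sampling_rate
  pieces <- if (is.null(segments))
    data.frame(start = rec$t0, end = rec$t0 + ncol(rec$samples) / fs)
  else segments
  for (ch in rec$channel_ids) {
    filters <- design_comb_filters(specs[[ch]], fs)
    for (j in seq_len(nrow(pieces))) {
      i0 <- floor((pieces$start[j] - rec$t0) * fs) + 1L
      i1 <- min(ncol(rec$samples), ceiling((pieces$end[j] - rec$t0) * fs))
      seg <- out$samples[ch, i0:i1]
      out$samples[ch, i0:i1] <- comb_apply_vector(seg, specs[[ch]], fs, filters)
    }
  }
  out
}

#' Serialize fitted comb filters to JSON and back
#'
#' The stored parameters (channel, D_F, module center frequencies and
#' element cutoffs) are sufficient to re-apply a fitted comb to another
#' recording session.
#'
#' @param specs named list of `"comb_filter_spec"` (or a single one).
#' @param path JSON file path.
#' @return `read_comb_filters` returns the named list of specs.
#' @export
write_comb_filters <- function(specs, path) {
  if (inherits(specs, "comb_filter_spec")) specs <- list(specs)
  payload <- list(channels = lapply(specs, function(s) list(
    channel_id = s$channel_id, D_F = s$D_F,
    residual_amplitude = s$residual_amplitude,
    modules = lapply(s$modules, function(m) list(
      f_peak = m$f_peak,
      elements = lapply(m$elements, function(e)
        list(f_low = e$f_low, f_high = e$f_high,
             order = e$order, ripple = e$ripple)))))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_comb_filters
#' @export
read_comb_filters <- function(path) {
  payload <- jsonlite::read_json(path)
  specs <- lapply(payload$channels, function(s) {
    modules <- lapply(s$modules, function(m) {
      elements <- lapply(m$elements, function(e)
        bandstop_spec(e$f_low, e$f_high, order = e$order, ripple = e$ripple))
      structure(list(f_peak = m$f_peak, N_F = length(elements),
                     elements = elements), class = "filter_module")
    })
    structure(list(channel_id = s$channel_id, D_F = s$D_F,
                   N_M = length(modules), modules = modules,
                   residual_amplitude = s$residual_amplitude,
                   residual_history = NULL),
              class = "comb_filter_spec")
  })
  names(specs) <- vapply(specs, function(s)
    if (is.null(s$channel_id)) "" else s$channel_id, character(1))
  specs
}
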