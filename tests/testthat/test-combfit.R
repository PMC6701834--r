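test_that("spectrum estimation locates tones and satisfies Parseval", {
  fs <- 20000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 1000 * t)
  sp <- compute_spectrum(x, fs)
  expect_equal(sp$resolution, 0.5)
  expect_lt(abs(sp$freqs[which.max(sp$magnitude)] - 1000), sp$resolution + 1e-9)
  expect_true(all(compute_spectrum(numeric(2 * fs), fs)$magnitude == 0))
  # Parseval via the two-sided reconstruction (n even)
  set.seed(41)
  x2 <- rnorm(4000, sd = 5)
  sp2 <- compute_spectrum(x2, 1000)
  m <- sp2$magnitude
  twosided <- m[1]^2 + m[length(m)]^2 + 2 * sum(m[2:(length(m) - 1)]^2)
  expect_lt(abs(twosided / length(x2) - sum(x2^2)) / sum(x2^2), 1e-6)
  expect_error(compute_spectrum(numeric(100), 1000), "at least 2 s")
})

test_that("comb spacing recovers the generator frame rate", {
  for (fr in c(15.5, 10)) {
    hs <- ceiling(300 / fr)
    nh <- floor(3000 / fr) - hs + 1
    m <- artifact_model(frame_rate = fr, sawtooth_amplitude = 5000,
                        harmonic_start = hs, n_harmonics = nh,
                        channel_scale = 1)
    set.seed(51)
    x <- artifact_trace(m, 4, 20000) + rnorm(4 * 20000, sd = 10)
    sp <- compute_spectrum(bandpass_sua(x, 20000), 20000)
    expect_lt(abs(estimate_comb_spacing(sp) - fr), sp$resolution + 1e-9)
  }
})

test_that("spacing estimation refuses spectra without a periodic series", {
  freqs <- seq(300, 3000, by = 1)
  mag <- rep(1, length(freqs))
  mag[freqs == 1000] <- 500
  sp <- spectrum_estimate(freqs, mag, 1)
  expect_error(estimate_comb_spacing(sp), "no periodic artifact")
})

# constructed spectrum: flat floor with harmonic peaks of given heights
peaky_spectrum <- function(centers, heights, lo = 300, hi = 700, res = 1) {
  freqs <- seq(lo, hi, by = res)
  mag <- rep(1, length(freqs))
  mag[match(centers, freqs)] <- heights
  spectrum_estimate(freqs, mag, res)
}

test_that("module construction follows the 15% contiguous-neighbor rule", {
  # center 100 with symmetric neighbors 40, 20, 10 at +-1,2,3 * D_F:
  # 40 and 20 exceed 15% of 100, 10 does not -> 5 elements
  sp <- peaky_spectrum(c(420, 430, 440, 450, 460, 470, 480),
                       c(10, 20, 40, 100, 40, 20, 10))
  mod <- build_filter_module(sp, 10, fit_config(band = c(300, 700)))
  expect_equal(mod$f_peak, 450)
  expect_equal(mod$N_F, 5)
  centers <- vapply(mod$elements, function(e) (e$f_low + e$f_high) / 2,
                    numeric(1))
  expect_equal(centers, c(430, 440, 450, 460, 470))

  # all neighbors below 15% -> single-element module
  sp1 <- peaky_spectrum(c(440, 450, 460), c(14, 100, 14.9))
  mod1 <- build_filter_module(sp1, 10, fit_config(band = c(300, 700)))
  expect_equal(mod1$N_F, 1)

  # a 465 Hz peak receives the (462, 468) Hz stopband
  sp465 <- peaky_spectrum(465, 100)
  mod465 <- build_filter_module(sp465, 15.5, fit_config(band = c(300, 700)))
  el <- mod465$elements[[1]]
  expect_equal(c(el$f_low, el$f_high), c(462, 468))
  expect_equal(el$f_high - el$f_low, 6)

  # the scan stops at the band edge without error
  spedge <- peaky_spectrum(c(310, 320, 330), c(80, 100, 80), lo = 300, hi = 340)
  modedge <- build_filter_module(spedge, 10, fit_config(band = c(305, 335)))
  expect_equal(modedge$N_F, 3)

  # elements sit on the measured local maximum, not the nominal position
  spoff <- peaky_spectrum(c(449, 459), c(100, 60))
  modoff <- build_filter_module(spoff, 10, fit_config(band = c(300, 700)))
  expect_equal(vapply(modoff$elements, function(e) (e$f_low + e$f_high) / 2,
                      numeric(1)), c(449, 459))
})

test_that("period folding isolates the periodic amplitude", {
  fs <- 20000
  expect_equal(measure_periodic_amplitude(numeric(fs * 2), 15.5, fs), 0)
  # a pure sawtooth of peak A folds back to A
  fsaw <- 10
  t <- seq(0, 2.5 - 1 / fs, by = 1 / fs)
  saw <- 100 * (2 * ((t * fsaw) %% 1) - 1)
  expect_lt(abs(measure_periodic_amplitude(saw, fsaw, fs) - 100) / 100, 0.05)
  # incoherent noise is suppressed as sigma / sqrt(n periods): folding 100
  # periods of white noise into 64 phase bins leaves well under 3 SE
  set.seed(61)
  noise <- rnorm(100 * fs / fsaw, sd = 30)
  expect_lt(measure_periodic_amplitude(noise, fsaw, fs, n_phase_bins = 64),
            3 * 30 / sqrt(100))
  expect_error(measure_periodic_amplitude(numeric(fs), 15.5, fs), "20 artifact periods")
})

test_that("the parameter-setting loop converges on contaminated data", {
  cfg <- small_config(seed = 13)
  gen <- generate_recording(cfg)
  bp <- bandpass_sua(gen$recording)
  x <- channel_signal(slice_recording(bp, 2, 10), 1)
  spec <- fit_comb_filter(x, 20000)
  expect_s3_class(spec, "comb_filter_spec")
  expect_lt(spec$residual_amplitude, 40)
  expect_equal(spec$N_M, length(spec$modules))
  expect_gt(spec$N_M, 0)
  # residual amplitude decreased monotonically over cycles
  expect_true(all(diff(spec$residual_history) < 0))
  # D_F recovered the frame rate
  expect_lt(abs(spec$D_F - 15.5), 1 / 8 + 1e-9)
  # every fitted element center lies within 3 Hz of a true harmonic
  centers <- unlist(lapply(spec$modules, function(m)
    vapply(m$elements, function(e) (e$f_low + e$f_high) / 2, numeric(1))))
  expect_true(all(abs(centers - round(centers / 15.5) * 15.5) < 3))
  # every element is exactly 6 Hz wide
  widths <- unlist(lapply(spec$modules, function(m)
    vapply(m$elements, function(e) e$f_high - e$f_low, numeric(1))))
  expect_true(all(abs(widths - 6) < 1e-9))
  # parameter recovery: stopbands cover all harmonics above 15% of the largest
  sp0 <- compute_spectrum(x, 20000, band = c(300, 3000))
  pks <- detect_spectral_peaks(sp0)
  strong <- pks$freq[pks$magnitude > 0.15 * max(pks$magnitude)]
  covered <- vapply(strong, function(f) any(vapply(spec$modules, function(m)
    any(vapply(m$elements, function(e) f >= e$f_low & f <= e$f_high,
               logical(1))), logical(1))), logical(1))
  expect_true(all(covered))

  # clean signal: empty comb leaves the data unchanged
  quiet <- bandpass_sua(channel_signal(
    generate_recording(quiet_config(duration = 4, seed = 14))$recording, 1), 20000)
  spec0 <- fit_comb_filter(quiet, 20000)
  expect_equal(spec0$N_M, 0L)
  rec <- recording(matrix(quiet, 1), 20000)
  expect_identical(apply_comb_filter(rec, spec0)$samples, rec$samples)
})

test_that("non-convergence raises a diagnostic carrying the partial comb", {
  cfg <- small_config(duration = 6, laser_on_interval = c(1, 5), seed = 15)
  gen <- generate_recording(cfg)
  x <- channel_signal(slice_recording(bandpass_sua(gen$recording), 1, 5), 1)
  err <- tryCatch(
    fit_comb_filter(x, 20000, fit_config(max_modules = 1)),
    comb_fit_error = function(e) e)
  expect_s3_class(err, "comb_fit_error")
  expect_s3_class(err$partial_spec, "comb_filter_spec")
  expect_equal(err$partial_spec$N_M, 1L)
  expect_gt(err$residual_amplitude, 40)

  # an unreachable threshold trips the no-progress guard rather than looping
  err2 <- tryCatch(
    fit_comb_filter(x, 20000, fit_config(amplitude_threshold = 1e-4)),
    comb_fit_error = function(e) e)
  expect_s3_class(err2, "comb_fit_error")
  expect_match(conditionMessage(err2), "stalled|max_modules")
})

test_that("applying a comb attenuates stopbands and spares the passband", {
  fs <- 20000
  sp465 <- spectrum_estimate(seq(300, 700), c(rep(1, 165), 100, rep(1, 235)), 1)
  mod <- build_filter_module(sp465, 15.5, fit_config(band = c(300, 700)))
  spec <- structure(list(channel_id = "ch1", D_F = 15.5, N_M = 1L,
                         modules = list(mod), residual_amplitude = 0,
                         residual_history = numeric(0)),
                    class = "comb_filter_spec")
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  mid <- 10000:30000
  rms <- function(v) sqrt(mean(v^2))
  x_stop <- sin(2 * pi * 465 * t)
  x_pass <- sin(2 * pi * 1000 * t)  # >= 20 Hz from the stopband
  rec <- recording(rbind(x_stop, x_pass), fs, c("ch1", "ch2"))
  out <- apply_comb_filter(rec, list(ch1 = spec, ch2 = spec))
  expect_lt(rms(out$samples[1, mid]) / rms(x_stop[mid]), 10^(-20 / 20))
  expect_lt(abs(rms(out$samples[2, mid]) / rms(x_pass[mid]) - 1), 0.1)
  expect_error(apply_comb_filter(rec, list(ch1 = spec)), "missing comb filter")
})

test_that("comb specs survive the JSON round trip", {
  sp465 <- spectrum_estimate(seq(300, 700), c(rep(1, 165), 100, rep(1, 235)), 1)
  mod <- build_filter_module(sp465, 15.5, fit_config(band = c(300, 700)))
  spec <- structure(list(channel_id = "ch1", D_F = 15.5, N_M = 1L,
                         modules = list(mod), residual_amplitude = 12.5,
                         residual_history = numeric(0)),
                    class = "comb_filter_spec")
  path <- file.path(tempdir(), "comb.json")
  write_comb_filters(list(ch1 = spec), path)
  back <- read_comb_filters(path)
  expect_equal(back$ch1$D_F, 15.5)
  expect_equal(back$ch1$N_M, 1L)
  e0 <- spec$modules[[1]]$elements[[1]]
  e1 <- back$ch1$modules[[1]]$elements[[1]]
  expect_equal(unclass(e1), unclass(e0))
})
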