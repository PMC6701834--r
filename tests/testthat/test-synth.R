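test_that("silent configuration produces an all-zero recording", {
  cfg <- synth_config(duration = 2, sampling_rate = 20000, n_channels = 2,
                      templates = list(), firing_rates = numeric(0),
                      noise_sd = 0,
                      artifact = artifact_model(sawtooth_amplitude = 0,
                                                transient_amplitude = 0,
                                                channel_scale = 1),
                      artifact_to_sua_ratio = NULL,
                      laser_on_interval = c(0.5, 1.5), seed = 1)
  gen <- generate_recording(cfg)
  expect_true(all(gen$recording$samples == 0))
})

test_that("artifact peak realizes the 50x ratio to the largest unit", {
  cfg <- synth_config(seed = 3)
  expect_equal(cfg$artifact$sawtooth_amplitude, 50 * 150)
  art <- artifact_trace(cfg$artifact, 2, cfg$sampling_rate)
  ratio <- max(abs(art)) * max(cfg$artifact$channel_scale) /
    max(vapply(cfg$templates, `[[`, numeric(1), "peak_amplitude"))
  expect_lt(abs(ratio - 50) / 50, 0.02)
})

test_that("inserted spike counts follow the configured Poisson rates", {
  cfg <- quiet_config(duration = 120, seed = 5,
                      templates = list(spike_template(150)), firing_rates = 5)
  gen <- generate_recording(cfg)
  n <- length(gen$ground_truth$spike_samples[[1]])
  expect_lt(abs(n - 600), 3 * sqrt(600))
  # enforced dead time: no ISI below 2 ms
  isi <- diff(gen$ground_truth$spike_times_s[[1]])
  expect_true(all(isi >= 0.002))
})

test_that("artifact trace is periodic and spectrally concentrated on the harmonic grid", {
  # frame rate dividing the sampling rate makes the period an exact number
  # of samples: tiling one frame must reproduce the longer trace
  m <- artifact_model(frame_rate = 20, sawtooth_amplitude = 1000,
                      harmonic_start = 15, n_harmonics = 50, channel_scale = 1)
  one <- artifact_trace(m, 1 / 20, 20000)
  three <- artifact_trace(m, 3 / 20, 20000)
  expect_equal(rep(one, 3), three, tolerance = 1e-9)

  # FFT oracle: every spectral peak of the sawtooth-only trace sits within
  # one frequency bin of k * frame_rate, and they cover 300-3000 Hz
  m2 <- artifact_model(sawtooth_amplitude = 7500, transient_amplitude = 0,
                       channel_scale = 1)
  x <- artifact_trace(m2, 4, 20000)
  X <- Mod(fft(x))
  half <- seq_len(length(x) / 2 + 1)
  freqs <- (half - 1) * 20000 / length(x)
  inband <- which(freqs >= 300 & freqs <= 3000)
  big <- inband[X[inband] > 0.05 * max(X[inband])]
  nearest_harm <- round(freqs[big] / 15.5) * 15.5
  expect_true(all(abs(freqs[big] - nearest_harm) <= 0.25 + 1e-9))
  harmonics <- seq(ceiling(300 / 15.5), floor(3000 / 15.5)) * 15.5
  peak_near <- vapply(harmonics, function(h) {
    idx <- which(abs(freqs - h) <= 0.25)
    max(X[idx])
  }, numeric(1))
  expect_true(all(peak_near > 10 * median(X[inband])))
})

test_that("artifact trace edge cases error or vanish as specified", {
  m0 <- artifact_model(sawtooth_amplitude = 0, transient_amplitude = 0,
                       channel_scale = 1)
  expect_true(all(artifact_trace(m0, 0.5, 20000) == 0))
  mbad <- artifact_model(frame_rate = 600, transient_width = 0.001)
  expect_error(artifact_trace(mbad, 1, 1000), "unresolvable")
  expect_error(artifact_model(frame_rate = -1), "frame_rate")
  expect_error(artifact_model(transient_width = 0.1), "transient_width")
  expect_error(artifact_model(transient_amplitude = -5), "amplitudes")
})

test_that("generator is seed-deterministic and component-additive", {
  base <- list(duration = 4, n_channels = 2, laser_on_interval = c(1, 3),
               seed = 9)
  g1 <- generate_recording(do.call(synth_config, base))
  g2 <- generate_recording(do.call(synth_config, base))
  expect_identical(g1$recording$samples, g2$recording$samples)
  expect_identical(g1$ground_truth, g2$ground_truth)

  # additivity: noise-only + spikes-only + artifact-only == full recording
  art0 <- artifact_model(sawtooth_amplitude = 0, transient_amplitude = 0,
                         channel_scale = 1)
  full <- g1$recording$samples
  noise <- generate_recording(do.call(synth_config, c(base, list(
    templates = list(), firing_rates = numeric(0), artifact = art0,
    artifact_to_sua_ratio = NULL))))$recording$samples
  spikes <- generate_recording(do.call(synth_config, c(base, list(
    noise_sd = 0, artifact = art0,
    artifact_to_sua_ratio = NULL))))$recording$samples
  # the 50x ratio only resolves against templates, so the artifact-only
  # config carries the resulting amplitude explicitly
  full_cfg <- do.call(synth_config, base)
  art_only <- full_cfg$artifact
  artifact <- generate_recording(do.call(synth_config, c(base, list(
    templates = list(), firing_rates = numeric(0), noise_sd = 0,
    artifact = art_only, artifact_to_sua_ratio = NULL))))$recording$samples
  expect_equal(noise + spikes + artifact, full, tolerance = 1e-9)
  expect_gt(max(abs(artifact)), 1000)  # artifact genuinely present
  # and confined to the laser-on interval
  fs <- 20000
  expect_true(all(artifact[, 1:(1 * fs - 1)] == 0))
  expect_true(all(artifact[, (3 * fs + 2):(4 * fs)] == 0))
})

test_that("ground-truth frame onsets are strictly periodic after rounding", {
  cfg <- small_config(duration = 6, laser_on_interval = c(1, 5), seed = 2)
  gen <- generate_recording(cfg)
  gt <- gen$ground_truth
  P <- gt$frame_period_samples
  expect_equal(P, 20000 / 15.5)
  m <- seq_along(gt$frame_start_samples) - 1
  ideal <- (1 * 20000 + 1) + m * P
  expect_true(all(abs(gt$frame_start_samples - ideal) <= 0.5 + 1e-9))
  n <- round(cfg$duration * cfg$sampling_rate)
  expect_true(all(gt$frame_start_samples >= 1 & gt$frame_start_samples <= n))
  expect_true(all(unlist(gt$spike_samples) >= 1 &
                  unlist(gt$spike_samples) <= n))
})

test_that("configuration validation names the offending field", {
  expect_error(synth_config(duration = -1), "duration")
  expect_error(synth_config(firing_rates = c(5, -1)), "firing_rates")
  expect_error(synth_config(firing_rates = 5), "firing_rates")
  expect_error(synth_config(noise_sd = -2), "noise_sd")
  expect_error(synth_config(laser_on_interval = c(50, 20)), "laser_on_interval")
  expect_error(synth_config(laser_on_interval = c(10, 70)), "laser_on_interval")
  expect_error(spike_template(waveform = rep(-1, 5)), "11 samples")
  expect_error(spike_template(waveform = c(rep(0, 10), 5, rep(0, 10))),
               "trough")
})
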