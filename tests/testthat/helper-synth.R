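# Shared fixtures, built in code. Durations are even numbers of seconds so
# that the 15.5 Hz harmonic series falls exactly on the FFT bin grid of the
# laser-on segment, keeping spectral tests sharp.

small_config <- function(duration = 12, n_channels = 1,
                         laser_on_interval = c(2, 10), seed = 7, ...) {
  synth_config(duration = duration, n_channels = n_channels,
               laser_on_interval = laser_on_interval, seed = seed, ...)
}

# artifact-free, spikes-only variant (useful for detection oracles)
quiet_config <- function(duration = 12, seed = 7, ...) {
  synth_config(duration = duration, n_channels = 1,
               artifact = artifact_model(sawtooth_amplitude = 0,
                                         transient_amplitude = 0,
                                         channel_scale = 1),
               artifact_to_sua_ratio = NULL,
               laser_on_interval = c(duration / 4, duration / 2),
               seed = seed, ...)
}

# best label agreement between two clusterings of the same points,
# maximized over label permutations (2 units)
label_agreement <- function(a, b) {
  ua <- sort(unique(a)); ub <- sort(unique(b))
  best <- 0
  perms <- if (length(ub) == 1) list(ub) else
    list(ub, rev(ub))
  for (p in perms) {
    mapped <- p[match(b, ub)]
    best <- max(best, mean(a == mapped))
  }
  best
}
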