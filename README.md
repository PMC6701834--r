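# combspike

Spike detection and sorting from microelectrode-array recordings
contaminated by the periodic photoelectric artifact of a simultaneously
scanning two-photon imaging laser.

The artifact appears as huge periodic waves at the imaging frame rate,
with harmonics of high magnitude throughout the 300–3000 Hz band where
extracellular single-unit activity (SUA) lives, and amplitudes around
50× the largest spikes. No single notch removes it. `combspike`
implements a *custom-set comb filter*: per channel, an iterative
parameter-setting algorithm reads the magnitude spectrum of the
band-passed contaminated signal and assembles modules of narrow
zero-phase band-stop elements on the measured harmonic frequencies until
the artifact is gone from the time domain.

## The algorithm

A fitted comb is parameterized by the inter-harmonic spacing $D_F$, the
number of modules $N_M$, the module center frequencies $f_{peak}$, and
the element counts per module $N_F$. Starting from the 300–3000 Hz
band-passed signal (2nd-order Chebyshev Type I, 0.4 dB passband ripple,
applied forward–backward so the net phase shift is zero):

1. $D_F$ is estimated once as the median spacing of the prominent
   spectral peaks (15.5 Hz at the imaging frame rate modeled here) and
   frozen.
2. Each cycle applies the comb built so far and folds the residual into
   one artifact period (median across periods per phase bin). If the
   folded amplitude is below **40 µV**, the comb is final.
3. Otherwise the highest remaining in-band peak becomes $f_{peak}$ of a
   new module; neighbors at $f_{peak} \pm n\,D_F$ are covered while they
   exceed **15%** of the center peak, each receiving a band-stop with
   cutoffs **±3 Hz** around the measured peak (a 6 Hz rejected band).

The same comb is then applied to the laser-free recording segments so
that spike waveforms are distorted equally in both conditions, which is
what makes the downstream validation (per-minute feature stability,
spike counts, laser-phase histograms) meaningful. Spikes are detected by
robust thresholding and sorted on three features: the trough voltage and
the voltages 250 µs (five datapoints at 20 kHz) before and after it.

A synthetic-recording generator (`generate_recording()`) with
ground-truth spike trains and a parametric laser-artifact model (harmonic
stack across the SUA band plus per-frame spike-like transients, peak
amplitude 50× the largest unit) makes every stage testable without
experimental data.

## Worked example

Sixty seconds, four channels at 20 kHz, two units (5 and 8 Hz), laser on
during the middle 30 s — the package's default study conditions. Takes
about two minutes.

```r
library(combspike)

cfg <- synth_config(seed = 42)          # 60 s, 4 channels, laser on 15-45 s
gen <- generate_recording(cfg)
gen$recording
#> <recording> 4 channel(s) x 1200000 samples @ 20000 Hz (60.000 s, t0 = 0 s)

res <- filter_recording(gen$recording, cfg$laser_on_interval)
res$specs[["ch1"]]
#> <comb_filter_spec> [ch1] D_F = 15.5 Hz, N_M = 3 modules, 174 elements, residual 12.60 uV
round(res$specs[["ch1"]]$residual_history, 1)
#> [1] 7097.0 3818.6 1453.0   12.6
```

The folded artifact amplitude on channel 1 falls from 7097 µV to 12.6 µV
in three modules (174 six-hertz notches on the 15.5 Hz harmonic grid);
the loop stopped because 12.6 < 40 µV. Detection and sorting on the
filtered data:

```r
ev <- detect_spikes(channel_signal(res$recording, "ch1"), 20000)
ev
#> <spike_events> 784 events (threshold -25.80 uV, 0 dropped at edges)
cl <- cluster_spikes(extract_features(ev), 2, waveforms = ev$waveforms)
cl
#> <cluster_set> 2 units, counts: 289, 492 (+3 noise)
```

The two clusters recover the generated 5 Hz and 8 Hz units (expected
~300 and ~480 spikes); three broadband laser-switching transients are
noise-labeled. Against the ground truth, detection on the laser-off
segments reaches recall 0.98 and precision 0.95, and the laser-on/off
comparison shows stable units:

```r
rp <- stability_report(ev$events$time_s[cl$labels > 0], cl$labels[cl$labels > 0],
                       extract_features(ev)[cl$labels > 0, ], 60,
                       segments = res$segments)
cc <- condition_compare(rp, res$segments)
cc$units[, c("unit", "rate_on", "rate_off", "rate_ratio",
             "d_v_trough", "d_v_pre5", "d_v_post5")]
#>   unit rate_on rate_off rate_ratio d_v_trough d_v_pre5 d_v_post5
#> 1    1    5.00     4.63      1.079      0.731    0.975     0.115
#> 2    2    7.87     8.53      0.922      1.993    1.724     0.248
```

Firing rates agree across laser conditions (ratios 1.08 and 0.92) and no
feature mean moves by more than 2 pooled SEMs — the laser artifact
neither distorts the sorted waveforms nor injects false-positive spikes.

A command-line front-end is installed at `inst/cli/combspike`
(`simulate`, `fit-filter`, `apply-filter`, `sort`, `report`), operating
on float32 flat-binary recordings with JSON sidecars.

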