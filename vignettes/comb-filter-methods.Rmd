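---
title: "Removing periodic imaging-laser artifacts from extracellular recordings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing periodic imaging-laser artifacts from extracellular recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Recording extracellular spikes with a microelectrode array while the
surrounding tissue is imaged with a two-photon microscope is compromised by
photoelectric artifacts: the scanning laser induces large periodic voltage
deflections on the electrodes. The artifact is periodic at the imaging
frame rate, its spectrum is a comb of harmonics with substantial power
throughout the 300--3000 Hz band in which single-unit activity (SUA) lives,
and its amplitude can be around fifty times that of the largest spikes. A
single notch or an ordinary band-stop filter cannot remove it; a *comb* of
narrow notches, placed on the measured harmonic frequencies of each
channel, can.

`combspike` implements that approach end to end: an iterative
parameter-setting algorithm that constructs a custom comb filter per
channel, zero-phase filtering, threshold spike detection, a three-feature
waveform representation for sorting, and a validation battery
(per-minute stability, laser-phase histograms, laser-on/off comparisons),
together with a synthetic recording generator that provides ground truth
for every stage.

## The comb filter and its parameter-setting algorithm

All filtering uses Chebyshev Type I IIR designs with a passband ripple of
0.4 dB, applied forward-backward (`zero_phase_apply()`) so the net phase
shift is zero and spike timing is preserved; the effective magnitude
response is the squared single-pass response. The recording is first
band-passed with a second-order 300--3000 Hz design (`bandpass_sua()`),
the standard SUA band.

A fitted comb (`CombFilterSpec`) is described by four parameters: the
inter-harmonic spacing $D_F$, the number of modules $N_M$, the module
center frequencies $f_{peak}$, and the number of band-stop elements per
module $N_F$. `fit_comb_filter()` constructs it from the band-passed
laser-contaminated signal as follows:

1. Estimate $D_F$ once from the initial magnitude spectrum
   (`estimate_comb_spacing()`): detect prominent peaks (local maxima above
   5 times the median in-band magnitude that are also the largest value
   within ±2 Hz) and take the median spacing of the strongest twenty.
   $D_F$ is then frozen; for a resonant scanner at the conditions modeled
   here it is 15.5 Hz, the imaging frame rate.
2. Apply the comb built so far (empty at first, leaving the data
   unchanged) and measure the residual periodic amplitude by period
   folding (`measure_periodic_amplitude()`): fold the signal into one
   artifact period, take the median across periods in each phase bin, and
   report the maximum absolute value of the folded waveform. If it is
   below 40 µV, the comb is final.
3. Otherwise recompute the spectrum of the residual and add one module
   (`build_filter_module()`): the global in-band maximum becomes
   $f_{peak}$; neighbors are scanned outward at $f_{peak} \pm n D_F$
   (each element is centered on the measured local maximum within one
   resolution bin of the nominal position) and covered while their height
   strictly exceeds 15% of the center peak, stopping at the first
   sub-threshold neighbor per side or at the band edge. Every covered
   peak receives a band-stop with cutoffs 3 Hz below and above it -- a
   6 Hz rejected band. Loop back to step 2.

The same comb is applied to the laser-free segments as well
(`apply_comb_filter()` with a segment table), so spike waveforms are
distorted identically in both conditions and their features remain
comparable -- the basis of the validation battery.

### Numerical choices

* **Band-stop element order 3.** Even-order Chebyshev Type I filters have
  a far-from-band gain of $-0.4$ dB, and a comb of ~170 elements applied
  zero-phase would attenuate the whole passband by $0.955^{348}\approx
  10^{-7}$, destroying the spikes. Odd-order designs have exactly unity
  far-field gain, so the cascade leaves the passband intact (gain ≈ 0.8 at
  an arbitrary in-band frequency, dominated by the near-notch ripple of
  the closest elements). The band-pass stays at order 2.
* **Second-order sections.** A 6 Hz notch at 20 kHz is a 6th-order
  transfer function whose direct-form polynomials nearly cancel; applied
  directly they leave a stationary narrowband numerical-noise floor of
  ~$10^{-4}$ µV and the cascade ceases to commute numerically. Every
  design is therefore factored into biquads. The notch zeros, a
  multiplicity-3 conjugate pair that root-finders recover poorly, are
  snapped to their analytically known position on the unit circle, which
  restores an essentially infinite notch depth; the response within ~1% of
  the band edges of a notch is accurate to about 1%. After this, applying
  elements in any order agrees to $10^{-12}$ µV RMS.
* **Edge padding.** Forward-backward filtering needs the signal extended
  at both ends. A fixed pad of 3 coefficient lengths is far too short for
  narrow notches, whose impulse responses ring for ~0.2 s (pole radius
  0.99975 at 20 kHz): the pad length adapts to the pole radius
  ($\lceil 8/(1-r)\rceil$ samples, capped at the signal length). Odd
  reflection -- the default -- additionally *flips the phase* of any
  strong in-notch periodic component at the boundary, which by itself
  excites hundreds of milliseconds of ringing. For comb application the
  signal is instead extended with a copy of itself shifted by a whole
  number of artifact periods (the shift chosen to minimize the fractional
  phase error), which keeps every harmonic phase-continuous; measured edge
  residuals drop from ~3500 µV to ~30 µV.
* **Period folding at full resolution.** The fold period
  ($f_s/D_F \approx 1290.3$ samples) is not an integer, so samples are
  assigned to phase bins; by default there is one bin per sample of the
  period. Coarse binning (say 64 bins, ~1 ms each) would smear
  sub-millisecond periodic residuals roughly twentyfold and allow the loop
  to terminate while large sharp periodic wavelets remain.
* **Termination guards.** The loop errors (carrying the partial comb and
  final residual) if 50 modules are reached or the residual improves by
  less than 1% over three cycles; on the synthetic conditions it converges
  in 3 modules / 4 cycles.
* **Incremental application.** Each cycle applies only the new module to
  the running residual; because zero-phase LTI elements commute this is
  equivalent to re-applying the full cascade to the original data, at a
  fraction of the cost.
* **Clean inputs.** If no periodic peak series is found in the initial
  spectrum (the spacings of the strongest peaks are not mutually
  consistent), the fit returns an empty comb ($N_M = 0$) rather than
  inventing notches.

## Spike detection, features, sorting

Detection is negative-going thresholding at $-k$ times the robust noise
SD (`median(|x|)/0.6745`), $k = 5$ by default; events align to the local
minimum within ±0.5 ms of the crossing and events closer than 1 ms merge
keeping the deeper trough. Each spike is reduced to three voltages: the
trough value and the values 250 µs -- five datapoints at 20 kHz -- before
and after it. These features track waveform consistency more directly
than PCA scores, which is what the stability analysis needs;
`pca_features()` provides the PCA alternative for comparison. (The
wording of the feature definition admits a second reading -- the *time
index* of the minimum rather than its value -- but three voltages are what
the feature plots show, so the value reading is implemented.)

Sorting is a deterministic k-means in the 3-feature space, initialized at
evenly spaced quantiles of the trough depth. Because forcing two
centroids onto a single unit would split it down the middle, cluster
pairs are merged when their centroid separation is below 3 in d′-style
units (separation over the root-sum-square of the robust projected
within-cluster spreads; MAD-based so that a handful of stray events, e.g.
laser switching transients, cannot inflate the spread). This automated
partition replaces manual accept/discard curation, which is out of scope.

Times are reported in seconds throughout (`time_s = (sample - 1)/fs`);
within R, sample indices are 1-based.

## The synthetic generator

`synth_config()` defaults define the validation conditions: 60 s at
20 kHz, 4 channels, two biphasic units (troughs 150 and 80 µV, distinct
shapes) firing at 5 and 8 Hz with a 2 ms dead time on every channel,
Gaussian noise of 10 µV SD, laser on during the middle 30 s.

The artifact model is strictly periodic at the 15.5 Hz frame rate and has
two components. The harmonic stack places cosines on the harmonic grid
*within* the 300--3000 Hz analysis band (indices
$k = \lceil 300/f_0\rceil \ldots \lfloor 3000/f_0\rfloor$), with
amplitudes decaying as $1/i$ across the series and the peak normalized so
that the artifact reaches `artifact_to_sua_ratio` (50) times the largest
template on the strongest channel; per-channel scale factors decline
across the array, as laser coupling differs between electrodes. Placing
the modeled series inside the analysis band reproduces the observed
spectral signature of the artifact -- harmonics of high magnitude
throughout the SUA band -- and is also a matter of internal consistency:
a low-frequency-dominant sawtooth of this amplitude would leave several
hundred µV of 230--300 Hz periodic residual that a second-order 300 Hz
band-pass barely attenuates (measured single-pass gain 0.95 at 294.5 Hz)
and that a 300--3000 Hz comb can never remove, so the 40 µV termination
rule could not be satisfied by *any* comb under those conditions. The
second component is one brief spike-like Blackman transient per frame:
5.5 ms wide, so that transients occupy about 8.5% of the signal, with a
default amplitude of 75 µV chosen so that what survives band-pass and
comb stays below the detection threshold -- matching the validated
outcome that the laser does not inject artifact spikes into the clusters.

What the generator does *not* emulate: line-scan substructure within a
frame, electrode drift, bursting or rate nonstationarity, waveform
overlap resolution, and any optical (calcium) signal. Passing tests
therefore demonstrate that the algorithm recovers its own model class --
a strictly periodic artifact plus stationary Poisson units -- not that it
handles every pathology of real recordings. Real laser switching also
produces brief broadband transients at the on/off boundaries; these
survive filtering (they are not periodic) and appear as a few outlier
events at the segment edges, which is why the robust variants of the
downstream statistics matter.

## Validation battery

`stability_report()` bins spikes into non-overlapping minutes and
tabulates counts and the mean ± SEM of each feature per unit;
`condition_compare()` expresses laser-on/off feature differences in
pooled-SEM units and reports per-unit rate ratios and autocorrelogram
differences; `laser_phase_histogram()` bins spike times by phase within
the artifact period (20 bins by default), using ground-truth frame onsets
when available or a period plus reference time otherwise. A chi-square
uniformity test (`phase_uniformity_test()`) flags phase-locked firing.

On the default synthetic conditions the pipeline terminates below
40 µV folded residual on all four channels, recovers the 15.5 Hz spacing
to within one frequency bin, suppresses the artifact harmonics by more
than two orders of magnitude, detects spikes with better than 90%
precision and recall, leaves per-unit features within 3 pooled SEMs
across laser conditions, and keeps laser-on spike counts inside the
Poisson envelope of the laser-off rate. The test suite computes all of
these; problem sizes (60 s / 4 channels for the end-to-end checks, 4--12 s
single-channel segments for unit-level checks) were chosen as the
smallest at which the spectral resolution and the period-folding
estimator operate comfortably.

## Known limitations

* The comb removes ~40% of the 300--3000 Hz band (174 elements × 6 Hz),
  so spike troughs shrink substantially (a 150 µV template comes out near
  90 µV); this distortion is identical across laser conditions by
  construction, but absolute amplitudes are not preserved.
* Laser on/off switching transients are broadband and survive filtering;
  a guard interval around transitions (or discarding boundary minutes, as
  the per-minute statistics naturally do) is advisable.
* The overall comb frequency range (300--3000 Hz) is fixed, not selected
  automatically, and residual spike-like artifacts synchronized with the
  laser period are not removed by a dedicated step; both are explicit
  non-goals here.
* D_F is estimated once and frozen; a drifting frame clock would require
  refitting per segment.
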