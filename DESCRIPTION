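Package: combspike
Title: Comb-Filter Removal of Periodic Imaging-Laser Artifacts from
    Extracellular Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and sorting extracellular single-unit
    activity recorded with microelectrode arrays while a two-photon imaging
    laser contaminates the signal with large periodic photoelectric
    artifacts. Implements an iterative parameter-setting algorithm that
    builds a custom-set comb filter per channel from the magnitude spectrum
    of the contaminated band-passed signal (modules of narrow 6 Hz
    zero-phase band-stop elements centred on the artifact harmonics),
    a period-folding estimator of the residual artifact amplitude used as
    the termination rule, threshold-based spike detection, a three-feature
    waveform representation for spike sorting, autocorrelograms, and a
    validation battery (per-minute spike stability, laser-phase histograms,
    laser-on/off comparisons). A synthetic recording generator with
    ground-truth spike trains and a parametric laser-artifact model makes
    the whole pipeline testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
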