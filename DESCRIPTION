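Package: owlcue
Title: Interaural Cue Reliability and Midbrain Spatial Tuning Analysis
Version: 0.1.0
Authors@R:
    person("Owlcue", "Maintainers", email = "maintainers@owlcue.org",
           role = c("aut", "cre"))
Description: Tools for analysing binaural spatial cues and auditory midbrain
    tuning in the barn owl. Estimates interaural phase difference (IPD)
    reliability across frequency and azimuth from head-related impulse
    responses (HRIRs) under concurrent-sound corruption, computes directional
    acoustic gain, simulates model space-map (ICx) neuron spatial tuning from
    per-frequency ITD/ILD cue fields, extracts tuning-curve metrics (best ITD,
    frequency bounds, frontal classification) from single-unit trial data, and
    compares neuron populations with nonparametric statistics (Mann-Whitney U,
    rank-biserial effect size) and pooled regressions. Includes parametric
    generators for "owl head" HRIR sets (with and without the facial ruff) and
    Poisson spike-count tuning curves with known ground truth, so the full
    pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
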