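---
title: "Interaural cue reliability and midbrain tuning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaural cue reliability and midbrain tuning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(owlcue)
```

## The scientific problem

Barn owls localize sound azimuth from the interaural time difference
(ITD), which their midbrain space map (the external nucleus of the
inferior colliculus, ICx) computes per frequency channel from the
interaural *phase* difference (IPD). In a natural scene a concurrent
sound ("masker") corrupts the IPD of a target; how badly depends on
frequency and on where target and masker are. The owl's facial ruff
boosts high-frequency gain for frontal directions, which makes
high-frequency IPD unusually robust — *reliable* — for frontal targets.
ICx neurons' frequency tuning tracks this reliability pattern, and the
package provides the computational side of that story: quantifying IPD
reliability from head filters, deriving the acoustic gain and ITD/ILD
cue fields those filters imply, predicting model-neuron spatial tuning,
extracting tuning metrics from (simulated) single-unit recordings, and
comparing neuron populations statistically.

## IPD reliability

For one head (an `hrir_set`) and one configuration
(`reliability_config`):

1. Per repetition, draw a fresh target and masker token (flat-spectrum
   0.5–10 kHz noise by default, or a vocalization surrogate).
2. For every pair (target azimuth, masker azimuth) on the elevation-0
   scan: render both sounds through the head, scale the masker by the
   masker/target *amplitude* ratio (default 1.0; 0.5 as an alternate),
   sum, and decompose with a gammatone filterbank (1–8 kHz, 0.2 kHz
   steps, order 4, ERB bandwidths).
3. Per band, the IPD is the lag of the maximum left–right
   cross-correlation within ±1 ms, scaled by 2π·f and wrapped to
   (−π, π]. The peak lag is refined by 3-point parabolic interpolation;
   without it the IPD is quantized to 2π·f/fs steps (π/2 per sample at
   f = fs/4), which collapses low-dispersion cells to zero circular
   spread.
4. Per (target azimuth, band): the circular standard deviation
   `sqrt(-2 log Rbar)` of the IPD across masker azimuths, averaged
   across repetitions. Reliability is its inverse, floored at
   `epsilon_sd` (default 10⁻³ rad) so it stays finite when corruption
   vanishes; unbounded dispersion (`Rbar → 0`) is capped at the value
   corresponding to `Rbar = 10⁻⁸`.
5. Per-owl maps are normalized per target azimuth (each azimuth's best
   band scores 1), then averaged across owls — in that order, which
   keeps owls with different absolute reliability from dominating. The
   reverse order is available via `normalize_and_average(...,
   normalize_first = FALSE)` but is not the default.

Conventions: positive azimuth = right of midline; positive ITD = right
ear leads (`t_left − t_right > 0`); positive IPD likewise; ILD is right
minus left in dB. The coincident target/masker azimuth is included by
default (`include_coincident_masker`): it contributes near-zero
dispersion equally everywhere and excluding it is a config flag.

## The synthetic owl head

`make_head_model_hrirs()` builds HRIR pairs as a per-ear fractional
delay (∓ITD/2) composed with a minimum-phase filter realizing a
closed-form magnitude model (`head_model_magnitude_db()`). Separating
the time cue from the level cues this way makes every downstream
estimator testable against closed forms. The model's terms:

* **ITD**: linear in azimuth at 3 µs/deg (the owl's measured relation;
  a spherical-head law adds nothing at this level of abstraction).
* **Ruff lobe** (ruff intact only): a gain boost of `A·w(f)·
  exp(−(az² + el²)/(2σ²))` on both ears, with A = 10 dB, σ = 30°, and
  `w(f)` a raised-cosine ramp from 4 to 5 kHz. This is the acoustic
  feature whose removal the ruff-removed condition models.
* **Low-frequency attenuation** (ruff intact only): −3 dB below
  ~2.5 kHz (ruff feathers absorb a little low-frequency energy).
* **Azimuthal head-shadow ILD**: `g(f)·sin(az)` with g growing to
  6 dB at 8 kHz; doubled in the ruff-removed condition, so ILD covaries
  with azimuth once the ruff is gone.
* **Elevational ILD** (ruff intact only): up to 10 dB × sin(el),
  growing with frequency — the ruff's asymmetry is what maps ILD onto
  elevation.
* **Per-owl ripple**: a smooth seeded ±1 dB gain ripple over frequency
  and azimuth, identical across conditions at the same seed, so that
  owls differ individually while condition differences remain exactly
  the closed-form ruff terms.

Magnitude values are plausibility-scaled: the model reproduces the
*qualitative* structure of owl head filtering, not any specific owl.
Deliberately absent: spectral notches and high-frequency measurement
irregularity, room acoustics, frequency-dependent ITD.

### What a green reliability test does and does not establish

At masker amplitude 1.0 the pipeline reproduces the expected pattern:
normalized reliability peaks at high frequencies for frontal targets
with the ruff intact, the ruff-removed maps shift toward lower
frequencies, and the largest reliability decreases concentrate at
(f > 4 kHz, |az| ≤ 40°). The same holds for the vocalization surrogate
(mean contrast; the concentration statistic there is marginal,
p ≈ 0.06). It does **not** hold at masker amplitude 0.5: with weak
corruption and the model's notch-free minimum-phase filters,
high-frequency bands are intrinsically reliable at *all* azimuths —
wider auditory bands average out target–masker interaction noise, so
the cross-correlation peak rarely leaves the target's lag — and the
frontal contrast needs corruption strong enough that the ruff lobe is
decisive. Real HRTFs carry high-frequency spectral irregularity that
penalizes high bands everywhere and is exactly what the synthetic head
omits. The corresponding acceptance assertions are left red rather than
retuning the generator; a green assertion here establishes a property
of the stated synthetic world, not of owl acoustics.

## Acoustic gain

`gain_map()` evaluates 20·log10 |DFT| of each HRIR (zero-padded to at
least 4096 points, nearest bin — bin error < 6 Hz, negligible against
200 Hz analysis steps) and reports the two-ear mean in dB (a flag
selects a single ear). 0 dB means "as if no head were present". Gain is
invariant to pure delays, so ITD handling cannot leak into it.

## The model ICx neuron

With tone frequency f, best ITD μ (0 µs for the frontal neurons of
interest), best ILD δ (0 dB), ILD width σ (dB²) and peak rate
a_max = 10 spikes/s:

* ITD response: `a_max · (exp(cos(2π f (ITD − μ))) − e⁻¹) / (e − e⁻¹)`
  — a von-Mises-like curve, periodic with period 1/f (the phase
  ambiguity of narrowband ITD detection), peaking at a_max and touching
  0 at the antiphase ITD.
* ILD response: `a_max · exp(−(ILD − δ)²/σ)` — Gaussian with
  half-height at δ ± √(σ ln 2).

The printed source for these equations is typographically garbled; this
interpretation is fixed by the stated boundary behaviour (both curves
peak at exactly a_max, the ITD curve is cyclic in f·ITD) and by the
half-height convention for σ. σ has no published value; the default 50
dB² (half-height full width ≈ 11.8 dB, typical of ICx ILD curves) is
exposed in `model_neuron_params()` and flagged as unconstrained.

`cue_field()` extracts per-direction ITD (narrowband cross-correlation
of gammatone-filtered HRIRs at f, ±1 ms) and ILD (right minus left DFT
magnitude at f). Cross-correlation rather than unwrapped phase is
deliberate: the model's cyclic ITD response absorbs the phase ambiguity
that narrowband ITD extraction necessarily has. `spatial_tuning_map()`
multiplies the two responses (the established ICx combination rule) and
normalizes the map maximum to 1; the default tone set is 3–7 kHz in
1 kHz steps, the range where tuning changes are observed.

## Tuning metrics from trial data

* **Best ITD / ITD width**: a 4-parameter Gaussian (amplitude, centre,
  sd, baseline) least-squares fitted to the *main peak only*. The main
  peak region surrounds the global maximum of the 3-point smoothed
  curve and is bounded by flanking minima found with a noise-tolerant
  outward walk (descend through fluctuations; stop when the curve rises
  ≥ 15% of its range above the running minimum — the flank of a side
  peak). Best ITD = fitted centre; width = FWHM = 2√(2 ln 2)·sd (the
  width convention is ours; the source metric is unspecified).
  Non-convergent fits raise rather than return numbers.
* **Frequency bounds / best frequency**: the responsive range is where
  the mean rate exceeds 50% of its maximum; the bounds are the
  outermost half-height crossings with linear interpolation between the
  200 Hz samples (without interpolation, best frequency quantizes to
  100 Hz multiples), ignoring sub-threshold dips in between. Best
  frequency = midpoint of the bounds — ICx curves are broad and often
  flat-topped, so the midpoint, not the argmax, is the robust summary.
  No baseline subtraction is applied before the 50% criterion (a flag
  could add it; the source is silent).
* **Frontal**: |best ITD| ≤ 30 µs, boundary inclusive (≈ ±10° at
  3 µs/deg).

## Population statistics

Pooled per-group Pearson regressions (p from the correlation t with
n − 2 df); slope and intercept comparisons by the two-regression
Student's t with pooled residual variance and n₁ + n₂ − 4 df;
Mann–Whitney U with ties counted 0.5, reported as min(U₁, U₂) — the
convention under which the published U values are consistent with their
effect sizes — with exact two-sided p when n₁·n₂ ≤ 400 without ties and
a tie/continuity-corrected normal approximation otherwise; rank-biserial
effect size r = |1 − 2U/(n₁n₂)| on the 0–1 scale (direction reported
separately as a sign field).

## Synthetic neurons

`simulate_tuning_curves()` draws Poisson spike counts around ground
truth rates: a Gaussian ITD main peak with side peaks at ±1/f at a
suppressed amplitude ratio (default 0.5 — ICx side peaks are
suppressed); a trapezoidal frequency profile whose half-height
crossings sit *exactly* at the stated bounds (so the frequency metrics
have closed-form truth); a Gaussian ILD curve. Defaults: 20 trials per
value, 100 ms counting window, 1 Hz baseline / 60 spikes/s peak —
typical ICx single-unit numbers; the tonal protocol covers 0.5–10 kHz
in 200 Hz steps, ITD ±300 µs in 10 µs steps. These rates put per-value
standard errors near 5 spikes/s, which is what makes the stated
recovery targets (median best-frequency error ≤ 150 Hz, best-ITD error
≤ 10 µs) demanding but attainable.

## Numerical choices

* Gammatone filters are FIR truncations of the analytic impulse
  response (length set by envelope decay to ~10⁻⁴), applied by FFT
  convolution; band transfer functions are reused so the reliability
  engine computes each band's cross-correlation as one inverse FFT of
  the broadband cross-spectrum times |G_b|².
* Minimum-phase realization by real-cepstrum folding on a 4× zero-padded
  grid; magnitudes floored at −160 dB before the log.
* Fractional delays by frequency-domain phase ramp with a quarter-length
  causal bulk delay.
* Cross-correlation ties resolved to the first (most negative) lag;
  sub-sample refinement clamped to ±0.5 samples.
* Pipeline stage seeds are fanned out from the global seed by a
  counter scheme (`seed·131 + stage·1009`, kept below 2³¹), so stages
  rerun independently and reproducibly; stimulus tokens depend only on
  (config seed, repetition), making condition comparisons paired.

## Known limitations

* The synthetic head is spectrally clean; see above for the
  consequences at weak masker corruption.
* Reliability maps are elevation-0 only (as measured); raw ITD
  reliability across frequency is intentionally not computed — IPD is
  the comparable quantity across bands.
* The real-recording regression numbers (r², intercepts) require the
  original electrophysiology and HRTF measurements and are out of
  scope; the package reproduces the self-contained arithmetic (effect
  sizes, conversions) exactly and the acoustic phenomenology
  qualitatively.
* SOFA reading requires a Python interpreter with h5py on the PATH (no
  HDF5 reader is available in this R stack) and is read-only.
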