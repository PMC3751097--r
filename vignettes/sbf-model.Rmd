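---
title: "The striatal beat-frequency model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The striatal beat-frequency model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sbftiming)
```

This vignette documents the model implemented by **sbftiming**, the
numerical and estimator choices behind it, and the places where the design
was genuinely open and a convention had to be fixed.

## The model

The SBF (striatal beat-frequency) architecture times an interval by
coincidence detection. A bank of `n_osc` oscillators with base frequencies
`f_k = f1 + k·df`, `df = (f2 − f1)/n_osc` (so the upper bound `f2` is
attained; `oscillator_bank()`), is reset to a common phase at trial onset —
the "start gun". The memory block stores each oscillator's state at the
reinforced criterion time `c`; under memory noise it stores `Nc` samples at
`c̃_i = c(1 + x_i)`. The decision block projects the running state onto the
stored state:

    output(t) = Σ_k [Σ_i ψ_k(c̃_i)] · ψ_k(t),

where `ψ_k` is the oscillator waveform (a cosine, or a normalised
Morris-Lecar membrane-potential cycle). Beats between nearby frequencies
let the bank time durations far beyond any single oscillator period; the
usable range is bounded by the grid recurrence `1/df` (see *Timing
capacity* below).

Two analytic facts organise everything the package computes:

1. **No noise ⇒ no scalar property.** The noiseless cosine output is a
   Dirichlet kernel, `½·sin(πn·df·u)·cos(π(2f1+(n+1)df)u)/sin(π·df·u)`
   with `u = t − c` (plus a mirrored branch at `u = t + c`). Its width
   solves `sin(πn·df·w/2)/sin(π·df·w/2) = n/2` (`noiseless_width()`) and
   depends only on the bank geometry, not on `c`. Note the exact carrier
   under the `k = 1..n` index convention is `2f1 + (n+1)df`; the
   equivalence of the closed form with the direct double sum to 1e−8 is a
   standing test.
2. **Any memory noise ⇒ Gaussian, scalar output.** The noisy output is a
   superposition of kernels at the sampled criteria. Its envelope is a
   smooth single bump centred on `c` whose width is set by the criterion
   spread `level·c` — hence grows linearly in `c` with a slope
   proportional to the noise level, for *any* noise distribution.

## Oscillators

*Cosine bank.* `cos(2πf_k t)`; phase zero at reset.

*Morris-Lecar bank.* The dimensionless two-variable conductance model
(membrane potential `x1`, slow potassium activation `x2`) with the standard
constants (`e_ca = 1.0`, `e_k = −0.7`, `e_l = −0.5`, `v1 = −0.01`,
`v2 = 0.15`, `v3 = 0.1`, `v4 = 0.145`, `g_k = 2.0`, `g_l = 0.5`,
`xi = 1/3`). `g_ca = 1.0` gives Type 1 excitability (oscillatory for bias
currents `i0` in ≈ (0.083, 0.242), verified by `find_oscillatory_range()`);
`g_ca = 0.5` gives Type 2, oscillatory for `i0` in ≈ (0.138, 0.305) as
determined empirically — the package scans rather than asserts this range.
Type 2 is the default time base because its membrane waveform is closest to
a cosine.

Integration is fixed-step classical RK4 (compiled), default `dt = 0.025`
(several hundred steps per period; terminal-state Richardson ratios ≈ 16
under step halving are a standing test). Periods are measured as the mean
spacing of upward mean-crossings with sub-step interpolation, after
discarding the first 20% of the trace or five periods, whichever is longer;
the mean-crossing criterion is robust for both spike-like and sinusoidal
waveforms.

### Hz calibration

The model's frequencies are stated in Hz but the Morris-Lecar equations are
dimensionless, so a mapping had to be fixed: a single bank-wide
`time_scale` (seconds per dimensionless unit) chosen so the geometric mean
of the attainable dimensionless rate span maps to the geometric mean of the
Hz range, with per-neuron bias currents set by monotone bisection to 0.5%
rate tolerance. The Type 2 regime's rate span (≈ 0.052–0.167 cycles per
unit, a 3.2× ratio) comfortably covers the 11.5/5.5 ≈ 2.1× Hz ratio, so
the per-neuron time-scale fallback is implemented but not exercised by the
default bank.

### Stored waveforms

Each calibrated neuron's limit cycle is stored once (2048 samples per
period, phase zero at the potential maximum — all neurons start in phase at
`t = 0`) and states at arbitrary times are read out by periodic phase
lookup; for a deterministic limit cycle this is exact, and ~1000× cheaper
than storing full trial-length traces. Two processing steps matter:

* **Cycle-mean removal.** Unlike a cosine, the ML waveform has a non-zero
  DC component; left in place it adds an `Nc`-proportional pedestal to
  every dot product that swamps the coincidence peak. Waveforms are
  therefore centred before peak-normalisation.
* **Quadrature companion.** The Hilbert transform of each waveform is
  stored alongside it to support the retained-branch readout (below).

## The readout and its branches

The plain dot product of real states contains, for every harmonic, both a
`t − c` term and a mirrored `t + c` term. The analysis of the model always
uses the physically meaningful `t − c` branch; numerically the mirrored
branch matters because the bank's `1/df` recurrence folds it back into the
observation window (images at `t = −c̃ + m/df`; for the 600-neuron bank,
at `100 − c` seconds) once criteria approach the timing capacity.
`sbf_output(branch = "retained")` therefore projects with the analytic
(in-phase + quadrature) representation, which keeps exactly the `t − c`
component for arbitrary waveforms; for cosine banks it reproduces the
closed-form retained branch to 1e−11. The cosine experiments use the
closed form directly (`memory_noise_output()`); the ML experiments use the
retained-branch projection.

## Timing capacity

An evenly spaced bank cannot distinguish times separated by `1/df`: the
kernel recurs. The standard bank geometries sit exactly at this design
boundary — 1000 cosine oscillators over 5.5–11.5 Hz give `1/df = 167 s`,
600 ML neurons give `100 s`, against criteria up to 90 s. Scaled-down
banks in the test suite shrink the criteria proportionally
(`scaled_criteria()`), otherwise the burst washes out — a real property of
the model, not an implementation artefact.

## Noise

`noise_spec(family, level, n_samples, seed)` treats `level` as the
*relative standard deviation* of the multiplier `1 + x` for every family
(uniform half-width `level·√3`), so levels are comparable across
distributions. Non-positive sampled criteria (possible at high uniform
levels) are resampled with the count recorded. Memory noise enters through
the stored criteria; frequency noise averages the output over `n_samples`
full bank draws, each with its own reference and running weights. All
draws are reproducible under the spec's seed, and experiment runners put
the whole run under `withr::with_seed(config$seed, ...)`.

## Envelope estimation and Gaussian fitting

Once `level·c` exceeds the carrier period, the per-sample kernels are
carrier-incoherent and the realised output is a noise burst: its
instantaneous amplitude fluctuates with Rayleigh-scale scatter, and the
hull of raw local maxima caps Gaussian-fit r² near 0.7 regardless of how
finely one simulates. `burst_envelope()` therefore uses the standard RMS
amplitude envelope: the criterion samples are split into 50 consecutive
batches (`keep_batches`), the per-batch output powers are averaged
(independent looks at the same ensemble; no extra simulation cost),
smoothed by a moving average of half the a-priori width estimate
`sqrt((level·c)² + σ_kernel²)`, and square-rooted.

`fit_gaussian()` is Levenberg-Marquardt least squares of
`A·exp(−(t−μ)²/(2σ²))` (optionally plus a non-negative floor) with start
values from the envelope's half-maximum crossings, parameter bounds inside
the fit window, and a small set of deterministic restart perturbations
(LM's parameter scaling is singular for exactly-zero starts). The fit
window is `c ± 3·sqrt(σ_noiseless² + (level·c)²)`; using the *noiseless*
width alone would truncate noise-broadened peaks. A fitted centre pinned
at the window boundary is reported as a failed fit — monotone or peakless
input cannot silently pass.

Two estimator-level facts are worth knowing when interpreting results:

* **Amplitude vs power conventions.** The RMS amplitude envelope of an
  incoherent burst is the square root of the criterion density convolved
  with the squared kernel, so for normal noise its Gaussian σ is
  `√2·sqrt((level·c)² + σ_K²)` — the width-versus-criterion slope is
  ≈ `√2·level`. Fitting the *power* envelope instead would halve the
  log-width, giving slope ≈ `level`. The package reports the amplitude
  convention (σ of the Gaussian fitted to the envelope); regressions,
  r² and slope *ratios* across noise levels are unaffected by the choice,
  but absolute slopes scale with it.
* **Uniform noise is only approximately Gaussian.** The uniform-criterion
  envelope is a kernel-rounded box; its best-possible Gaussian fit has
  r² ≈ 0.88 once the box dominates the kernel width. The Gaussianity of
  the output is a large-`Nc` statement about the value distribution at
  each time point, not a claim that every envelope shape is exactly
  Gaussian.

Additionally, the fitted centre tracks the *sample mean* of the stored
criteria, which deviates from `c` by `level·c/√Nc` (≈ 0.013 s at
`c = 30 s`, 1% noise, `Nc = 500`) — the precision floor of any centre
estimate from one session's samples.

## Width conventions and the analytic width equation

The reported width is the Gaussian σ; where a half-maximum width is needed
it is converted via `FWHM = 2σ·sqrt(2·ln 2)`. `solve_scalar_width()`
implements the mean-value-theorem width equation: with `θ` a mean-value
abscissa of the noise distribution (default: the mean of `|x|`,
`level·√(2/π)` normal, `level·√3/2` uniform), the dimensionless half-width
`y0` solves `K(cθ(1−y0)) = K(cθ)/2` for the composite kernel `K`; the first
sign change in `y ∈ (0, 1)` is bracketed by a dense scan and polished to
residual < 1e−10. The width law `σ = 2cθ·y0` is linear in `c` by
construction once `y0` is fixed — `predict()` evaluates it at other
criteria; the residual dependence of `y0` itself on the product `cθ` is
weak and is reported rather than hidden.

## Experiment defaults (the study conditions)

* Cosine experiments: 1000 oscillators over 5.5–11.5 Hz (matching the ML
  range keeps widths comparable), criteria {30, 60, 90} s.
* ML experiments: 600 Type 2 neurons over 5.5–11.5 Hz, criteria
  {30, 45, 60, 75, 90} s (five points give a meaningful OLS slope and
  standard error), normal memory noise at levels {0.001, 0.01, 0.1},
  `Nc = 500` stored samples (Monte-Carlo error of σ well below
  inter-criterion differences).
* Time grids: step `min(1/(20·f2), c/2000)` (resolves the fastest
  oscillator and the envelope), window `c ± 6` width-estimates, aligned so
  `c` lies on the grid.

With these sizes a full three-level ML sweep (calibration included) takes
well under a minute on one CPU; the whole test suite runs in about a
minute.

## What the generator does and does not emulate

The synthetic experiments implement the model's own idealisations: exact
frequency grids, perfect phase reset on every trial, stationary noise,
read-out without response thresholds or motor variability. Passing tests
therefore validate the model's internal claims (closed forms, width laws,
pdf-independence, noise-level scaling) — they do not validate the SBF
hypothesis against behavioural or electrophysiological data, and the
behavioural-data side of the scalar property is out of scope. Plasticity
of the weights, synaptic coupling between oscillators, stochastic
ion-channel gating and neuromodulator dynamics beyond the phase reset are
likewise not modelled.

## Known limitations

* High-`h` harmonic recurrences of the ML kernel produce faint ghost
  structure at `m/(h·df)` offsets even with the retained branch; they are
  negligible for the Type 2 waveforms used here but would grow for
  spike-like (Type 1) waveforms.
* The bisection calibration assumes the rate-versus-bias curve is monotone
  within the scanned regime (it is, for both presets, on the scanned
  grids; a warning is emitted otherwise).
* At 10% noise and `c = 90 s` the burst occupies a large fraction of the
  timing capacity; widths there carry a few percent of capacity-edge bias.
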