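# sbftiming

Simulation and analysis toolkit for the **striatal beat-frequency (SBF)
model of interval timing** — the hypothesis that animals time
seconds-to-minutes durations by coincidence detection among cortical
oscillators, read out by striatal neurons against a memorised oscillator
state. The package is aimed at computational neuroscientists studying why
timing behaviour is both *accurate* (responses peak at the trained
criterion time) and *scalar* (the spread of responses grows linearly with
the timed duration, so normalised response curves superimpose).

## The model

A bank of `N` oscillators with equally spaced frequencies
`f_k = f1 + k·df`, `df = (f2 − f1)/N`, is reset to a common phase at trial
onset. The memory stores the oscillator states at the reinforced criterion
time `c`; at decision time the running states are projected onto the stored
ones:

```
output(t) = Σ_k w(k, c) · w(k, t)
```

For noiseless cosine oscillators this sum has the closed Dirichlet-kernel
form `½ sin(πN·df·u) cos(π(2f1 + (N+1)df)u) / sin(π·df·u)` with `u = t − c`:
a sharp peak at `t = c` whose width depends only on the frequency range and
bank size — **not** on `c`, violating the scalar property. When the stored
criterion fluctuates (`c̃ = c(1 + x)`, `x` a zero-mean random variable of
relative standard deviation `level`), the output becomes a burst of kernels
whose Gaussian-fitted envelope width grows linearly with `c`, for *any*
noise distribution — the scalar property emerges from noise.

The package provides:

* cosine phase-oscillator banks and dimensionless **Morris-Lecar**
  conductance-based neurons (Type 1 and Type 2 excitability), with a
  compiled fixed-step RK4 integrator, period measurement, oscillatory-regime
  scans, and Hz calibration of whole banks;
* coincidence-detection outputs (dot product or cosine-angle similarity),
  with memory and frequency noise, closed-form noiseless outputs, and a
  retained-branch (analytic-signal) readout;
* envelope analyses: Dirichlet envelope and its half-maximum width, the
  envelope-maxima equation `tan(Nx₀) = N·tan(x₀)`, RMS burst envelopes,
  Gaussian least-squares fits, width-versus-criterion regressions, the
  mean-value-theorem width equation, and superposition reports;
* experiment runners with YAML configs, seeded reproducibility, CSV/JSON
  export (`write_experiment_bundle()`), ggplot2 `autoplot()` methods and
  broom-style `tidy()`/`glance()`.

## Worked example

```r
library(sbftiming)

# noiseless cosine bank: accurate but not scalar
ex <- run_noiseless_sbf(experiment_config(criteria = c(30, 60, 90)))
ex$widths
#>   criterion  sigma width_halfmax  peak
#> 1        30 0.0832         0.196   500
#> 2        60 0.0832         0.196   500
#> 3        90 0.0832         0.196   500
```

All three outputs peak exactly at their criterion with amplitude
`N/2 = 500`, and the half-maximum width (0.196 s; the closed-form solver
gives 0.201 s) is identical at 30, 60 and 90 s — constant width, no
scalar property.

```r
# 1% uniform memory noise: the scalar property emerges
cfg <- experiment_config(criteria = c(30, 60, 90),
                         mem_noise = noise_spec("uniform", 0.01, 500),
                         seed = 1)
exn <- run_memory_noise_sbf(cfg)
glance(exn$regression)
#>    slope  slope_se intercept    r2
#> 1 0.0141 0.0000576    0.0374 1.000
```

The fitted envelope width now grows from 0.46 s at `c = 30` to 1.31 s at
`c = 90` — linear in the criterion (slope ≈ √2 × noise level, r² = 1.00).
The same experiment with normally distributed noise gives the same slope:
the scalar property is independent of the noise distribution.

The biophysical version replaces cosines by 600 calibrated Type 2
Morris-Lecar neurons spanning 5.5–11.5 Hz
(`run_ml_sbf()`); sweeping memory noise over 0.1%, 1% and 10% yields
width-versus-criterion slopes of about 0.001, 0.014 and 0.15 — a ten-fold
slope increase for a ten-fold noise increase.

A thin command-line front end is installed at `inst/cli/sbf.R`
(`Rscript inst/cli/sbf.R ml --seed 1 --out results/`).

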