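# lassa

Heart-rate extraction from remote photoplethysmography (rPPG) traces by
singular spectrum analysis with low-rank and autocorrelation guided
component selection.

## The problem

A camera pointed at a face records a tiny periodic color fluctuation of
the skin driven by the blood volume pulse.  The spatially averaged green
channel of the facial skin region carries that pulse, buried under
baseline drift from illumination changes, transient spikes from facial
motion, and broadband sensor noise.  `lassa` denoises such a trace and
reads out heart rate per sliding analysis window, for researchers working
on camera-based vital-sign measurement who need a transparent, fully
scriptable reference pipeline.

## The method

Per 30 s window (1 s step), the preprocessed trace
(smoothness-prior detrending → standardization → 5-point moving average →
EEMD with pulse-band mode selection) is embedded in the Hankel trajectory
matrix *X* (window length *L* = 3 s of samples) and decomposed by SVD:

    X = Σ_{i=1}^{d} λ_i u_i v_i^T

Two screens then pick the components to keep:

1. **Global** — the number *s* of retained leading components is the rank
   of the low-rank part *A* of the robust-PCA split
   `min ‖A‖* + η‖E‖₁ s.t. X = A + E`, solved by the exact augmented
   Lagrange multiplier method (η = 1/√max(m,n)).
2. **Local** — each retained component series *z_i* (by diagonal
   averaging) is kept only if its maximum autocorrelation coefficient
   ρ_i — the largest interior peak of the biased normalized
   autocorrelation, P(0) = 1 — exceeds 0.85.

The kept set *S* is recombined with singular-value-proportional weights,
`x_rc = Σ_{i∈S} w_i z_i`, `w_i = λ_i / Σ_{j∈S} λ_j`, and heart rate is
60× the in-band (0.7–3 Hz) spectral argmax of `x_rc`.  Agreement with a
reference PPG channel is reported as MAE, RMSE, Pearson r, and
Bland-Altman limits (±1.96 σ).

See `vignettes/lassa-methods.Rmd` for the full account of the model,
parameter defaults, and numerical choices.

## Worked example

```r
library(lassa)

# 2 minutes of simulated pulse at 72 bpm with drift, motion artifacts
# (6/min) and noise, then the full pipeline:
sim <- simulate_pulse_trace(pulse_sim_config(
  duration_s = 120, fps = 30, hr_bpm = 72,
  drift_amplitude = 2, artifact_rate = 6, noise_sigma = 0.3, seed = 11))

res <- run_lassa(sim$trace, seed = 11)
res
#> <lassa_result> 91 windows, method lassa, median HR 72.1 bpm

evaluate_hr(res$hr, true_hr_windows(sim))
#> <eval_report> n=91 windows
#>   MAE  0.09 bpm
#>   RMSE 0.10 bpm
#>   r    NA
#>   Bland-Altman 0.01 [-0.19, 0.20] bpm
```

The mean absolute error of 0.09 bpm says every one of the 91 windows
recovered the simulated 72 bpm rate to within a fraction of a spectral
bin (0.22 bpm) despite the injected disturbances; Pearson r is undefined
here because the true rate is constant.  `run_lassa(..., ablation =
TRUE)` additionally returns the readouts of the two ablated chains (raw
filtered trace, EEMD-only) for comparisons, and
`recovery_benchmark()` sweeps this experiment over seeds.

A command-line front end wrapping the same functions ships in
`inst/cli/lassa.R`:

```sh
Rscript inst/cli/lassa.R simulate --preset noisy --duration 120 --seed 11 --out trace.csv
Rscript inst/cli/lassa.R run --trace trace.csv --seed 11 --out outdir
Rscript inst/cli/lassa.R eval outdir/hr.csv ref_hr.csv
```

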