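# clotwave

Estimating plasma fibrinogen concentration (g/L) from optical clot
waveforms — the transmitted-light traces that coagulometers and plate
readers record anyway while running prothrombin-time (PT), Reptilase-time
(RT) or thrombin-generation (TG) assays.

The package is aimed at coagulation-lab methodologists and modellers who
want to prototype waveform-based fibrinogen estimation end-to-end without
patient data: every component can be driven by a built-in, seeded synthetic
cohort whose defaults emulate a realistic diagnostic mix (44 samples,
fibrinogen 1.1–16.6 g/L, VKA-, heparin- and D-dimer-challenged subsets).

## What it computes

**Mechanistic route (TG + turbidity).** A 144-state mass-action model of
fibrin polymerization — 12 enzymatic states (fibrinopeptide A/B release via
enzyme–substrate complexes, FXIII activation, enzyme inhibition) and 132
polymer states (oligomer ladder O₂…O₁₂₁ ending in the mature protofibril,
plus lateral fiber bundles B₂…B₁₃) — is driven by the sample's own measured
thrombin curve. Light attenuance follows the thin-rod Carr–Hermans
relation τ ∝ Σₖ cₖ·µₖ (fiber mass concentration × mass/length ratio,
µₖ = k·µ_pf). Simulating over a fibrinogen grid yields a strictly
increasing *reference curve* of maximum attenuance increase vs fibrinogen;
the measured turbidity signal is projected onto it by monotone
interpolation. Atypical inputs (thrombin peak < 10 nM, attenuance increase
< 0.02) are QC-flagged, never estimated; out-of-range signals are refused,
never extrapolated.

**Statistical route (PT/RT).** Four waveform features — minimum
transparency, maximum |gradient|, maximum and minimum second derivative
(Savitzky–Golay) — feed a multivariate linear regression and a 4-3-1 tanh
network trained with full-batch Adam (Keras-default hyperparameters,
standardized inputs). A combined rule gates on the network's own
prediction: ≥ 6 g/L takes the network, below takes the regression.
Evaluation is leave-one-out with Pearson r and anticoagulation-strata
filters.

Also included: a clot-waveform plot digitizer (fixed 0–60 s / 0–4000 mA
axes, Otsu dark-pixel threshold, per-column centroid extraction), CSV/JSON/
YAML I/O for waveforms, reference curves, models and parameter sets, and a
CLI (`inst/cli/clotwave`) over the same functions.

## Worked example

```r
library(clotwave)

# one synthetic sample: truth 3.2 g/L, TG + PT waveforms, seeded
rec <- synth_sample(3.2, "DEMO", assays = c("TG", "PT"), seed = 11)

# mechanistic route: per-sample reference curve, then projection
est <- infer_fibrinogen_tg(rec, fib_grid = c(1, 2, 3, 4, 6, 9),
                           t_grid = seq(0, 600, 10))
est
#> <tg_estimate> qc=ok fibrinogen=3.34 g/L (peak thrombin 115.1 nM, max dA 0.3477)

# statistical route: the four PT waveform features
extract_features(rec$waveforms$pt)
#> <feature_vector>
#>      t_min      g_max     d2_max     d2_min
#> 2412.22332   68.19731   14.19545  -21.96293

# leave-one-out over a small cohort
coh <- synth_cohort(cohort_config(n = 12, seed = 3), assays = "PT")
ps  <- loo_evaluate(coh, "PT", train_config(seed = 5))
pearson_eval(ps, "combined")
#> combined LOO Pearson r = 0.945 (p = 3.6e-06, n = 12)
```

The TG estimate of 3.34 g/L against a truth of 3.2 g/L reflects the 1%
instrument noise and the coarse demonstration grid; on the default 0.5 g/L
grid with noiseless input the round trip is exact to < 2%. The feature
vector reads: the well bottomed out at 2412 mA (from 4000), fastest
clouding 68 mA/s, with the acceleration extremes bracketing the clotting
transition.

## Layout

```
R/                  waveform representation + features, polymerization ODE
                    model, TG reference-curve inference, estimators + LOO,
                    synthetic cohort, I/O + digitizer + CLI
tests/testthat/     unit, property and whole-pipeline suites
vignettes/          methods vignette (model, assumptions, design choices)
scripts/            acceptance.R
inst/cli/           clotwave CLI wrapper
```
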