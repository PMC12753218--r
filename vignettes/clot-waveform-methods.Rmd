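---
title: "Estimating fibrinogen from clot waveforms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fibrinogen from clot waveforms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clotwave)
```

## The problem

Plasma fibrinogen is routinely measured with the Clauss assay, but every
optical coagulometer already records a richer signal for free: the clot
waveform, the transmitted-light trace acquired while a prothrombin-time (PT)
or Reptilase-time (RT) test clots, and — on plate readers — the turbidity
curve acquired alongside a thrombin-generation (TG) measurement. This
package implements two complementary routes from those waveforms back to a
fibrinogen concentration in g/L, plus everything needed to exercise them
end-to-end without patient data: a mechanistic forward model, a synthetic
cohort generator, and a digitizer for waveforms that only exist as printed
plots.

## The mechanistic route (TG + turbidity)

### Forward model

The forward model is a mass-action ODE system for fibrin polymerization with
144 states: 12 in an enzymatic block and 132 in a polymer block.

The enzymatic block covers the classical proteolytic steps. The driving
enzyme E (thrombin, or batroxobin in RT mode) reversibly binds fibrinogen
and releases fibrinopeptide A to give fibrin I; binds fibrin I and releases
fibrinopeptide B to give fibrin II; activates factor XIII; and is inhibited
first-order. The twelve species are fibrinogen, E·fibrinogen, fibrin I,
FpA, E·fibrin-I, fibrin II, FpB, FXIII, E·FXIII, FXIIIa, free enzyme and
inhibited enzyme. The free enzyme is an *exogenous input*, clamped to the
driving curve (a measured or synthetic thrombin trace, a constant batroxobin
level, or a saturating tissue-factor burst); its own state is carried for
completeness with zero derivative. In RT mode fibrinopeptide B release is
forced off — batroxobin only cleaves fibrinopeptide A — which the tests
verify as an exact invariant (`FpB` identically zero).

The polymer block is a nucleation–elongation–lateral-aggregation ladder.
Fibrin II monomers (and fibrin I at relative efficiency `eps_I`) nucleate
dimers at rate `k_nuc` and elongate oligomers `O_j + M -> O_(j+1)` at rate
`k_poly` up to the mature protofibril `O_121`; protofibrils aggregate
laterally, `B_k + O_121 -> B_(k+1)` (with `B_2` from two protofibrils), up
to `K_max = 13` protofibrils per fiber. That sizing — 120 oligomer species
plus 12 bundle species — gives the 132 polymer states.

Two structural choices deserve emphasis:

* **Nucleation must be much slower than elongation.** The mean ladder length
  self-limits near `sqrt(k_poly / k_nuc)`; if dimerization ran at the
  elongation rate the monomer pool would be exhausted into short oligomers
  and no protofibril would ever mature. The default `k_nuc = 1e-4`
  1/(µM·s) against `k_poly = 4` keeps the mean length well above the
  ladder, so essentially all clottable protein reaches fibers across the
  whole 0.5–12 g/L working range. This mirrors the classical
  initiation/elongation picture of fibrin assembly.
* **Fibrin I polymerizes at `eps_I = 0.5` relative to fibrin II.** desA
  monomers (the only species RT mode produces) polymerize more slowly than
  desAB monomers but must still clot within the 60-s RT acquisition
  window; 0.5 achieves realistic RT clotting times (~20–40 s) at normal
  fibrinogen.

Rate constants for the enzymatic steps are literature-plausible for
thrombin (fast FpA release, roughly tenfold slower FpB release); they are
parameters of a `kinetic_parameters()` object, serializable to YAML/JSON,
not measured claims. Integration uses `deSolve::ode` (lsoda, stiff-capable)
at `rtol = 1e-6`, `atol = 1e-9`; solver-scale negative excursions are
clipped at the absolute tolerance. Fibrinogen-equivalent mass — the
monomer-weighted sum over fibrinogen, complexes, monomers, `j·O_j` and
`121·k·B_k` — is conserved along every trajectory to well below 1e-6
relative, which the acceptance suite rechecks.

### Turbidity output

Light attenuance follows the thin-rod (Carr–Hermans) relation: turbidity is
proportional to fiber mass concentration times mass/length ratio,

τ = (88/15) π³ n_s (dn/dc)² / (N_A λ³) · Σ_k c_k µ_k,

with µ_k = k·µ_pf for a k-protofibril bundle (µ_pf = 1.5e11 Da/cm), n_s =
1.333, dn/dc = 0.176 mL/g, λ = 450 nm, converted to decadic attenuance over
a 0.5 cm path. Oligomers below protofibril maturity carry optical weight 0
by default (`oligo_weight`): thin protofibrils scatter negligibly compared
with laterally aggregated fibers. A lumped geometric prefactor `C_geom = 4`
calibrates the output once so that 3 g/L of fully clotted fibrinogen gives a
maximum attenuance increase near 0.3 — the magnitude a plate reader reports
— and is exposed like every other optical constant. Because the whole
pipeline (reference curve and inversion) is scale-consistent, `C_geom`
affects realism, not accuracy.

### Reference-curve inversion

For a sample with a measured thrombin curve and a measured turbidity curve,
`infer_fibrinogen_tg()`:

1. applies QC: thrombin peak below θ_peak = 10 nM or maximum attenuance
   increase below θ_A = 0.02 flags the sample atypical (the thresholds are
   invented configuration — the study excluded "atypical and very low"
   curves without numeric criteria — and are exposed as arguments);
2. simulates the model over a fibrinogen grid (default 0.5–12 g/L, step
   0.5), driven by *that sample's own* thrombin curve, recording the
   maximum attenuance increase per grid point — the reference curve, which
   must come out strictly increasing;
3. inverts the reference curve at the measured maximum attenuance increase
   by monotone shape-preserving (Fritsch–Carlson) interpolation. No
   extrapolation: measurements outside the simulated range return
   `out_of_range` rather than a number, because the method is explicitly
   not equipped for extreme concentrations.

The per-sample (rather than pooled) reference curve follows from the
structure of the method: the simulation is conditioned on the sample's own
thrombin exposure. Simulate-then-invert round trips recover fibrinogen to
well under 2% at and between grid nodes.

## The statistical route (PT/RT features)

Four features summarize a transparency waveform sampled at 1 s over 0–60 s:
minimum transparency (mA), maximum absolute transparency gradient (mA/s),
and the maximum and minimum second derivative (mA/s²). Derivatives use
Savitzky–Golay local-polynomial filters (window 5, polynomial order 2 by
default) — exact on low-order polynomials, noise-robust otherwise; the
original differentiation scheme is unstated, so the choice is recorded here
and both settings are arguments. Features are computed on raw mA values
(no per-sample normalization), again because the source is silent; the
standardizer below handles scale where it matters.

Two estimators map features to fibrinogen:

* **Multivariate linear regression** (OLS with intercept) on the raw
  features.
* **A 4-3-1 network**: three tanh hidden units, linear output, inputs
  standardized to zero mean/unit SD with constants fitted on the training
  fold only. Training is full-batch Adam on mean squared error at the Keras
  defaults (learning rate 0.001, β₁ 0.9, β₂ 0.999, ε 1e-7), weights
  Glorot-uniform from a fixed seed. The epoch count is 10000: at learning
  rate 0.001 Adam's effective per-epoch step is about the learning rate, so
  a few thousand epochs cannot even carry the output bias from 0 to the
  cohort's ~5 g/L mean — with 2000 epochs the network visibly underfits
  (leave-one-out r ≈ 0.89 on the synthetic cohort), while by 10000 it has
  converged (r ≈ 0.99). Targets are deliberately left in g/L (not
  standardized) to keep the fitted output directly interpretable, which is
  why the bias has that distance to travel.
* **The combined rule**: the network is the better estimator above 6 g/L,
  the regression below; the gate is the network's own prediction, with the
  6 g/L boundary assigned to the network branch (the printed rule leaves
  exactly 6 unassigned).

Evaluation is leave-one-out: per fold, standardizer and both models are
refitted on all-but-one sample (fold f reseeded as `seed + f`), the
held-out sample predicted by each method; samples missing the assay
waveform or the reference value are excluded with an explicit reason.
Agreement is the sample Pearson r with a two-sided t-test p-value. The
`regular` strata filter drops INR-elevated and anti-Xa-positive samples,
mirroring the usual sensitivity analysis on anticoagulated specimens.

## The synthetic cohort

The generator emulates the study's sample mix as its defaults: 44 samples,
fibrinogen log-uniform over 1.1–16.6 g/L (the clinically skewed range),
24/44 with prolonged PT (VKA-like INR 2–3), 14/44 anti-Xa positive
(0.1–1.37 U/mL), 4/44 with elevated D-dimer, and additive Gaussian noise at
1% of each waveform's transparency amplitude on a 4000 mA baseline.
Thrombin curves are gamma-shaped with per-sample lag, peak, peak-time and
decay draws. Challenge effects are invented, config-exposed stand-ins (the
source reports only that such samples yield atypical or absent thrombin
generation): anti-Xa scales the thrombin amplitude geometrically from 1
down to 0.02 as anti-Xa goes 0 → 1.4 U/mL (heparin suppression is closer to
log-linear than linear in dose, and the high end must fall below the 10 nM
QC threshold); INR stretches the PT burst rise time proportionally; D-dimer
touches metadata only. RT is generated unperturbed by either — batroxobin
is insensitive to heparin and to thrombin inhibitors, which is precisely
the assay's clinical point.

Everything is a pure function of the configuration seed, and the caller's
RNG stream is restored afterwards.

What the generator does **not** emulate: dysfibrinogenemia (abnormal
fibrinogen with normal antigen), fibrinolysis, inner-filter or substrate-
consumption artifacts of fluorogenic thrombin measurement, inter-instrument
optics, or any real covariance between INR, anti-Xa and waveform shape
beyond the two stand-in mappings. Passing tests therefore demonstrate
internal consistency of the methods under controlled conditions — feature
informativeness, inversion correctness, QC behaviour — not clinical
performance on real plasma.

## The digitizer

Waveforms that exist only as printed plots (fixed axes: 0–60 s, 0–4000 mA)
are recovered from rasterized images: per second-column inside a calibrated
pixel box, the darkness-weighted centroid of below-threshold pixels maps
back to mA. The dark threshold defaults to an Otsu histogram split with a
manual override. Columns with no curve pixel are filled by linear
interpolation, capped at 20% of columns before extraction aborts (gap
handling is undescribed in the source; the cap keeps silent failure
impossible). On curves rendered at ≥ 3 px stroke the extraction is exact to
one pixel quantum (axis range divided by box height), which the tests
assert by rendering and re-extracting known curves.

## Numerical choices and problem sizes

* Solver tolerances `rtol = 1e-6` / `atol = 1e-9`; halving them moves final
  attenuance by < 0.1%.
* Reference curves in routine use and in the checks are built on a 10-s
  output grid over 0–600 s (the clot signal saturates within minutes); the
  24-point 0.5 g/L grid costs about a minute of CPU.
* The test and acceptance runs use the full 44-sample cohort for the PT/RT
  leave-one-out evaluations and small grids (6-point fibrinogen grid,
  3 + 3 samples) for QC demonstrations; these sizes were chosen as the
  smallest that exercise every code path meaningfully.
* Interpolation inverse uses `splinefun(method = "monoH.FC")`, which cannot
  overshoot between nodes, so the inverse is defined wherever the curve is.
* Degenerate inputs fail loudly: non-monotone reference curves name the
  offending interval, zero-variance features name the feature, unsorted
  waveform CSVs name the first inverted line.

## Known limitations

The 12 + 132 state structure matches the printed architecture of the
original (proprietary) model, but the specific processes and constants here
are an independently designed stand-in; absolute simulated attenuances are
calibrated, not derived. The statistical route's reported correlations on
synthetic cohorts are upper bounds of a sort — the generator's noise is
well-behaved and its fibrinogen-to-waveform mapping is exactly the forward
model the features summarize. Real plasma brings matrix effects,
dysfibrinogenemia and instrument idiosyncrasies that neither route has seen
here.
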