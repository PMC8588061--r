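---
title: "Methods: energy-balance glucose estimation from the wrist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy-balance glucose estimation from the wrist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucoheat)
```

## The model and its assumptions

Glucose oxidation is the dominant fuel of resting metabolism, so resting
metabolic heat production carries information about blood glucose. The
estimation chain in this package rests on five assumptions:

1. the body at rest is in thermal balance — heat generated equals heat
   dissipated;
2. dissipation at the wrist happens through radiation, convection and
   evaporation (conduction through the probe housing is neglected);
3. external work at rest is zero;
4. blood oxygen content is tied to heart rate and blood flow;
5. metabolic heat production is related to glucose, oxygen saturation and
   heart rate.

Under (1)–(3), metabolic heat production equals the summed surface fluxes:

$$H = R + C + E = \varepsilon\,\sigma\,T_r^4
  + 2.38\,(t_w - t_s)^{1.25}
  + 3.054\,(0.256\,t_w - 3.37)(1 - He)$$

and under (4)–(5) glucose is a function $BG = F(H, SpO_2, HR, BF)$ whose
form is unknown and is estimated by regression.

The estimate is only meaningful for a subject at rest: exercise breaks
assumption (3), and transient thermal states (walking in from the cold)
break assumption (1). The model also assumes net heat *loss*; an ambient
warmer than the skin puts the convective term outside the model, and the
package raises a flagged out-of-model condition rather than returning a
complex or silently absolute value (`convective_heat(allow_signed = TRUE)`
opts into a signed extension for exploration).

## Units, constants and their defaults

Physical units are deliberately asymmetric and embedded in the I/O schema
column names, because the two cheapest mistakes here — Celsius where kelvin
is needed, percent where a fraction is needed — are silent and large:

| quantity | symbol | unit | default / range |
|---|---|---|---|
| radiometric wrist temperature | `Tr` | **K** (the fourth-power law needs an absolute scale) | — |
| skin / ambient temperature | `tw`, `ts` | °C | `tw` > 13.164 °C |
| relative humidity | `He` | fraction in [0, 1] | — |
| emissivity | ε | — | 0.96 |
| Stefan–Boltzmann constant | σ | W m⁻² K⁻⁴ | 5.67×10⁻⁸ |
| convective coefficient | — | W m⁻² K⁻¹·²⁵ | 2.38 |
| fused evaporative constant | r·m | kPa⁻¹-scaled | 3.054 |
| saturation pressure line | — | kPa, kPa/°C | 0.256·tw − 3.37 |

Three choices deserve comment.

* **The latent-heat and permeability factors are never separated.** Only
  their product 3.054 enters the flux, so `energy_constants()` carries the
  fused value; it is configurable but there is no way (and no need) to
  vary the factors independently.
* **The radiative term uses the absolute emission** εσTr⁴, not a
  skin-minus-ambient exchange difference εσ(Tr⁴ − Ta⁴). This is the
  model form implemented; it inflates `H` by a large constant common to
  all records, which the downstream regression absorbs. Users comparing
  against textbook radiative-exchange formulations should expect that
  offset.
* **H is a flux (W/m²), not whole-body power.** No body-surface-area
  scaling is applied, again because a constant scale is absorbed by the
  regression.
* The skin temperature floor 13.164 °C is the root of the linear
  saturation-pressure approximation; below it the evaporative term would
  go negative, which is unphysical, so it is a hard domain error.

## The optical chain

The pulse detector is not prescribed by the estimation model, so the
package uses a deliberately boring, deterministic design: a 2nd-order
Butterworth band-pass over the cardiac band (0.5–8 Hz) run forward and
backward (zero phase), local-maximum candidates with a relative prominence
floor (25% of the filtered amplitude by default), a greedy
largest-amplitude selection enforcing a minimum inter-peak spacing of
`Fs·60/220` samples (a 220 bpm ceiling), and finally each peak snapped to
the raw-signal maximum within a quarter beat, which undoes the small
phase-independent bias filtering can introduce at the record edges. Ties
in the greedy selection are resolved by amplitude order and then position,
so the detector is a pure function of its input.

Heart rate uses the first-to-last-peak span,
$HR = F_s (N_{peak} - 1)/(x_{end} - x_{start}) \times 60$, which averages
beat intervals without needing every interval to be clean.

The perfusion ratio is estimated by ratio-of-ratios, the standard pulse
oximetry quantity: per-channel AC (per-beat peak-to-trough excursion,
averaged over beats delimited by the infrared peaks) over DC (channel mean
across the analysis window, the full record by default). The saturation
map

$$SpO_2 = 100\cdot\frac{K2_{ir}\,r - K2_{red}}
  {(K2_{ir} - K1_{ir})\,r + (K1_{red} - K2_{red})}$$

requires $K2_{red} > K1_{red}$ and $K1_{ir} > K2_{ir}$ (deoxyhemoglobin
dominates red absorption, oxyhemoglobin dominates infrared); the
constructor enforces that ordering, which is exactly the condition making
the map strictly decreasing in `r` across the physiological range. The
`K1` pair is oxyhemoglobin and the `K2` pair deoxyhemoglobin throughout —
the assignment the map's algebra itself forces, since swapping them would
make saturation increase with red pulsatility. Default coefficient values
follow published hemoglobin extinction spectra at 660/880 nm, but every
saturation test in the package constructs its own coefficients so that
correctness never rests on the defaults. Saturations computed slightly
outside [0, 100]% from noisy ratios are clamped with a warning; the
denominator within 10⁻¹² (relative) of zero is a hard singularity error.

## The regression models

**MPR4.** The design matrix holds exactly the 15 products of distinct
predictors — subsets of {x₁ = H, x₂ = SpO₂, x₃ = HR, x₄ = BF} of size 1
to 4, in the fixed order x₁, x₂, x₃, x₄, x₁x₂, x₁x₃, x₁x₄, x₂x₃, x₂x₄,
x₃x₄, x₁x₂x₃, x₁x₂x₄, x₁x₃x₄, x₂x₃x₄, x₁x₂x₃x₄. Pure powers are excluded
by design (interaction-only, to limit collinearity); the published term
sequence contains an obvious transcription slip (one predictor repeated
where its neighbor was meant), resolved here to the complete
distinct-subset enumeration that the phrase "interaction terms" and the
count of 15 both force. The fit is ordinary least squares through a QR
decomposition on the raw features — the coefficients are meant to be read
on physical scales — with two refusals rather than silent degradation: a
sample size not exceeding 3 × 15 = 45 (the model family's own adequacy
rule), and a rank-deficient design, reported with the collinear columns
named.

**BPNN.** A 4-9-1 network (hidden size from N_hid = 2·N_in + 1), tansig
hidden units, linear output. Training is nonlinear least squares by
Levenberg–Marquardt with an analytic Jacobian. Decisions the model family
leaves open, resolved here:

* **Scaling.** Predictors and target are standardized to the training
  split's mean/sd; H (~500), SpO₂ (~96), HR (~80) and BF (~15) differ by
  orders of magnitude and an unscaled tansig layer saturates. The scaling
  is stored in the model, so prediction is self-contained.
* **Initialization and determinism.** Weights start uniform in
  [−0.5, 0.5] from a seeded RNG; the global RNG state is saved and
  restored, so fitting is bit-reproducible by `(data, seed)` and does not
  perturb callers' random streams.
* **Overfitting control.** 55 weights against cohort-scale training sets
  (≈ 118 records) will memorize measurement noise if the optimizer runs to
  convergence. The standard safeguard pair is used: a seeded 20%
  validation hold-out with early stopping (patience 25 epochs, evaluated
  in 5-epoch chunks), and 5 seeded restarts with the best-validation
  restart kept, since the tansig loss surface is multimodal. Both are
  configurable (`validation_fraction = 0` recovers pure training-loss
  optimization).
* **Convergence reporting.** `max_epochs = 1000`-style hard failures are
  avoided by returning the best iterate with `converged = FALSE` and a
  warning instead of erroring; default `max_epochs = 200`, tolerance
  10⁻⁸.

The hold-out split is a seeded uniform partition; its default training
fraction is 118/211, the emulated protocol's published counts. Those
counts are internally inconsistent (118 train + 63 test is 181, not 211),
and the package keeps the fraction as a visible config default rather than
quietly renormalizing it.

Models serialize to YAML — every weight, coefficient, scale and the seed
in plain text — so a fit can be audited, diffed and moved between
machines without binary artifacts.

## Evaluation metrics

mARD, Pearson correlation, RMSE and the Clarke grid are standard. Two
metrics need explicit definitions because their printed conventions vary:

* **MAD** is provided in two forms. `mad_printed()` is the mean absolute
  deviation of the *predictions about their own mean* — a spread measure
  that never sees the reference values — because that is the convention
  this model family reports; `mad_conventional()` is the usual
  mean |Yᵢ − Xᵢ|. Reports include both, labeled.
* **SEP** (standard error of prediction) has no universal formula; here it
  is the standard deviation of the residuals Yᵢ − Xᵢ about their mean,
  divisor n − 1 by default and configurable to n. It measures residual
  spread, not bias: a constant offset yields SEP = 0 by construction.

The correlation is plain Pearson (the printed definitional forms in this
literature are sometimes typographically garbled; the tests pin the
implementation to the covariance-over-root-variances definition).

The Clarke grid uses the canonical 1987 piecewise geometry, computed in
mg/dL (mmol/L × 18.016): zone A is a relative deviation of no more than
20% — *inclusive*, so a prediction at exactly 1.2× the reference is still
A — or both readings under 70 mg/dL; E is the hypo/hyper confusion
corners; C the over-correction wedges; D the failure-to-detect bands at
the 70 and 180 mg/dL clinical thresholds; B everything else. The
inequalities are encoded twice in the repository — once in the package,
once as an independently written transcription in the test suite — plus a
small golden-point table, so a regression in the geometry cannot pass
silently.

## The synthetic cohort

No dataset pairing wrist heat flux, dual-wavelength PPG, laser-Doppler
flow and reference glucose is publicly available, so the package
generates one with known ground truth. The generator emulates a
meal-challenge protocol in healthy adults: per subject, a fasting
baseline (uniform 4.4–5.6 mmol/L) plus a log-normal-shaped postprandial
excursion (amplitude 1.5–4.5 mmol/L, peak 30–60 min post meal), sampled
30 min before and 30/60/90/120 min after up to three meals, clipped to
4.1–10 mmol/L, until the configured 211 records exist.

The core of the generator is that it makes the unknown relation $F$
explicit and *invertible*: given a record's true glucose, vitals and blood
flow, it solves $F(H, \cdot) = BG$ for the demanded heat production
(1-D monotone root finding), then solves the heat model for the skin
temperature that reproduces that H under freshly drawn ambient conditions
(again monotone in `tw`, bisection to 10⁻¹⁰; inadmissible ambient draws
are resampled up to a bounded retry count). Every generated frame
therefore passes validation *and* reproduces its target H to numerical
precision — the pipeline's principal end-to-end correctness test rests on
this.

Two truth families are registered. `"mpr4-span"` (default) is a sparse
fixed coefficient set on the interaction terms (−42 + 0.095·H + 0.012·HR
+ 0.05·BF + 4×10⁻⁴·HR·BF), inside the polynomial's span, so a noiseless
fit must recover it exactly — coefficients to 10⁻⁶, test mARD under
0.5% through the full frames-and-waveforms pipeline. `"saturating"` is a
logistic response in H (base 3.8, span 6.5, midpoint 500 W/m², scale
12 W/m², plus a small HR term), deliberately outside the span, giving the
network genuine nonlinearity to exploit; on this family the 4-9-1 network
beats the polynomial on held-out mARD averaged over a fixed seed batch —
a directional property only, asserted without clinical magnitudes.
Truth-family outputs are range-checked at generation: the trajectory and
the noisy reference are clipped into the configured glucose band (the
family functions themselves are left unclipped so that inversion stays
exact).

Measurement noise is multiplicative Gaussian on the reference glucose
(default sd 5%, matching strip-glucometer proportional error); frames and
waveforms are noise-free by default so that each stage's error budget is
attributable. Waveforms carry their record's HR and SpO₂ by construction:
a systolic-bump-plus-dicrotic-shoulder template at the target beat rate,
channel AC/DC fractions set so the ratio-of-ratios maps back to the
target saturation (infrared AC/DC 0.04, red scaled by the implied ratio).

What the generator does **not** emulate — and therefore what passing
tests do not demonstrate about real data: motion artifacts and baseline
wander in the PPG, probe contact-pressure variation, radiometric
calibration error, inter-subject variation in the true $F$, diabetic-range
glucose (> 10 mmol/L), and any correlation structure between vitals and
glucose beyond what $F$ itself imposes. The synthetic results validate
the *software chain*, not the clinical method.

## Numerical choices and degenerate inputs

* Root finding (`uniroot`) tolerances 10⁻¹⁰ on both inversions; brackets
  are checked before solving and failures surface as explicit errors
  naming the record.
* The peak detector is deterministic: no randomness, stable tie-breaks.
* A flat PPG channel is "insufficient pulsatility" (error), but a flat
  *red* channel with a pulsatile infrared channel gives perfusion ratio 0
  — a meaningful limit, not an error.
* Zone percentages are exact multiples of 100/n; their sum is asserted to
  100 within 10⁻⁹ everywhere they are produced.
* The 45-record refusal in `fit_mpr4` is strict (> 45, so n = 46 is the
  smallest admissible fit); `fit_bpnn` requires n ≥ 20.
* Empty tables flow through feature extraction as empty results, not
  errors; invalid rows are reported with row numbers and never silently
  dropped, so record counts are conserved across every stage.

## Problem sizes in the shipped tests

The test suite runs the default 211-record cohort wherever the protocol's
shape matters, a 2000-record frame-only draw for the admissibility sweep,
10⁴ random frames for the heat-model additivity property, a 5-seed batch
for the model-comparison property, and 10–12 s waveforms at 100 Hz for
the optical round trips. These sizes keep the full suite in the tens of
seconds on a single core while leaving every property's sampling error
far below its assertion margin.

## Known limitations

* The energy balance is steady-state; no transient thermal dynamics.
* `BF` is consumed as an opaque positive scalar in perfusion units; no
  flow-probe model is included.
* The convective power law is an empirical still-air form; forced
  convection (airflow over the wrist) is out of scope.
* The saturation map is two-wavelength and calibration-free; real
  oximeters apply empirical calibration curves on top of the Lambert–Beer
  form.
* Conclusions about clinical accuracy cannot be drawn from the synthetic
  cohort (see above); the package's claims are about the correctness of
  the computation, reproducibility and the documented conventions.
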