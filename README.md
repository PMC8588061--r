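# glucoheat

Noninvasive blood-glucose estimation from wrist sensor readings, built on
the conservation of energy metabolism.

Finger-prick glucometers are accurate but painful, and the pain limits how
often people with diabetes actually test. One noninvasive alternative
reasons from physiology: at rest, the body's metabolic heat production —
fueled largely by glucose oxidation — equals its surface heat loss, which
*can* be measured. `glucoheat` implements that full measurement chain for
wrist-worn sensing:

1. **Metabolic heat production** `H` from an energy balance over the three
   surface loss channels,

   ```
   H = R + C + E
     = ε σ Tr⁴ + 2.38 (tw − ts)^1.25 + 3.054 (0.256 tw − 3.37)(1 − He)
   ```

   with skin emissivity ε = 0.96, Stefan–Boltzmann constant
   σ = 5.67×10⁻⁸ W m⁻² K⁻⁴, radiometric wrist temperature `Tr` (K), skin
   and ambient temperatures `tw`, `ts` (°C) and ambient relative humidity
   `He` (fraction). All fluxes in W/m².

2. **Heart rate and oxygen saturation** from a dual-wavelength
   (660/880 nm) reflective photoplethysmogram: systolic peak detection
   after zero-phase band-pass conditioning, `HR = Fs (Npeak − 1) /
   (xend − xstart) × 60`, the ratio-of-ratios perfusion ratio
   `r = (AC/DC)₆₆₀ / (AC/DC)₈₈₀`, and

   ```
   SpO₂ = 100 · (K2ᵢᵣ r − K2ᵣₑ𝒹) / ((K2ᵢᵣ − K1ᵢᵣ) r + (K1ᵣₑ𝒹 − K2ᵣₑ𝒹))
   ```

   from the hemoglobin absorption coefficients.

3. **Glucose regression** `BG = F(H, SpO₂, HR, BF)` (`BF` = laser-Doppler
   blood flow) with two models: **MPR4**, ordinary least squares on the 15
   interaction-only products of the four predictors (no squared terms, to
   limit collinearity), and a **4-9-1 feedforward network** (hidden size by
   the Kolmogorov rule N_hid = 2·N_in + 1, tansig hidden units, linear
   output) trained by Levenberg–Marquardt least squares with seeded
   restarts and validation-based early stopping.

4. **Clinical evaluation**: mARD, Pearson correlation, MAD (two
   conventions), RMSE, SEP, and the Clarke error grid with the canonical
   1987 zone geometry (zone A = within 20% of the reference, inclusive, or
   both readings below 70 mg/dL).

Because no public dataset of synchronized wrist heat-flux + PPG + reference
glucose exists, the package ships a seeded **synthetic cohort generator**
that emulates the target study design — 211 records from meal challenges,
reference glucose in 4.1–10 mmol/L, 118-record hold-out training split —
with an explicit, configurable ground-truth relation, so the entire
pipeline is testable end to end.

## Worked example

```r
library(glucoheat)

# one sensor frame -> heat budget
frame <- sensor_frame(Tr = 306.15, tw = 33.2, ts = 24, He = 0.45, BF = 14)
metabolic_heat(frame)
#>          R        C        E        H
#> 1 478.1799 38.13395 8.615517 524.9294

# dual-wavelength PPG -> vitals
w <- generate_ppg(target_hr = 72, target_spo2 = 97, fs = 100, duration = 10)
v <- process_ppg(w)
#> HR 71.97 bpm, r 0.358, SpO2 97.00 %

# synthetic cohort -> train network -> evaluate on the hold-out test set
co    <- generate_cohort(cohort_config(truth = "saturating", ppg = FALSE),
                         seed = 1)
feats <- data.frame(H = co$H_true_Wm2, SpO2 = co$SpO2_true_pct,
                    HR = co$HR_true_bpm, BF = co$BF_pu,
                    bg_ref = co$BG_ref_mmolL)
sp <- holdout_split(feats, seed = 1)       # 118 train / 93 test
b  <- fit_bpnn(sp$train, seed = 1)
evaluate_predictions(sp$test$bg_ref, predict(b, sp$test))
#> Glucose prediction accuracy (n = 93)
#>   mARD: 4.582 %   CORR: 0.957
#>   MAD (about prediction mean): 1.040 mmol/L   MAD (vs reference): 0.284 mmol/L
#>   RMSE: 0.362 mmol/L   SEP: 0.359 mmol/L
#>   Clarke error grid:
#>     zone A: 100.000 % (n = 93)
#>     ...
```

The 4.58% test mARD here reflects the generator's 5% multiplicative
reference-measurement noise — the model is recovering the configured
ground-truth relation essentially up to the noise floor. `plot_clarke_grid()`
draws the zone chart for reports.

A thin command-line wrapper over the same functions lives at
`inst/scripts/glucoheat` with subcommands `simulate`, `extract`, `train`,
`predict` and `evaluate`.

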