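# avscreen

Screening of hemodialysis arteriovenous-access stenosis from multi-site
Doppler ultrasound velocimetry.

Hemodialysis depends on a surgically created arteriovenous access (fistula
or graft) whose lumen progressively narrows with repeated puncture and
long-term use. `avscreen` grades that narrowing — the degree of stenosis
`DOS = 1 − (d_H/D_H)²`, banded as Class I (mild, < 0.30), Class II
(0.30–0.50) and Class III (severe, > 0.50) — from routine Doppler
measurements at three points along the access: the arterial anastomosis
(A), the loop (L) and the venous anastomosis (V).

The pipeline, for sonographers' standard inputs (peak-systolic velocity
V_p, peak-diastolic velocity V_m, heart rate, hydraulic diameter per site):

1. **Hemodynamics.** Each site's measurements become dimensionless
   numbers: Reynolds `Re = ρ V_p D_H / μ`, Womersley
   `α = (D_H/2)√(2πf/ν)`, Strouhal `St = f D_H / V_p`, the pulsatile
   transition threshold `Re_peak = 169 α^0.83 St^−0.27`, the supracritical
   Reynolds number `Re_supra = |Re − Re_peak|`, and the resistive index
   `Res = (V_p − V_m)/V_p`.
2. **Features.** A six-element pattern per subject,
   `Φ = [Ratio_A, Ratio_L, Ratio_V, Res_A, Res_L, Res_V]`, where each
   `Ratio` is `Re_supra` normalized by the loop-site value (so
   `Ratio_L ≡ 1`).
3. **Classification.** A color relation analysis (CRA) classifier:
   exponential similarity grades `ρ(k) = ξ·exp(−ξ·ED(k))` against labelled
   training patterns, class-averaged and mapped through an HSV-style
   transform to a hue angle — blue (240°) for Class I, green (120°) for
   Class II, red (0°/360°) for Class III. The decision variable
   `H_C = H/360` is matched to the class centers (2/3, 1/3, 1) by circular
   distance.
4. **Tuning.** The recognition coefficient ξ is chosen by particle swarm
   optimization with time-varying acceleration coefficients (20 particles,
   ≤ 100 iterations, c1 2.5→0.5, c2 0.5→2.5), minimizing the leave-one-out
   mean squared hue error with a 0.05 convergence threshold.
5. **Synthetic cohorts.** A generator reproducing published
   class-conditional velocity statistics (30 subjects, 12/11/7 across the
   classes) makes the whole pipeline trainable and testable without
   clinical data, including pulsatile waveform synthesis and landmark
   extraction.

## Worked example

```r
library(avscreen)

cohort <- sample_cohort(cohort_config(), seed = 1)   # 30 labelled subjects
feats  <- featurize(cohort)
head(feats, 3)
#>   subject_id ratio_A ratio_L ratio_V  res_A  res_L  res_V dos_class
#> 1       S001  1.0083       1  0.9977 0.5108 0.6895 0.4677         I
#> 2       S002  0.9222       1  1.0682 0.6072 0.5697 0.4286         I
#> 3       S003  0.9868       1  1.0287 0.5837 0.9085 0.5697         I

model <- cra_train(feats, seed = 1)                  # PSO-tuned classifier
model
#> Color relation analysis classifier
#>   training patterns: 30 (I: 12, II: 11, III: 7)
#>   recognition coefficient xi: 18.6068
#>   hue convention: class_centered; error mode: wrapped
#>   leave-one-out MSEF at xi: 0.0124

newpat <- featurize(sample_cohort(
  cohort_config(class_sizes = c(I = 1, II = 1, III = 1)), seed = 99))
predict(model, newpat)
#>   subject_id     H_deg      S        HC predicted_class low_confidence
#> 1       S001 227.56578 0.9997 0.6321272               I          FALSE
#> 2       S002 122.52854 0.9972 0.3403571              II          FALSE
#> 3       S003   0.05266 1.0000 0.0001463             III          FALSE
```

Reading the output: each subject's hue angle lands in its class's color
sector — the mild subject near blue (227.6°, `H_C` 0.63 ≈ 2/3), the
moderate one near green (122.5°, `H_C` 0.34 ≈ 1/3) and the severe one
essentially on red (0.05°, `H_C` ≈ 0, circularly adjacent to the Class III
center at 1). Saturation `S` near 1 marks a confident, well-separated
grade profile. The training summary shows the tuned recognition
coefficient and a leave-one-out mean squared hue error of 0.0124, below
the 0.05 convergence threshold.

A thin command-line interface over the same functions ships at
`inst/cli/avscreen` (subcommands `simulate`, `featurize`, `train`,
`classify`, `evaluate`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/avscreen", package = "avscreen"))')
Rscript $CLI simulate --out cohort.csv --seed 5
Rscript $CLI featurize --in cohort.csv --out features.csv
Rscript $CLI train --in features.csv --model model.json --trace trace.csv --seed 5
Rscript $CLI classify --in features.csv --model model.json --out predictions.csv
```

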