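# pulsekinetics

Kinetics of starch and protein digestion in hydrothermally processed
pulses (chickpea, pea, black bean) and their isolated cotyledon cells
(ICC).

In cooked pulses, intact cell walls encapsulate starch and protein and act
as a barrier for digestive enzymes. Studies of this barrier effect share a
common quantitative core, which this package implements for R users in
food-structure and digestion research:

- **Assay conversions** — DNS reducing-sugar readings to digested starch
  (the maltose × 0.95 / total-starch × 100 rule) and OPA free-amino-group
  readings to digested soluble / readily bioaccessible protein
  percentages, with OLS calibration lines.
- **Kinetic modelling** — the fractional conversion model
  `C(t) = Cf + (Ci − Cf)·e^(−kt)` and the lag-phase logistic
  `C(t) = Cf / (1 + exp(4·kmax/Cf·(λ − t) + 2))`, fitted by bounded
  Levenberg–Marquardt least squares with deterministic multistart; initial
  reaction rates (tangent slope at t = 0), adjusted R², AICc-based model
  discrimination for lag detection.
- **Joint confidence regions** — SSE/F-ratio regions
  `SSE(θ) ≤ SSE(θ̂)·(1 + p/(n−p)·F(p, n−p, 1−α))` for parameter pairs such
  as (k, Cf), with polygon overlap quantification.
- **Texture** — hardness-softening kinetics on per-seed forces, residual
  hardness plateau, percent hardness reduction and the earliest cook time
  aligning a sample at the plateau.
- **Particle size** — cotyledon-cell yield (volume in the 76–133 µm
  window), volume-weighted mean size and modality of binned volumetric
  PSDs.
- **Composition** — fiber-rich residue by difference and the
  starch/protein, starch/FRR and seed-coat/cotyledon ratios.
- **Synthetic data** — generators emulating every measured input
  (digestion tubes, assay plates, 25-seed hardness batches, log-normal PSD
  mixtures) with preset "truths" per sample, making the full pipeline
  testable offline.

## Worked example

Simulate black-bean cotyledon-cell starch digestion (true lag phase
λ = 11 min), let the package decide between the two models, and inspect
the chosen fit:

```r
library(pulsekinetics)

tc <- generate_digestion_timecourse("BB_ICC_60", "starch",
                                    noise_sd = 2, seed = 7)
disc <- discriminate_models(tc)
disc$choice
#> [1] "logistic"

disc$fits$logistic
#> Kinetic fit: logistic
#>         estimate     se
#> Starchf  91.3876 1.1298
#> kmax      1.4003 0.0567
#> lambda   11.2152 1.2884
#> SSE 83.72 on 18 obs; R2_adj 0.9957

round(disc$diagnostics$lambda_ci, 2)
#> [1]  8.47 13.96
```

The lag phase is recovered at 11.2 min with a 95% CI excluding zero, so
the logistic is selected over the fractional conversion model; the plateau
(91.4% digested starch) and maximum rate (1.40 %/min) match the
generating preset within their standard errors.

Composition ratios from the packaged table:

```r
comp <- read_composition_csv(system.file("extdata", "pulse_composition.csv",
                                         package = "pulsekinetics"))
compute_frr(comp[["CP raw"]])
#> [1] 27.53
macronutrient_ratios(comp[["CP raw"]])
#> $starch_protein  2.048994   $starch_frr  1.443153
```

A fiber-rich residue of 27.5 g/100 g and a starch/protein ratio of 2.05
place chickpea among the starch-rich, thin-walled pulses; black bean's
lower starch/FRR ratio (1.02) reflects the thicker cell walls behind its
slower softening and its starch-digestion lag.

`run_analysis()` chains the stages (simulate/read → fit → rates → joint
regions → texture → PSD → composition) from a YAML/JSON or list
configuration and writes CSV/JSON outputs plus a run log; identical
configuration and seed reproduce identical files.

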