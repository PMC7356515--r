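# pkpdsynergy

A minimal pharmacokinetic–pharmacodynamic (PKPD) simulator of non small
cell lung cancer (NSCLC) tumor growth under combined antiangiogenic
therapy, immunotherapy and radiotherapy, for in-silico comparison of
therapy management protocols (fractionation schedules, drug synergy,
patient resistance). It is aimed at modelers and treatment-planning
researchers who want a small, fully deterministic, testable model rather
than a mechanistic multi-scale one.

## The model

Eight states: proliferating tumor volume `x1` (mm³), necrotic volume `x2`,
and serum/effect-site pairs for each therapy channel (`x3/xe3`
antiangiogenic, `x4/xe4` immunotherapy, `x5/xe5` radiotherapy in
Gy/day-equivalent units). Tumor dynamics:

    dx1/dt = (a − n) x1 − E·x1
    dx2/dt = n x1 + E·x1

so killed volume accumulates as necrosis and total volume grows at `a·x1`.
Each channel has first-order serum kinetics with an external dose-rate
input, and an effect-site compartment filled from the serum at a rate
modulated by the tumor–drug Hill surface.

Treatment effect is built from Hill response surfaces over
potency-normalized levels. Two agents at normalized levels `U_A`, `U_B`
interact through the index

    I = U_A + U_B + σ·U_A·U_B,      Effect = Emax · I^γ / (1 + I^γ)

where `σ` is the synergy coefficient and `γ` the sigmoidicity (patient
responsiveness/resistance). Three tumor–drug terms (as drug-attributable
excess over the drug-free surface section) and three drug–drug terms (as
interaction beyond additivity) are averaged into the kill rate
`E = (Et_all + Ed_all)/2`. An LQ radiobiology module
(`−ln S = αD + βD²`, incomplete-repair g-factor) supports fractionation
analysis. See the methods vignette
(`vignettes/combined-therapy-model.Rmd`) for the full account, including
the aggregation design decisions.

## Worked example

```r
library(pkpdsynergy)

# untreated control: exact exponential growth
run_control()
#>     label end_total_volume end_active_volume end_necrotic_volume
#> 1 control         149361.9          90017.13            59344.75

# weekly AG 0.171 mg/mL + weekly IM 0.2 mg/mL + radiotherapy Protocol 2
# (5 Gy x 3 days, then 2 Gy x 3 days after two weeks)
p1 <- run_protocol(1)
p2 <- run_protocol(2)
p2
#>        label end_total_volume end_active_volume end_necrotic_volume
#> 1 protocol_2         91446.55          49716.44            41730.11

relative_difference(p2, p1)
#> [1] 8.794353

# resistance sweep: gamma 1 (responsive) vs 8 (resistant), sigma = 4
rw <- resistance_sweep(gamma_values = c(1, 8))
attr(rw, "percent_increase")
#> [1] 39.93829
```

The control ends at ~149,362 mm³ total (90,017 active + 59,345 necrotic),
matching the closed form `V0·e^{(a−n)·30}`. Protocol 2 ends ~8.8% above
Protocol 1 (timing effect: Protocol 1 keeps dosing late, when the
regrowing tumor matters most), and raising the resistance exponent from 1
to 8 raises the end volume by ~40%.

Trajectories (`attr(p2, "trajectory")`) carry all states plus the effect
breakdown per day and can be written to tidy CSV with
`write_trajectory()`; `write_summary()` emits a JSON summary with a full
provenance block that `replay_summary()` re-runs bit-for-bit.

## Command line

```sh
Rscript inst/cli/pkpdsynergy.R protocol --id 2 --out p2
Rscript inst/cli/pkpdsynergy.R sweep --param sigma --values 1,4,8 --out syn
Rscript inst/cli/pkpdsynergy.R surface-export --sigma 4 --gamma 2.5 --out surf
```

Subcommands: `control`, `protocol`, `simulate`, `sweep`,
`surface-export`; parameters can be overridden with `--param KEY=VALUE`
or a JSON `--config` file.

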