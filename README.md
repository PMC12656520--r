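# seedhtt

Population-based threshold models for seed germination: thermal time,
hydrotime and hydrothermal time, with the PEG-6000 osmoticum calibration
used to impose water-potential treatments, a generative trial simulator for
validating the fitters, and a multivariate stage (PCA + clustering) that
relates fitted germination parameters to seed trait profiles such as
fatty-acid composition.

The package is written for seed biologists and agronomists who score
germination counts on a fixed schedule across grids of constant temperature
and osmotic potential, and who want physiologically interpretable
parameters — base temperature, base water potential, time constants — rather
than treatment-by-treatment summaries.

## The models

Let t(g) be the time for fraction *g* of the seed lot to germinate at
temperature *T* (°C) and water potential *Ψ* (MPa). The package fits three
nested threshold models:

- **Thermal time** (per water potential, sub-optimal range):
  θ<sub>T</sub>(g) = (T − T<sub>b</sub>) · t(g), so the germination rate
  GR(g) = 1/t(g) is linear in T with x-intercept T<sub>b</sub>.
- **Hydrotime** (per temperature):
  θ<sub>H</sub> = (Ψ − Ψ<sub>b</sub>(g)) · t(g), where the per-seed base
  water potential Ψ<sub>b</sub> is Normal(Ψ<sub>b(50)</sub>, σ<sub>Ψb</sub>).
- **Hydrothermal time** (whole grid):
  θ<sub>HT</sub> = (Ψ − Ψ<sub>b</sub>(g)) · (T − T<sub>b</sub>) · t(g).

The normal threshold distribution linearizes under the probit:

probit(g) = [Ψ − θ<sub>HT</sub>/((T − T<sub>b</sub>)·t(g)) − Ψ<sub>b(50)</sub>] / σ<sub>Ψb</sub>

so for a candidate (θ<sub>HT</sub>, T<sub>b</sub>) the model is a straight
line; the fitters nest that probit regression inside a grid search over the
time constant (and T<sub>b</sub>), keeping the candidate with maximal R²,
and read Ψ<sub>b(50)</sub> = −intercept/slope, σ<sub>Ψb</sub> = 1/slope off
the winning line. A nonparametric bootstrap over replicate dishes gives the
standard error of θ<sub>HT</sub>.

Water-potential treatments are prepared from the Michel–Kaufmann (1973)
calibration of PEG-6000: `peg_potential()`, `peg_concentration()` and
`peg_table()` evaluate and invert the published polynomial (bar scale,
converted to MPa).

## Worked example

A small synthetic trial (2 dishes × 50 seeds at 3 temperatures × 3 water
potentials, scored every 8 h for 7 days, generated with
θ<sub>HT</sub> = 500 MPa °C h, T<sub>b</sub> = 10 °C,
Ψ<sub>b(50)</sub> = −0.6 MPa, σ<sub>Ψb</sub> = 0.2 MPa) ships with the
package:

```r
library(seedhtt)
path   <- system.file("extdata", "synthetic_trial_counts.csv", package = "seedhtt")
counts <- read_germination_counts(path)
pct    <- percentile_times(truncate_plateau(counts))
fit    <- fit_htt(pct)
fit
#> Hydrothermal time fit
#>   theta_HT = 474.0 MPa degC h,  Tb = 9.914 degC
#>   psi_b50 = -0.579 MPa,  sigma_psib = 0.202 MPa
#>   temperatures used: 15-35 degC
#>   probit R2 = 0.9815, RMSE = 2.70 %G, n = 41
```

All four generating parameters are recovered within a few percent from this
small design (θ̂<sub>HT</sub> = 474 vs 500; T̂<sub>b</sub> = 9.9 vs 10;
Ψ̂<sub>b(50)</sub> = −0.58 vs −0.6; σ̂ = 0.202 vs 0.2); the probit R² near 1
says the threshold model describes the whole grid with one parameter set.
The fitted lot can then be predicted anywhere on the grid:

```r
predict_time_course(fit, temperature = 25, psi = -0.3, times = c(24, 48, 72, 168))
#> [1] 0.000 0.032 0.218 0.675
```

i.e. about 22% of sown seeds germinated by 72 h and 67% by the end of the
test at 25 °C / −0.3 MPa. The PEG-6000 concentrations needed to impose
those water potentials:

```r
round(peg_table(c(-0.3, -0.6), c(15, 25, 35)), 1)
#>            psi_MPa
#> temperature  -0.3  -0.6
#>          15 135.7 204.4
#>          25 151.4 223.7
#>          35 170.6 246.7
```

`run_pipeline()` chains all stages (read/simulate → plateau truncation →
percentile times → three model fits → optional PCA/HCPC of a trait table)
and writes per-stage CSVs plus a JSON manifest recording every decision;
`inst/exec/seedhtt` exposes the same stages as shell subcommands
(`simulate`, `peg-table`, `fit-tt`, `fit-ht`, `fit-htt`, `pca`, `run`).

Parameter-recovery validation at full trial scale (8 temperatures × 7 water
potentials × 4 dishes × 50 seeds) is one call:

```r
recovery_suite(trial_config(rng_seed = 1), n_runs = 20)
```

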