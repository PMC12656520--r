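---
title: "Threshold models for germination time courses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold models for germination time courses: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedhtt)
```

## The population threshold model

Seeds in a lot do not germinate in lockstep: under the population-based
threshold view, each seed carries its own base water potential
$\psi_b$ below which it cannot germinate, while the lot shares a base
temperature $T_b$. Above both thresholds a seed accumulates "hydrothermal
time" at a rate proportional to both excesses, and germinates when its
running total reaches a lot-level constant $\theta_{HT}$
(MPa&nbsp;°C&nbsp;h). For the seed at population quantile $g$,

$$\theta_{HT} = (\psi - \psi_b(g))\,(T - T_b)\, t(g),$$

with $\psi_b(g) = \psi_{b(50)} + \sigma_{\psi b}\,\Phi^{-1}(g)$ under the
assumption that base water potentials are normally distributed across
seeds. Two reduced models handle single-factor designs: thermal time
$\theta_T(g) = (T - T_b)t(g)$ at fixed water potential, and hydrotime
$\theta_H = (\psi - \psi_b(g))t(g)$ at fixed temperature. The three share
their interpretation: time constants measure lot vigor (smaller = faster),
thresholds measure stress tolerance (lower = hardier).

Applying the probit transform linearizes the joint model,

$$\mathrm{probit}(g) = \frac{\psi - \theta_{HT}/\big((T-T_b)\,t(g)\big) - \psi_{b(50)}}{\sigma_{\psi b}},$$

so that for a *candidate* $(\theta_{HT}, T_b)$ the transformed data lie on
a straight line in $x = \psi - \theta_{HT}/((T-T_b)t(g))$. The fitters
exploit this: an inner ordinary least-squares probit regression scores each
candidate by its $R^2$, an outer search picks the best candidate, and the
winning line yields $\psi_{b(50)} = -a/b$ and $\sigma_{\psi b} = 1/b$ from
its intercept $a$ and slope $b$. A non-positive slope is reported as a
non-identifiability error rather than silently returning a negative
standard deviation.

## From counts to percentile times

The raw observable is a cumulative count of germinated seeds per dish on a
fixed scoring schedule (default every 8&nbsp;h for 7 days = 168&nbsp;h,
with $t=0$ at imbibition). The pipeline:

1. **Plateau truncation** (`truncate_plateau`): once a dish stops gaining
   germinants, later observations are uninformative about timing and are
   dropped, keeping the first time the maximum is reached. Dishes with no
   germination collapse to one flagged row. The operation is idempotent.
2. **Pooling**: replicate dishes of a treatment are summed as step
   functions on the union of their scoring times, so dishes truncated at
   different points still contribute their plateau counts at later times.
   Final germination of a pooled treatment is total germinated over total
   sown — a count-weighted pool, not a mean of replicate percentages.
3. **Percentile extraction** (`percentile_times`): the pooled cumulative
   fraction is interpolated linearly to the times $t(g)$ at the requested
   fractions (deciles 0.1–0.9 by default, always including 0.5). The curve
   is anchored at the origin — zero germinated at imbibition is a physical
   fact, not an extrapolation — and never extended beyond the last scoring
   time: an unreached fraction is `NA`, never zero.

Fractions are computed **relative to seeds sown** by default. The probit
model regresses population fractions against quantiles of the whole lot's
threshold distribution, so the denominator must be the lot, not the subset
that happened to germinate; `basis = "final"` is available for sensitivity
checks. Treatments with zero germinated seeds are excluded from fitting
(threshold configurable upward), which automatically removes, e.g., a
temperature at or below $T_b$ for every cultivar, and the exclusions are
recorded in the percentile table's attributes and the run manifest.

## Search strategy and numerical choices

- **Hydrotime**: $\theta_H$ is searched on a 40-point log-spaced grid over
  [0.1, 500] MPa h — bracketing reported crop values by more than an order
  of magnitude on each side — then refined by golden-section search between
  the bracketing neighbours of the best grid point, on the log scale, to a
  relative tolerance of $10^{-4}$. A grid-edge optimum raises a boundary
  warning instead of being hidden.
- **Hydrothermal time**: $T_b$ runs over a 0.5&nbsp;°C grid on
  $[0, \min(T_\mathrm{used}) - 1]$, each candidate with the inner
  $\theta_{HT}$ search (default bracket [1, 10^5] MPa °C h); the best pair
  is then polished by a nested continuous optimization of $T_b$ (tolerance
  $10^{-3}$ °C). `fixed_Tb` skips the outer search for the workflow where
  $T_b$ comes from a thermal time analysis. Both modes are provided because
  published whole-grid fits rarely state which was used; neither claims to
  reproduce any particular published table.
- **Thermal time** needs no search: the linear form $GR = a + bT$ gives
  $T_b = -a/b$, $\theta_T = 1/b$ directly. Temperatures above the observed
  rate optimum are excluded by default because the model has no ceiling
  term; `suboptimal_only = FALSE` overrides.
- **Probit clipping**: observed fractions of exactly 0 or 1 are excluded
  from the regression (their probits are infinite). With decile percentile
  grids this only removes unreachable levels, which are already `NA`.
- **Optimality criterion**: maximal probit-regression $R^2$, equivalent to
  minimal residual sum of squares on the probit scale at fixed data.
- **Ties and determinism**: all searches are deterministic; if the
  continuous refinement does not beat the best grid point (flat objective),
  the grid point is kept.

Diagnostics follow the conventions of published germination tables:
thermal-time $R^2$ on the rate scale with RMSE in hours on back-predicted
$t(g)$; hydro/hydrothermal probit $R^2$ with RMSE in percentage points of
germination (observed vs model fraction at each percentile observation).
The headline rate $GR_{(50)}$ of a thermal-time fit is reported at an
explicit reference temperature (default 25&nbsp;°C) stored in the fit,
because a single tabulated $GR_{(50)}$ per water potential is not
self-consistent without one. The "predicted G" of a hydrotime fit is
$100\,\Phi((\psi_\mathrm{ref} - \psi_{b(50)})/\sigma_{\psi b})$ at a
declared reference potential (default: the highest with data), with the
observed pooled percentage alongside — the raw ingredients are always
retained because published definitions of this column vary.

## The PEG-6000 calibration

Water potentials are imposed with polyethylene glycol 6000. The
Michel–Kaufmann (1973) regression gives the solution potential in bars as

$$\psi = -1.18\times10^{-2}C - 1.18\times10^{-4}C^2 + 2.67\times10^{-4}CT + 8.39\times10^{-7}C^2T$$

for $C$ g PEG per litre of water at $T$ °C; the package converts to MPa
(÷10) and inverts by bracketed root-finding on [0, 600] g/L to
$10^{-9}$ MPa, erroring outside the bracket rather than extrapolating.
Round-trip accuracy across the design grid is below $10^{-6}$ MPa.
Published tabulations of this calibration carry their own last-digit
rounding, so agreement with printed tables is expected to about
±0.2&nbsp;g/L, not to machine precision.

## What the simulator emulates — and what it does not

`simulate_trial` generates data from exactly the model the fitters assume:
per-seed normal base water potentials, sharp thresholds, hydrothermal-time
accumulation, observation on a discrete scoring grid with right-censoring
at the census end. Germination times are rounded **up** to the next
scoring time, which is how interval counting actually observes an event;
a useful consequence is that the observed cumulative count at each scoring
time is an unbiased binomial draw of the true model CDF at that time.
Defaults mirror a full factorial sesame-type assay: 6 cultivars' worth of
parameters can be supplied one at a time; 8 temperatures (10–45&nbsp;°C),
7 water potentials (0 to −1.2&nbsp;MPa), 4 dishes of 50 seeds, 8-h scoring,
168-h census, with generating parameters $\theta_{HT} = 500$ MPa °C h,
$T_b = 10$ °C, $\psi_{b(50)} = -0.6$ MPa, $\sigma_{\psi b} = 0.2$ MPa —
mid-range for reported sesame fits. Per-dish RNG substreams are derived
deterministically from the master seed, so extending the design never
reshuffles existing dishes.

The simulator deliberately omits features real trials have: seed dormancy
and viability loss, between-dish random effects, drift of the osmotic
potential during the test, supra-optimal shifts of $\psi_{b(50)}$ with
temperature, and scoring error. Passing recovery tests therefore
demonstrates that the estimation machinery is correct and well-conditioned
at trial scale — not that the threshold model is true of any particular
seed lot. An overdispersion hook (dish-level shift of $\psi_{b(50)}$) is
left off by default to match the model's own assumptions.

`recovery_suite` wraps the loop: simulate, extract percentiles, fit,
tabulate bias, RMSE and the fraction of runs with every parameter inside
its tolerance. The validation suite runs 20 trials at the full design
above and checks ≥ 90% joint coverage at tolerances of 15% on
$\theta_{HT}$, 1.5&nbsp;°C on $T_b$, and 0.05&nbsp;MPa on $\psi_{b(50)}$
and $\sigma_{\psi b}$; noiseless quantile data must be recovered within 1%
with probit $R^2 \ge 0.999$, and fixed-temperature slices of joint-model
data must reduce to hydrotime fits with
$\hat\theta_H = \theta_{HT}/(T - T_b)$.

The bootstrap standard error of $\theta_{HT}$ resamples replicate dishes
with replacement within each treatment (B = 200 by default, seeded),
recomputing percentiles and refitting each time; resampling dishes rather
than percentile rows respects the data's dependence structure.

## Multivariate stage

Cultivar trait profiles (e.g. eight fatty-acid percentages) are analysed by
PCA on the **correlation** matrix — traits and model parameters live on
incommensurate scales — with fitted parameters ($T_b$, $\psi_{b(50)}$,
$\theta_{HT}$) projected as *supplementary* variables: their correlations
with the component scores are reported without letting them influence the
decomposition (the eigenvalues are bit-identical with and without them).
Per component, variables get contributions (squared loading × 100, summing
to 100) and cos², their squared quality of representation. Component signs
are fixed by making each component's largest-magnitude loading positive.

Clustering is agglomerative with Ward linkage on Euclidean distances
between PC scores (HCPC), the standard default where the published
literature names only the method family; all components are retained
unless a count or cumulative-variance threshold is given. Labels are
renumbered by decreasing cluster size (ties by first member), making them
deterministic and permutation-equivariant. With six cultivars any
correlation against traits is descriptive; `trait_correlations` flags
n&nbsp;<&nbsp;10 as low-power rather than pretending otherwise.

## Limitations

- The percentile-based probit fit treats interpolated $t(g)$ values as
  data; with 8-h scoring this discretization is the dominant error source
  at high temperatures where germination is fast (finer scoring
  demonstrably reduces it).
- No weighting: all percentile observations enter the regression equally,
  though extreme deciles are estimated from fewer seeds.
- The thermal-time module covers the sub-optimal range only; dent/beta
  cardinal-temperature models are out of scope.
- Time-varying water potential (priming) and dormancy processes are not
  modelled.
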