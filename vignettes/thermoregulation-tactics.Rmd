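---
title: "Behavioural thermoregulation tactics from telemetry time series: methods"
author: "thermotactics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural thermoregulation tactics from telemetry time series: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cold-water stenothermic fish such as brook charr (*Salvelinus fontinalis*)
thermoregulate behaviourally in summer-stratified lakes: they hold in cool
water and make feeding excursions into the warm, well-mixed surface layer
(the epilimnion). Thermo-sensitive radio transmitters record each fish's
*selected* temperature hour by hour; the periodic structure of that series
— broad multi-day drifts, diel (24 h) cycles, crepuscular (12 h) and finer
(8 h, 4 h) rhythms — is an individual behavioural signature. `thermotactics`
implements the full analysis chain for such data:

1. **Temporal eigenfunction regression** of each fish's hourly
   body-temperature series, producing a *scalogram* of per-scale
   contributions to model fit;
2. **Tactic classification** by PCA of Hellinger-transformed scale-band
   totals;
3. **Lake layer detection** from thermograph profiles;
4. A **regression tree** relating daily epilimnion-excursion frequency to
   lake thermal covariates, validated by unit-blocked cross-validation,
   1-SE pruning and a permutation test;
5. A **synthetic-data module** that generates all of the above inputs with
   known ground truth.

## Temporal eigenfunctions

On a regular grid of $n$ hourly samples the basis column $k$ is
$$E_k(i) = \sin\!\left(\frac{k \pi i}{n+1}\right), \qquad i = 1, \dots, n,$$
with period $2n/k$ hours. The columns are exactly orthogonal on the
complete grid, and unlike Fourier regression the fit degrades gracefully
under missing observations (rows are simply dropped). For the canonical
450-hour window with $K = 205$ harmonics the periods run from 900 h (the
half-wave of $E_1$ spans the whole window) down to about 4.4 h.

Two filters reduce the basis before regression:

* **Moran's I retention.** Only columns whose lag-1 temporal
  autocorrelation is positive and significant (one-sided normal test with
  the randomization variance, $\alpha = 0.05$) are kept — negatively
  autocorrelated, saw-tooth-like waves model noise, not structure. The
  basis is deterministic, so the analytic approximation is used rather
  than a permutation test. A subtlety worth knowing: $I$ decays
  monotonically from $k = 2$ on, but $I(1)$ sits slightly *below* $I(2)$
  because the half-wave $E_1$ has a positive mean and mean-centring
  shortens it.
* **VIF pruning.** After listwise deletion of a fish's missing hours the
  observed-row design is no longer orthogonal. We recompute variance
  inflation factors and repeatedly delete the worst column while any
  VIF exceeds 10 (ties go to the higher, finer-scale index). The VIF is
  defined *through the origin* (from the Gram matrix of unit-scaled
  columns), not from the correlation matrix: on the complete grid every
  through-origin VIF is exactly 1, so the step responds only to the
  deletion-induced collinearity it is meant to control. The centred
  alternative would assign $E_1$ a VIF in the hundreds even with complete
  data — an artefact of its nonzero mean, not of collinearity among the
  waves.

## Scalogram: partial adjusted R²

Each fish's observed hours are regressed on the retained eigenfunctions
(OLS with intercept). The fit is summarised by the adjusted coefficient of
determination
$R^2_{adj} = 1 - (1 - R^2)\,(n_{obs}-1)/(n_{obs}-p-1)$,
and decomposed into per-harmonic contributions by leave-one-out:
$$c_k = \max\{0,\; R^2_{adj} - \max(0, R^2_{adj,-k})\},$$
where $R^2_{adj,-k}$ is the adjusted R² of the model refit without column
$k$ on the same rows. Flooring the *reduced* model's value at zero makes
the decomposition exactly additive for noise-free in-basis signals (a pure
$E_{36}$ signal yields $c_{36} = 1$, all other $c_k = 0$) and keeps the
scalogram a nonnegative, energy-like display. In practice the
contributions are obtained from a single fit via the OLS identity
$\mathrm{SSE}_{-k} = \mathrm{SSE} + \beta_k^2 / [(X'X)^{-1}]_{kk}$, which
is algebraically identical to refitting; `loo_contribution()` performs the
explicit refit and the tests verify the two agree.

On centred orthogonal designs the $c_k$ are proportional to the
predictors' variance shares; their sum exceeds $R^2_{adj}$ by the factor
$(n-1)/(n-2)$ per dropped degree of freedom, a discrepancy of order $p/n$
that vanishes for long series.

Contributions are grouped into four scale bands. For the canonical
450 h / 205-harmonic geometry the published index partition is used
verbatim — broad 1–25 (periods > 35 h), diel 26–62 (35–14 h), crepuscular
63–87 (14–10 h), fine 88–205 (< 10 h) — because no single period mapping
reproduces those printed boundaries exactly; for any other geometry the
bands are derived from the period cuts at 35, 14 and 10 h.

## Tactic classification

The fish × band matrix of cumulative contributions is Hellinger-transformed
(row-wise square root of proportions), which removes each fish's overall
fit level and leaves its *composition* across scales; PCA is then run on
the covariance matrix (the transformation already equalises scales, so no
correlation standardisation). Axes are oriented deterministically — axis 1
so the broad-band loading is positive, axis 2 so crepuscular + fine
loadings sum positive — and the four quadrants define the tactics:

| tactic | axis 1 | axis 2 | signature |
|---|---|---|---|
| I  | − | + | diel + crepuscular/fine |
| II | + | + | broad + crepuscular/fine |
| III| + | − | broad only |
| IV | − | − | diel only |

Tactics are additionally pooled by the sign of axis 1 alone ("I/IV" =
diel side, "II/III" = broad side), the contrast that carries most of the
variance. A score of exactly zero is resolved toward the positive side
and flagged (`boundary_flag`), so classification is deterministic even in
the zero-measure tie case.

## Lake layers and epilimnion occupancy

From each hourly thermograph column the downward gradient per depth
interval is computed in °C/m; the **metalimnion** is the shallowest
maximal contiguous run of intervals steeper than 1 °C/m (`meta_top` to
`meta_bottom`), and the **epilimnion** is everything above. For cell
averaging the boundary sensor at `meta_top` is counted with the
metalimnion so the layers never overlap. Daily summaries take per-hour
bounds (reported as medians) and average all (depth, hour) cells per
layer.

Because transmitters report temperature rather than depth, a fix is
classified as epilimnetic when the body temperature is at least the
hour's minimum epilimnetic temperature minus a 0.5 °C tolerance; the
tolerance absorbs the ~20 min equilibration lag of implanted transmitters.
Occupancy is undefined (and the fix dropped with a warning) for
unstratified hours.

## Excursion tree, unit-blocked CV, permutation test

Daily excursion frequency (percent of a fish-day's defined fixes that were
epilimnetic) is modelled by a least-squares binary regression tree on mean
daily epilimnion temperature, mean daily metalimnion temperature, day of
year, and year. The grower is written in-package and deliberately simple:
candidate thresholds are midpoints between consecutive distinct predictor
values; the split maximising the SSE reduction is taken (ties to the first
predictor in column order, then the smallest threshold); growth stops when
the best reduction falls below `cp` (default 0.01) times the root SSE or a
child would hold fewer than `min_leaf` (default 5) observations. The tests
check the grower against an independent exhaustive-search oracle for exact
tree equality.

Repeated fish-days of one fish are correlated, so folds of the 10-fold
cross-validation contain only whole fish: units are shuffled under an
explicit seed and dealt round-robin. For every candidate size in the
master tree's cost-complexity (weakest-link) sequence, each fold's
training tree is pruned to that leaf count and scored on the held-out
units; errors are reported relative to the total sum of squares with a
between-fold standard error. The **1-SE rule** then selects the smallest
size whose CV error is within one standard error of the minimum. On
unit-correlated data, naive observation-level CV is systematically more
optimistic than the blocked version — a property the test suite
demonstrates rather than assumes.

The pruned tree's $r^2 = 1 - \mathrm{SSE}_{tree}/\mathrm{SSE}_{root}$ is
tested by permutation: whole response blocks are reassigned among fish
with equal record counts (preserving within-fish correlation under the
null), a greedy tree of the observed leaf count is grown best-first on
each permuted dataset (for the tree sizes this pipeline produces this
coincides with growing fully and weakest-link-pruning; growing directly
to the target complexity keeps large calibration studies fast), and
$$p = \frac{\#\{r^2_{null} \ge r^2_{obs}\} + 1}{m + 1}.$$
Under a null with unit-correlated noise the rejection rate at
$\alpha = 0.05$ is calibrated (checked over 500 replicates with $m = 99$).
Note the permutation only has power when covariates differ between fish
records; if every fish shared an identical covariate sequence, permuting
whole blocks would not alter the design at all.

## The synthetic study

The generators define the conditions under which the pipeline is
validated:

* **Lake** — logistic depth profile
  $T(z,t) = T_{hypo} + (T_{surf}(t)-T_{hypo})/(1+e^{(z-z_0)/w})$ with
  $T_{hypo} = 6$ °C, surface base 23.5 °C, a 1.5 °C linear seasonal drift,
  a 0.75 °C diurnal cycle peaking mid-afternoon, thermocline at 3.2 m with
  width 0.55 m, and 0.02 °C sensor noise; depths 0–10 m at 0.5 m, hourly.
  These values give an epilimnion in the low-to-mid 20s over a metalimnion
  gradient of several °C/m starting near 1.5 m — the mid-summer regime of
  a small temperate oligotrophic lake — and every hourly column is
  stratified by the >1 °C/m criterion.
* **Fish series** — per-tactic sums of sinusoids (I: 24 + 12 + 8 h;
  II: 300 + 12 + 8 h; III: 300 h; IV: 24 h; dominant amplitudes
  1.5–2 °C), seeded random phases, AR(1) noise (coefficient 0.6,
  innovation sd 0.3 °C) mimicking thermal inertia rather than white
  noise, and missing-completely-at-random dropout drawn per fish from
  9–35 %, realised as an exact count so the requested rate is hit up to
  rounding. Receiver dropout in the field is equipment-driven, so MCAR is
  the appropriate mechanism.
* **Telemetry** — four fixes per day (dawn/day/dusk/night), random-walk
  positions with gamma step lengths whose mean is 150 m on cool-epilimnion
  days and 60 m on warm days (threshold 22.4 °C).
* **Excursion records** — expectation is a step function: 1 % when the
  epilimnion mean exceeds 22.4 °C, otherwise 40 % when the metalimnion
  exceeds 12 °C and 10 % below, plus truncated Gaussian noise (sd 5
  points) clipped to [0, 100]. Covariates are drawn uniformly
  (epilimnion 20–26 °C, metalimnion 10–15 °C) *per fish-day record*,
  emulating fish-specific tracking windows across pooled study years;
  this per-record variation is also what gives the unit-block permutation
  test its power (see above).

What the generators do **not** emulate: spatial heterogeneity of the lake,
behaviourally driven (non-MCAR) data gaps, transmitter measurement error,
phase coupling between fish, or bioenergetic movement rules. Passing the
recovery tests therefore shows the *estimators* work under the assumed
data-generating structure, not that real populations satisfy that
structure.

## Numerical choices and problem sizes

* All stochastic steps take explicit integer seeds; generators save and
  restore the global RNG state, so they never perturb a caller's stream.
* OLS uses QR (`lm.fit`); the leave-one-out drops use the Cholesky inverse
  of $X'X$. Post-VIF designs are well conditioned by construction.
* Degenerate inputs error early with named reasons: constant series,
  zero-row band totals (naming the individual), unstratified hours,
  duplicate fix timestamps, empty Moran retention.
* The test suite runs the full canonical geometry (450 h, 205 harmonics)
  where the claim depends on it — argmax recovery under 35 % dropout
  (100 replicates), pooled-tactic recovery (20 populations × 16 fish),
  threshold recovery (20 datasets of 1 008 fish-days) — and a 240 h / 96
  harmonic grid for unit tests where geometry is incidental. Permutation
  calibration uses 500 replicates of 10 units × 8 observations with
  $m = 99$. The whole suite completes in a few minutes on one CPU.

## Known limitations

* The partial-R²adj decomposition is one defensible definition among
  several; alternatives (e.g. LMG averaging over orderings) would change
  per-harmonic values but not the band-level picture for well-separated
  signals.
* With fewer than ~3 observations per depth the layer detector cannot
  run; profiles with surface-starting gradients yield an empty epilimnion
  and undefined occupancy.
* The permutation scheme requires fish with equal record counts to
  exchange blocks; fish with unique counts keep their own responses. With
  very ragged designs the effective permutation space shrinks.
* Band boundaries for non-canonical geometries follow the period cuts,
  which is a convention; results near a cut should be read with that in
  mind.
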