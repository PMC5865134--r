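---
title: "Small-area disease mapping with carmap: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area disease mapping with carmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carmap)
```

`carmap` maps the incidence of prehospital emergency events across
administrative regions. This vignette explains the statistical machinery,
the parameters that matter, the design decisions taken where the
methodology leaves genuine freedom, and what the synthetic validation
studies do and do not demonstrate.

## The model

For region $i$ with observed caseload $O_i$ and expected caseload $E_i$
(from indirect age–gender standardisation), the Besag–York–Mollié (BYM)
model is

$$O_i \sim \mathrm{Poisson}(\mu_i), \qquad
\log \mu_i = \log E_i + \alpha + x_i^\top\beta + u_i + v_i,$$

where $u$ is a spatially structured random effect with an intrinsic CAR
prior over the Queen-contiguity graph — conditionally,
$u_i \mid u_{-i} \sim N(\bar u_{N(i)},\ 1/(\tau_u n_i))$ with $n_i$ the
neighbour count — and $v_i \sim N(0, 1/\tau_v)$ is unstructured
heterogeneity. $\exp(\alpha + x_i^\top\beta + u_i + v_i) = \mu_i/E_i$ is
the region's smoothed standardised incidence ratio (SIR). The ICAR prior
is improper (constant shifts within each connected component of the map
are unidentified); we resolve this the classical way, re-centring $u$ to
zero mean within every connected component at each sweep, with island
regions (degree 0) held at $u_i = 0$ so their extra variability is
carried entirely by $v_i$.

### Priors

The hyperpriors follow the diffuse conventions of the disease-mapping
software era in which this model became standard: $\tau_u, \tau_v \sim
\mathrm{Gamma}(0.5, 0.0005)$ (shape, rate) and
$\alpha, \beta_j \sim N(0, 10^6)$. All are configurable through
`bym_priors()`. Nothing in the applications we emulate reports
variance-component estimates, so there is no empirical anchor for
$\tau_u, \tau_v$; the generator's default of 10 for both (giving random
effects with standard deviations around 0.2–0.4 on the log-risk scale,
i.e. regional risk variation of roughly ±20–40%) was chosen once as a
realistic magnitude for chronic-disease emergency mapping and is a design
choice, not a calibration.

## The sampler

`fit_bym()` runs an Rcpp Metropolis-within-Gibbs sampler:

* conjugate Gamma draws for $\tau_u$ (shape $a + r/2$ with $r$ the ICAR
  rank, $\sum_c (|c| - 1)$ over non-island components; rate
  $b + \tfrac12 u^\top(D - W)u$) and for $\tau_v$;
* random-walk Metropolis for $\alpha$, each $\beta_j$, each $u_i$
  (against Poisson likelihood plus the ICAR full conditional) and each
  $v_i$. Proposal standard deviations are an adaptive multiplier over
  $1/\sqrt{\text{approximate conditional precision}}$ (prior precision
  plus the observed count), so proposals keep pace with the current
  precision draws; the multipliers adapt every 100 sweeps during burn-in
  toward acceptance rates of 0.2–0.5 and are frozen afterwards, so
  detailed balance holds for every retained draw;
* a joint scale move on $(u, \tau_u)$ and on $(v, \tau_v)$: propose
  $s = e^\varepsilon$, rescale the effect vector by $s$ and the precision
  by $s^{-2}$. The prior kernel $\tau\,u^\top(D-W)u$ is invariant and the
  normalising and Jacobian terms cancel to
  $\log r = \Delta\ell - 2a\varepsilon - b\tau(s^{-2} - 1)$. Without this
  move the precisions mix slowly (their marginal chains must wait for the
  whole effect vector to change magnitude one region at a time), and the
  Monte-Carlo error of $\tau_u$ fails the usual "MC error below 5% of the
  posterior SD" reporting criterion at bench scale; with it, all
  monitored parameters sit comfortably below 2%.

Fitted means are cached and updated multiplicatively on acceptance, with
a periodic full recomputation to stop floating-point drift; a non-finite
fitted mean aborts with a diagnostic message. Chain $k$ is seeded
`seed + k - 1`; there is no hidden global random state anywhere in the
package — every stochastic function takes an explicit seed.

### Chain lengths

`mcmc_config()` defaults to a production-scale run (2 chains, 100,000
burn-in, 500,000 iterations, keeping every other draw — thinning applies
after burn-in). The validation studies and examples use a bench scale of
2 × 5,000 burn-in + 20,000 iterations (thin 2), which for 80-region maps
yields Gelman–Rubin statistics below 1.01 and MC-error ratios below 2% on
null data; an 80-region fit takes on the order of a second. DIC is
computed from the pooled thinned draws as $2\bar D - D(\hat\mu)$ with
$\hat\mu$ the posterior mean of $\mu$.

### Posterior summaries

Smoothed SIRs are summarised by the posterior **median** (the methodology
we follow never states mean versus median; medians are consistent with
the reported quantile intervals) and equal-tailed 95% credible intervals
from linear-interpolation percentiles. A region is flagged *elevated*
when the CrI lower bound strictly exceeds 1; a bound exactly at 1 does
not flag. The same percentile rule is used everywhere quantiles appear
(quintile boundaries, age IQRs, coefficient intervals).

## Covariate modelling

Continuous area covariates are cut into quintiles at their 20/40/60/80
percentiles. Assignment is left-closed above: a value equal to a cut
point joins the upper category, matching the "category 5: ≥ cut" style of
published index tables, and ties at a boundary all move up. Covariates
with externally defined classes (e.g. a six-level remoteness index) enter
through `precategorised()` unchanged. Quintiles are computed unweighted
over regions. Categorical blocks use reference-cell coding against
category 1.

`univariable_screen()` fits one model per covariate and orders them by
DIC. `stepwise_multivariable()` then adds covariates in that order,
retaining a block iff at least one of its category coefficients has a 95%
CrI excluding zero (equivalently, an SIR-ratio CrI excluding 1 — the two
are the same statement since $\exp$ is monotone). Selection is
forward-only: a covariate rejected once is not revisited, and covariates
accepted earlier are never removed even if a later addition erodes their
significance — a deliberate, documented divergence risk of stepwise
procedures generally. Whole blocks are kept or dropped; we never retain a
subset of categories. Correlated index families (such as the four
census-derived socioeconomic indices) are reduced to one configured
representative by `select_seifa_representative()` before the stepwise
stage.

## The synthetic-data generator

The generator emulates the area-level inputs of a state-wide ambulance
study — roughly 80 regions, 18 age–gender strata, expected caseloads of a
few hundred per region — with known ground truth:

* `generate_lattice(8, 10)`: 80 unit squares standing in for a state's
  local government areas. Queen degrees run 3–8 (a real map's irregular
  polygons gave a median of 5, range 1–9; the lattice is deliberately
  regular so that geometry is exact).
* `generate_population()`: region totals uniform on 20,000–100,000,
  split multinomially by a fixed adult-skewed pyramid (the published
  strata define only the labels, not proportions).
* `default_baseline_rates()`: stratum rates rising steeply with age
  (overall ≈ 60–70 cases per 10,000 residents over the study window,
  male rates 1.35× female), mirroring the strong old-age skew of diabetic
  emergency caseloads.
* `simulate_spatial_effects()`: exact ICAR draws via the
  eigendecomposition pseudo-inverse of $\tau_u(D - W)$ with per-component
  centring — exactness is what lets the tests check the quadratic form
  against dense-matrix oracles — and iid normal $v$.
* `simulate_counts()`: Poisson counts at region × stratum level, so
  state-wide stratum totals can be re-aggregated downstream and the
  indirect-standardisation identity $\sum_i E_i = \sum_g \text{cases}_g$
  holds *exactly* when regions partition the standard population.

What the generator does **not** emulate: repeat callers (every case
independent), within-region population movement, irregular polygon
geometry, missing-data windows, or temporal drift in rates (a single
mid-period population table is used, with no interpolation across study
years). Passing tests therefore demonstrate correctness of the
*computations* under the stated generative model, not robustness to those
real-data complications.

## Validation studies and their design

The acceptance suite (`tests/testthat/test-acceptance.R`, re-run
numerically by `scripts/acceptance.R`) checks:

1. **Conservation** — expected caseloads sum to the state caseload to
   relative error $10^{-9}$ on a full synthetic state.
2. **Oracle equivalence** — expected caseloads, Poisson log-likelihood,
   the ICAR quadratic form and Queen adjacency each match independent
   brute-force or dense-matrix computations on small instances.
3. **Parameter recovery** — 50 replicates, 80 regions, one binary
   covariate with $\beta = 0.7$, $\tau_u = \tau_v = 10$, bench-scale
   chains: the 95% CrI covers the truth in ≥ 85% of runs and the median
   of $\exp(\hat\beta)$ is within 10% of $e^{0.7}$. The covariate is
   assigned to regions **at random**: assigning it as two contiguous
   blocks of the map confounds it with the ICAR field (the smooth spatial
   effect can absorb a smooth covariate), visibly biasing $\beta$
   downward. That spatial-confounding sensitivity is a well-known
   property of BYM ecological regression and worth remembering when
   interpreting real covariate effects.
4. **Null calibration** — with all effects zero, ≥ 95% of regions'
   smoothed-SIR CrIs contain 1, all monitored parameters (intercept,
   precisions, every regional SIR) have $\hat R < 1.1$, and every
   MC-error/SD ratio is below 5%.
5. **Stepwise operating characteristics** — 25 replicates with one
   dose-dependent predictive quintile covariate (category effects 0,
   0.18, 0.35, 0.53, 0.7) and one null covariate: the predictive one is
   retained and the null excluded in ≥ 80% of runs. Note the null
   exclusion rate is bounded near $0.95^4 \approx 0.81$ by the familywise
   error of four category tests — an inherent property of block
   significance testing, not a defect.
6. **Worked-example arithmetic** — case-mix shares (e.g. 27,483 of
   39,332 cases = 69.9%) and SIR↔percent-risk conversions
   (0.70 → −30%, 2.02 → +102%) reproduce exactly.

Problem sizes (80 regions, 50/25 replicates, 2 × 25,000-sweep chains)
were chosen as the smallest at which these operating characteristics are
statistically meaningful while keeping the whole suite runnable in a few
minutes on a single core.

## Numerical conventions and degenerate inputs

* Regions with $E_i = 0$ and $O_i = 0$ get an *undefined* crude SIR flag
  (never a silent 0) and must be excluded before modelling; $E_i = 0$
  with $O_i > 0$ is an error, since it contradicts the standardisation
  that produced $E$.
* Polygon comparisons snap coordinates to a $10^{-9}$ grid; Queen
  contact is "shares at least one snapped boundary point". This is exact
  for lattices and guillotine tilings; real-world shapefiles with
  sliver mismatches are out of scope.
* GAL files use the GeoDa dialect (count header; `id degree` line then a
  neighbour-id line per region); both bare-count and four-token headers
  are read. Asymmetric files are rejected naming the offending pair.
* All CSV/GeoJSON exports print full precision, so re-imports reproduce
  values bit-for-bit; display rounding (SIR to 2 dp, percentages to 1 dp)
  happens only in print methods.
* Batch-means MC error uses 50 equal batches, dropping any trailing
  remainder; the Gelman–Rubin statistic is the classic
  $\sqrt{\{(n{-}1)/n\,W + B/n\}/W}$ (identically duplicated chains give
  $\sqrt{(n-1)/n}$, marginally below 1).

## Known limitations

Forward-only stepwise selection inherits the instabilities of all
stepwise procedures; the BYM model cannot separate spatially smooth
covariate effects from the ICAR field (see above); DIC comparisons
between models with different random-effect structures are informal; and
the sampler is designed for the hundreds-of-regions scale — production
chain lengths on much larger maps would warrant blocked updates.
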