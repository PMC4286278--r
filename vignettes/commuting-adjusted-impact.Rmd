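---
title: "Commuting-adjusted attributable deaths: models, assumptions and design choices"
author: "commutad"
output: rmarkdown::html_vignette
---

# Scope

`commutad` estimates the short-term impact of annual average PM10 on total
mortality at the municipality level, under counterfactual
pollution-reduction scenarios, while accounting for daily
intermunicipality commuting and propagating the uncertainty of every
input.  The pipeline has four probabilistic inputs -- smoothed mortality
rates, a predicted PM10 surface, concentration-response effects, and
commuting probabilities -- and one deterministic calculus that combines a
joint draw from each input into attributable deaths (AD).  A
synthetic-region generator with known ground truth makes every stage
testable offline.

# The attributable-death calculus

For a static population, the deaths in municipality $i$ attributable to
concentrations above a threshold $x_0$ under a log-linear
exposure-response are

$$AD_i = y_i - y_i / \exp\{\beta_i (x_i - x_0)\, I(x_i > x_0)\},$$

with $y_i$ total deaths, $\beta_i$ the log relative risk per $\mu g/m^3$
and $x_i$ the annual average concentration.  With commuting, each
municipality's impact is split into three parts:

* $A_i$ — deaths among residents of $i$ attributable to exposure in $i$
  (the static share of the population);
* $B_i$ — deaths among residents of $i$ attributable to exposure in the
  municipalities $j$ where they commute ("imported" impact);
* $C_i$ — deaths among non-residents attributable to exposure in $i$
  ("exported" impact).

Commuters are assumed to spend a fraction `share` (default 1/3,
representing a balance between travel time and weekend breaks) of their
time at the destination.  Expected death counts are

$$\mu_i^S = \left(pop_i - \tfrac13\sum_{j\neq i} exit(i,j)\right) r_i,
\qquad \mu_{ij}^C = \tfrac13\, exit(i,j)\, r_i,$$

which conserve person-time exactly: $\mu_i^S + \sum_j \mu_{ij}^C = pop_i\,
r_i$.  Realized counts $y_i^S, y_{ij}^C$ are Poisson draws around these
means (intrinsic variability of death counts); an `expected_counts` mode
replaces draws by their means for deterministic testing.  The effect
applied to each term is that of the municipality of *exposure*, the
mortality rate that of the municipality of *residence*.  Because the same
$y_{ij}^C$ matrix feeds both the $B$ (row) and $C$ (column) sums,
$\sum_i B_i = \sum_i C_i$ holds exactly in every draw — this is a
structural identity, not an approximation, and the test suite asserts it
at $10^{-10}$ relative tolerance.

Two impact measures are reported: $AD^{A+B}_i = A_i + B_i$ (burden on
residents of $i$ wherever exposed) and $AD^{A+C}_i = A_i + C_i$ (burden
caused by exposure in $i$ on all residents of the region).

## Scenarios

Thresholds follow four rules: `RS0` ($x_0 = 20\ \mu g/m^3$, the WHO annual
guideline), `RS1` ($x_0 = 40$, the EU annual limit), `RS2` (20% reduction
where $x > 20$, or less if sufficient to reach 20: $x_0 = \max(0.8x,
20)$), and `RS3` (the same rule anchored at 40).  The rules are pointwise
ordered, so with shared death-count draws the per-draw, per-municipality
impacts satisfy $AD(RS3) \le AD(RS1) \le AD(RS0)$ and $AD(RS3) \le
AD(RS2) \le AD(RS0)$, which the suite checks on every draw.

## Negative sampled effects

Impact measures presume a harmful exposure, so a negative sampled effect
cannot contribute negative attributable deaths.  The default (`truncation
= "term"`) applies $\beta^+ = \max(\beta, 0)$ inside every term that uses
that effect, which is equivalent to zeroing the AD of the municipality
whose effect was negative without coupling unrelated municipalities.  An
alternative reading — discard the whole draw's AD when any effect is
negative — is available as `truncation = "draw"`.  The source analysis
does not specify which of the two it used inside the commuting cross
terms; term-level is the default here because draw-level truncation makes
municipality $i$'s impact depend on the sign of an unrelated
municipality's effect.

# Input models

## Mortality rates (BYM)

Five-year death counts are Poisson, $deaths_i \sim
\mathrm{Pois}(D_i r_i)$ with $D_i$ five times the census population, and
$\log r_i = \alpha + u_i + v_i$ with exchangeable $u_i \sim N(0,
\tau^2_u)$ and intrinsic-CAR $v$ (conditional mean the neighbour average,
conditional variance $\tau^2_v / n_i$).  Two departures from the bare
model statement, both standard: an explicit intercept $\alpha$ with a
vague normal prior (the level is otherwise unidentified once $u$ has mean
zero), and a sum-to-zero constraint on $v$ imposed by re-centring each
sweep (the usual propriety fix for the improper ICAR prior; isolated
municipalities have $v_i$ pinned at 0).  "Noninformative inverse gamma"
variance priors are instantiated as InvGamma(0.5, 0.0005), the
conventional weakly-informative choice of the disease-mapping
literature; both are configurable.

The sampler (Rcpp) uses single-site adaptive random walks plus three
non-local moves that repair the notoriously slow directions of the BYM
posterior: a level swap $(\alpha + \delta, u - \delta)$, joint rescalings
$(u, \tau^2_u) \to (cu, c^2\tau^2_u)$ (and likewise for $v$), and a
balance move $(u, v) \to (u + (1-c)v, cv)$ that shifts scale between the
two layers without touching the likelihood.  Defaults: 4 chains, 2,000
warmup + 2,000 sampling iterations thinned to 1,000 total draws.
Split-chain convergence statistics are reported for every rate, the
intercept and both variances; rates converge comfortably below 1.05 on
the desk-scale region, while the two variance parameters — whose split is
identified only weakly by the priors — may show statistics around 1.2-1.4.
Since the pipeline consumes rates only, the warning threshold is applied
to rates.  Calibration is verified by recovery: across 20 synthetic
regions the 80% intervals cover the true rates at the nominal rate and
the posterior mean beats the crude rate in RMSE.

## PM10 surface (Bayesian universal kriging)

Log monitor concentrations are multivariate normal with mean $\alpha +
\beta z_s$ ($z_s$ the deterministic dispersion-model prediction at the
monitor's grid cell) and covariance $\sigma^2 \exp(-\phi d^{\kappa})$.
The stated prior constraint — correlation "one" at the minimum distance
(3 km) and "zero" at the maximum (250 km) — is operationalized as
$\ge 0.95$ and $\le 0.05$: given $\kappa$, $\phi$ is uniform on
$[-\ln(0.05)/250^{\kappa},\ -\ln(0.95)/3^{\kappa}]$.  That interval is
empty below $\kappa \approx 0.92$, so the $\kappa$ prior is uniform on
$(0.92, 2]$ (the interval ordering as literally transcribed elsewhere
would be reversed and empty for all $\kappa$; the constraint itself
dictates the ordering used here).  A small nugget ($10^{-4}$ on the log
scale, configurable to 0) stabilizes the covariance; at nugget 0 the
predictive interpolates monitors exactly, which the suite asserts.

Coefficients are updated by conjugate Gibbs steps, $(\kappa, \phi,
\sigma^2)$ by an adaptive joint random walk on transformed coordinates
respecting the prior box.  Prediction at all grid cells is a joint
conditional-Gaussian simulation per parameter draw (never marginal), so
between-cell correlation is preserved; parameter draws are taken evenly
across chains.  Municipality values are equal-weight means over owned
cells on the concentration scale (area weighting on a uniform grid; the
original account does not say whether its integration was area- or
population-weighted, and the weight matrix interface accepts either).

Leave-one-out cross-validation reports RMSE and fractional bias
$FB = 2(\bar p - \bar o)/(\bar p + \bar o)$, both on the log scale (FB in
%; no formula is given in the source, so the standard air-quality
definition is used).  By default LOOCV reuses full-data parameter draws
with exact leave-one-out conditional prediction via the precision-matrix
identity; `refit = TRUE` refits per fold.  The default was chosen for
desk-scale runtime and the source does not say which it did.

## Effects (random-effects meta-analysis)

City estimates $\hat\theta_k \sim N(\theta_k, se_k^2)$, $\theta_k \sim
N(\mu, \tau^2)$, vague normal prior on $\mu$, half-normal on $\tau$.
Municipalities hosting an estimate take their city's $\theta$ draws; all
others take posterior-predictive generic-city draws $\beta_{new} \sim
N(\mu^{(d)}, \tau^{(d)2})$.  By default one generic draw per iteration is
*shared* by all unmapped municipalities — the phrase "a generic
city-specific effect" is singular, and sharing preserves
between-municipality correlation — with an independent-per-municipality
mode behind a flag to document the ambiguity.  Effects are stored as log
RR per 1 $\mu g/m^3$; converters to percent change per 10 $\mu g/m^3$ are
provided.  Negative effect draws are legitimate here (truncation is the
impact engine's job).  With `tau_fixed = 0` the fixed-effect limit is
computed in closed conjugate form, so it matches the precision-weighted
mean identically.

## Commuting (conjugate beta)

The census count $c_{ij}$ out of $pop^{2001}_i$ trials with a uniform
beta prior gives $p_{ij} \sim \mathrm{Beta}(1 + c_{ij},\ 1 + pop^{2001}_i
- c_{ij})$, independent across pairs.  Flow draws use $exit(i,j) \sim
\mathrm{Binomial}(pop^{2007}_i, p_{ij})$ — the 2007 intercensual
population supplies the trials while the 2001 census informs the
posterior; both populations are kept as distinct fields.  No simplex
constraint is imposed on $\sum_j p_{ij}$ (probabilities are tiny in
practice); a guard resamples any row whose flows would reach the
population, and the event count is reported (zero at realistic inputs).
One flow tensor draw is used everywhere within a Monte Carlo iteration,
which is what makes the $\sum B = \sum C$ identity exact.

# Monte Carlo propagation and summaries

1,000 draws by default.  Draw $d$ consumes row $d$ of every input matrix
(row alignment preserves each input's between-municipality posterior
correlation; nothing is resampled across rows), one flow tensor, and one
set of Poisson death counts shared across scenarios.  The master seed
spawns independent sub-streams for flows and counts so stages can be
re-run independently.  Summaries are computed sum-then-summarize: group
draws are summed within the group first and quantiles taken across draws,
which is what makes group credible intervals valid under correlation.
Percentiles use linear interpolation between order statistics (R type 7),
fixed for bit-reproducibility; the 80% interval spans the 10th-90th
percentiles and the posterior median (not the mean) is the point summary,
a conservative choice given the truncation at zero.  `Pr(C > B)` counts
strict inequality; ties count against.  The attributable community rate
(ACR) is $10^5 \cdot AD/pop$, computed from the posterior-median AD — the
published province tables are reproducible from their own printed medians
and populations under exactly this convention.

# The synthetic world

`make_lattice_region()` builds a square rook-adjacency lattice (default
7x7 = 49 municipalities, 4 grid cells of 4x4 km each), provinces as
contiguous ~3-wide blocks, log-uniform populations between $10^3$ and
$10^5$ with the largest member of each province flagged capital and
inflated 4x.  `simulate_truth()` draws log rates from the BYM generative
model itself (ICAR component simulated on the sum-to-zero subspace via
the Laplacian pseudo-inverse — the proper realization of the improper
prior), a log-scale PM10 field of background 24 $\mu g/m^3$ plus a
nearest-capital bump (~+65% at a capital, 15 km decay; the nearest-bump
rather than a sum keeps a dense capital layout from compounding into
implausible levels) plus a smooth Gaussian process (sd 0.15, 30 km
range), effects from $N(\log(1.01)/10, (6\times10^{-4})^2)$ — a mean of
+1% mortality per 10 $\mu g/m^3$ with heterogeneity large enough that
low-effect cities have substantial probability of a negative draw — and
gravity commuting $p_{ij} \propto pop_j^{0.8} e^{-d_{ij}/15}$ with a 3x
capital attraction, scaled to a 30% out-commuting fraction (7% for
capitals, mirroring the capital-centred pattern of the real flows).

`observe_study()` applies the stated observation models: Poisson deaths
over five years, binomial commuting counts, lognormal monitor noise (sd
0.05), and dispersion-model predictions $z = 0.9 \cdot field + 2 +
$ smooth error — an affine distortion that forces the kriging regression
to estimate a non-trivial $(\alpha, \beta)$.  City effect estimates (one
per capital, se $3\times10^{-4}$) emulate externally fitted time-series
estimates, whose internal regressions are out of scope.

What a green test does and does not establish: the generator emulates the
*structure* of the real inputs (spatially correlated rates and exposure,
monitor sparsity, capital-centred flows, heterogeneous effects), not
their magnitudes or geography, and it omits age structure, intra-annual
variation, intraurban commuting and cross-border flows — as does the
method itself.  Recovery tests therefore establish statistical
correctness of the machinery, not the real-world numbers.

One calibration subtlety is worth recording.  The kriging likelihood
regresses *log* concentration on a *concentration-scale* covariate, so
data generated by the affine field distortion are mildly misspecified for
the model (the smooth curvature is absorbed by the spatial term, but
interval calibration at cells is not guaranteed — and with a near-zero
nugget the model also treats monitor noise as signal).  The calibration
acceptance test therefore simulates fields from the kriging model class
itself on the synthetic grid, with the spatial parameters drawn from
their prior per replicate (the standard simulation-based-calibration
design); the distorted-world data are used for the LOOCV error bound and
the exact-interpolation check, where no calibration claim is involved.

# Numerical choices and degenerate inputs

* Percentiles: type 7, asserted against a sort-based oracle.
* Kriging covariances are Cholesky-factorized with a tiny ridge
  ($10^{-12} + 10^{-9}\sigma^2$) on the predictive covariance.
* `export_import_log_ratio` returns flags, not errors: $+\infty$
  (exporter only), $-\infty$ (importer only), `NaN` (no commuting impact
  at all); report tables render them as labels.
* Zero-death municipalities are valid inputs everywhere (the rate
  posterior stays positive); zero commuting matrices are valid and
  collapse the engine to the static pipeline exactly, draw by draw.
* All randomness flows from explicit seeds; identical seeds give
  bit-identical arrays, asserted in the suite.

# Known limitations

Annual averages are the only exposure metric (no daily series); total
mortality only, no age standardization or morbidity; exposure assumed
homogeneous within a municipality; commuter frailty assumed equal to the
general population's; the time-at-destination share is a single global
constant; no structural-uncertainty assessment of the log-linear
exposure-response itself.
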