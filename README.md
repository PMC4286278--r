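# commutad

Commuting-adjusted short-term health impact assessment of air pollution,
with full uncertainty propagation.

## The problem

Health impact assessments of particulate matter usually ask: how many
deaths in each area are attributable to concentrations above a policy
threshold?  Two things routinely undermine the answer at the municipality
scale.  First, every input is an estimate — small-area mortality rates
are noisy, the pollution surface is predicted rather than observed,
concentration-response effects come from a meta-analysis, commuting flows
from a census — and the uncertainty must be propagated, not ignored.
Second, people are not static: commuters are exposed where they work or
study, so a city's pollution harms residents of other municipalities and
vice versa.

`commutad` is a reusable pipeline for this problem, aimed at
environmental epidemiologists and regional public-health analysts.  Every
input gets a Bayesian model producing joint posterior draws, and a Monte
Carlo engine combines them, draw by draw, into attributable-death (AD)
distributions per municipality under four reduction scenarios.

## Models at the core

| Input | Model |
|---|---|
| Mortality rates `r_i` | BYM small-area smoothing: `deaths_i ~ Pois(D_i r_i)`, `log r_i = α + u_i + v_i`, exchangeable `u` + intrinsic-CAR `v` (own Rcpp MCMC) |
| PM10 surface `x_i` | Bayesian universal kriging: `log(x) ~ MVN(α + β z, σ² exp(−φ d^κ))` calibrating monitors against deterministic-model predictions `z`, joint predictive at grid cells, aggregated to municipalities |
| Effects `β_i` | Normal-normal random-effects meta-analysis; known cities keep their posterior, all others share a posterior-predictive "generic city" effect |
| Commuting `p_ij` | Conjugate `Beta(1 + c_ij, 1 + pop_i − c_ij)` per ordered pair; flows `exit(i,j) ~ Binomial(pop_i, p_ij)` |

The impact calculus splits each municipality's burden into `A_i` (deaths
among residents from local exposure), `B_i` (residents' deaths from
exposure where they commute — "imported"), and `C_i` (non-residents'
deaths from exposure here — "exported"), using
`AD = y − y/exp(β⁺ (x − x0) I(x > x0))` per person-time block, with
commuters spending one-third of their time at the destination.  Per draw,
`Σ B_i = Σ C_i` exactly.  Scenarios: RS0 (`x0 = 20` µg/m³, WHO guideline),
RS1 (`x0 = 40`, EU limit), RS2/RS3 (20% reduction capped at those limits).
Negative sampled effects contribute zero AD; summaries are posterior
medians with 80% credible intervals (10th–90th percentiles).

## Worked example

Everything below runs offline on a synthetic 49-municipality region with
known ground truth (no external data needed):

```r
library(commutad)
study <- simulate_study(seed = 1)            # 7x7 lattice, 12 monitors
res   <- run_pipeline(study, seed = 42, n_draws = 1000)
res$impact
#> impact_draws: 1000 draws x 49 municipalities
#>   regional median AD(A+B): RS0=325.1, RS1=40.8, RS2=143.4, RS3=36.2

summarize_impact(res$impact, study$region$pop2007, "region")
#>   scenario ad_ab_median ad_ab_lo80 ad_ab_hi80 pr_ad_positive acr_median
#> 1      RS0        325.1      255.4      399.4              1      11.49
#> 2      RS1         40.8       20.1       71.7              1       1.44
#> 3      RS2        143.4      112.7      175.3              1       5.07
#> 4      RS3         36.2       19.3       53.5              1       1.28
```

Read: in this synthetic region (2.83 M inhabitants), annual PM10 above
20 µg/m³ accounts for a median 325 deaths in the study year (80% CrI
255–399), i.e. an attributable community rate of 11.5 per 100,000; only
41 of those are above the EU limit of 40 µg/m³, and a 20% reduction
capped at 20 µg/m³ would avert a median 143.  `report_tables(res$impact,
study$region)` emits the province table, the ACR table, the capital
export/import table (`Pr(C > B)` per capital) and the per-municipality
log export/import ratio; capitals show `Pr(C > B)` near 1 — they export
impact to their commuter belt:

```r
report_tables(res$impact, study$region)$table3[3:4, c("city", "ad_ab_median", "ad_ac_median", "pr_c_gt_b")]
#>   city ad_ab_median ad_ac_median pr_c_gt_b
#> 3   12           58           60      0.98
#> 4   25           47           49      0.98
```

A command-line interface is installed with the package
(`system.file("cli", "commutad", package = "commutad")`):

```sh
commutad simulate --side 7 --n-monitors 12 --seed 1 --out-dir study/
commutad impact --in-dir study/ --scenarios RS0,RS1,RS2,RS3 --draws 1000 --seed 42 --out-dir out/
commutad report --in-dir study/ --impact-dir out/ --out-dir tables/
```

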