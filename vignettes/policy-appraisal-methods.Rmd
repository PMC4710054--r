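---
title: "Methods: appraising alcohol pricing policies on survey microdata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: appraising alcohol pricing policies on survey microdata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcpolicy)
```

## The model in one paragraph

`alcpolicy` estimates, for a declared alcohol policy, the downstream change
in consumption, spending, revenues, and health, crime and workplace harms
over a ten-year horizon. A policy first transforms a weighted,
transaction-level distribution of prices paid per unit of ethanol (a
minimum unit price lifts every sub-floor price to exactly the floor; a
percent rise multiplies prices; a discount restriction raises sold prices
toward usual prices). The induced vector of sixteen mean percent price
changes — one per beverage category (beer, wine, spirits, RTDs × on-/off-trade
× low/high price tier) — is mapped to sixteen percent consumption changes
through a 16×16 own- and cross-price elasticity matrix, estimated separately
for two demand segments (moderate drinkers; hazardous and harmful drinkers
combined). Those aggregate changes are applied uniformly to each
individual's consumption record, peak-day drinking is revised through a
linear peak-from-mean model, and the revised consumption distributions
drive harm through relative-risk functions and the potential impact
fraction (PIF),

$$\mathrm{PIF} \;=\; 1 - \frac{\sum_i w_i\,RR_i'}{\sum_i w_i\,RR_i},$$

where $w_i$ are survey sample weights, $RR_i$ the relative risk at baseline
consumption and $RR_i'$ at post-policy consumption. Revised absolute harm
rates are baseline rates times $(1-\mathrm{PIF})$, projected per subgroup
cohort over ten years and monetised.

## Population structure

Individuals are classified into 54 subgroups: 9 age bands (11–15 through
75+) × 2 sexes × 3 drinking levels. Moderate means at most 168 g
ethanol/week for men and 112 g for women; harmful means strictly more than
400 g (men) / 280 g (women); hazardous lies between. One UK unit is 8 g of
ethanol. Binge status is a peak-day intake strictly above 64 g (men) / 48 g
(women). Three boundary conventions are deliberate and tested:

* consumption exactly at the harmful threshold is *hazardous* (the verbal
  definitions leave equality unassigned; we close the hazardous band at its
  upper bound);
* abstainers are moderate drinkers for classification purposes, with their
  zero consumption and empty beverage mix retained for demand handling;
* the 11–15 band uses the same binge thresholds as adults — no separate
  youth limit is defined, and we flag this as a convention rather than an
  evidence-based choice.

## What the synthetic generators emulate — and what they do not

No public microdata ship with the package; seeded generators stand in for
the two survey inputs.

**Consumption survey.** Per sex × age band cell: an abstainer fraction, a
log-normal mean-weekly-units distribution (right-skewed, two parameters),
a sparse Dirichlet beverage mix over the 16 categories, and a peak-day
value from the linear peak-from-mean model plus a Gaussian residual. The
real instrument is an empirical non-parametric sample; the generator's
contract is only right skew with configurable location and scale, never
distributional fidelity to any real population. Defaults (median weekly
units peaking around 14 for men aged 25–34, abstainer fractions 12–55%
rising at the age extremes, female consumption roughly 60% of male) were
chosen once as plausible survey-shaped values and are not tuned.

**Purchasing diary.** One synthetic week of transactions per drinker, one
transaction per consumed category, with ethanol volume share × weekly
units (volume conservation is exact and tested), a log-normal usual price
per category (off-trade low tier around 36–55 p/unit, on-trade roughly
2.6× dearer, high tiers 1.7× their low tier), and Beta-distributed
discounts affecting 30% of off-trade and 5% of on-trade volume. A 14-day
diary, outlet detail, and zero-purchase imputation are not emulated.

**Price calibration.** Because diary prices understate true sales prices,
the sold-price distribution is adjusted so its volume-weighted CDF matches
target shares at ten calibration price points: the weighted empirical
quantile at each target share is mapped to the calibration price, with
linear interpolation between knots (anchored at zero). Above the last
knot prices are unchanged, clamped up to the last calibration price only
where needed to keep the map monotone — the tail behaviour is otherwise
unconstrained by the method's description, and we prefer an order-preserving
map to a literal-but-reordering one.

Consequently, passing tests demonstrate the *mechanics* — conservation
laws, calibration round trips, monotone responses — on survey-shaped data;
they do not validate magnitudes against any real population, which would
require the confidential survey and market-research inputs.

## Elasticities and the demand response

The elasticity matrices are inputs, not estimates: the econometric system
that produces them is out of scope. The shipped defaults are synthetic and
deterministic: own-price elasticities between −0.45 and −0.88 (on-trade,
RTD and high-tier categories more elastic), tier-substitution cross terms
of +0.12, smaller cross-beverage terms, and the hazardous+harmful segment
scaled 1.08× against 0.92× for moderate drinkers. The scale was chosen so
the population-average own-price response sits near −0.5, the magnitude
published meta-analyses report for alcohol overall.

The response is first order in the percent domain,
$\Delta c = E\,\Delta p$, matching the mean-percent-change pipeline; a
multiplicative variant $\prod_j (1+\Delta p_j/100)^{\varepsilon_{ij}}$ is
available behind a flag for sensitivity, since the functional form is not
pinned down. Segment-level changes are applied uniformly to every
individual in the segment; a `coverage` argument supports partial-uptake
interventions. Segment membership is fixed at the *baseline* drinking
level: an individual who crosses a classification boundary post-policy
keeps their baseline segment matrix (the alternative creates a circular
dependence between classification and response).

The peak update preserves each individual's residual around the linear
fit: `peak' = max(0, peak + slope × Δmean)`. The underlying two-part
(probability and scale) formulation of binge behaviour is simplified to
the scale component; this is a known limitation.

Elasticity-coefficient uncertainty is propagated by multivariate-normal
sampling through a triangular (Cholesky) factor of the coefficient
covariance, with an eigenvalue-based PSD factor as fallback for degenerate
(e.g. zero) covariances.

## Risk functions and calibration

Four harm classes are modelled: chronic/acute × wholly/partially
attributable. Chronic harms use mean weekly units; acute harms use
peak-day units.

* **Chronic, partially attributable** (e.g. oesophageal cancer): tabulated
  published relative-risk curves, interpolated linearly and held constant
  beyond the tabulated range. Curves are config data, not code.
* **All other classes**: two-part linear functions — RR = 1 up to a
  threshold, rising linearly. Thresholds: 4/3 units peak-day (male/female)
  for acute harms; 3/2 units per day × 7 on the weekly basis for chronic
  wholly attributable harms; 7.1/5 units per day × 7 for unemployment.

Slope calibration exploits a closed form. For a two-part function the
implied attributable fraction (excess-over-total,
$\mathrm{AAF} = \sum w(RR-1) / \sum w\,RR$) is $sE/(W+sE)$ with
$E=\sum_i w_i \max(c_i - T, 0)$ and $W = \sum_i w_i$: strictly increasing
in the slope $s$ whenever mass exists above the threshold, with unique
exact root $s = \mathrm{AAF}\,W / ((1-\mathrm{AAF})\,E)$. We use the root
directly rather than iterative search; the tests nonetheless verify it
against an independent 10,000-point grid-search oracle. The
excess-over-total AAF form was chosen over alternatives because it makes
the zero-consumption identity exact — the PIF of a counterfactual that
sets all consumption to zero *equals* the implied AAF, for any function
and population — which is the model's own cross-check and holds to 1e-9
in the acceptance suite. Wholly attributable harms are calibrated in
absolute terms instead: the slope equates expected annual incidents
$s\,E$ with the observed volume.

Crime uses peak-basis two-part functions per sex for two age groups
(under 16, 16–25); older bands reuse the 16–25 functions, mirroring the
estimation coverage of the source data — a documented limitation. Offence
changes are apportioned to offender subgroups by weights that split the
youth bands with equal per-year probabilities and decline linearly with
age above 35; apportionment conserves category totals exactly.
Under-reporting multipliers scale baseline volumes before the PIF is
applied (the two operations commute; the order is fixed for clarity).

Unemployment applies only to harmful drinkers (its threshold *is* the
harmful boundary, so RR = 1 elsewhere by construction). The calibration
target — problem drinkers' probability of being in work reduced by 6.9% —
is not given an operational formula in its source; we define the implied
reduction as the implied AAF of the function over the harmful working-age
population, which makes the calibration round trip exact. The female
target is adjusted by the female/male participation-rate ratio. Absence
uses peak-basis functions with the acute thresholds (no dedicated absence
threshold exists; this default is flagged as a choice) and a configured
causal attributable fraction.

## Projection, lag and discounting

Harm is projected as Future A (policy) versus Future B (do-nothing).
Future B is steady state: baseline rates every year (a trend hook exists
but defaults off, since differencing two futures cancels common trends).
Chronic risk reductions phase in linearly over ten years — 1/10 of full
effect in year 1, 2/10 in year 2, and so on; acute harms take full effect
from year 1. With constant rates the cumulative ten-year chronic effect is
exactly 5.5/10 of the no-lag effect (arithmetic series), a closed-form
identity the tests verify.

Each sex × age band cohort is projected at its band-midpoint age, ageing
one year per model year. Within-year mortality is additive across
conditions plus life-table other-cause mortality, capped at 1 (no explicit
competing-risk adjustment — a stated simplification). Each averted death
accrues the discounted quality-adjusted life expectancy remaining at that
age from the life table (QALYs for averted deaths are spread over
remaining life-years, not lumped at the death year; the convention is
ours and is documented rather than prescribed). Hospitalisations proxy
morbidity prevalence: prevalent cases accrue per-case utility decrements
and treatment costs. Discounting is end of year: QALYs at 3.5%/year,
costs at 1.5%/year. Crime, absence and unemployment changes are per-annum
steady-state quantities accrued over the horizon with the same channel
discounting and no lag.

The default life table is synthetic (Gompertz-type mortality with male
excess; utilities declining from 0.95 after age 20), as are baseline harm
rates, crime volumes, salaries and absence days. One configured value is
anchored to a published figure: the road-traffic attributable fraction of
0.37 for men aged 25–34, which the calibration reproduces as a
zero-consumption PIF to 1e-9.

## Valuation

Sales decompose exactly into retailer income, duty and VAT: retail prices
are VAT-inclusive, so VAT = sales × r/(1+r) with r = 17.5% (the rate is
given; the base is our reading of standard VAT practice, and it is
config-overridable); duty is per-unit by beverage type; the retailer takes
the remainder, and the identity re-sums exactly on every run. A health
QALY is valued at £50,000 and a crime-victim QALY at £81,000; workplace
changes are valued at average salaries (absence at salary/220 per day).
All amounts are at the base-year price level. Signed "change (A − B)"
reporting is used throughout; reductions in harm appear as negative
volumes and positive monetised benefits. Policy implementation costs,
consumer surplus, and supply-chain knock-ons are excluded by scope.

## Numerical and degenerate-input conventions

* Consumption floors at zero under extreme negative changes; shares are
  re-normalised only when the new mean is positive.
* Categories with zero volume report a 0% price change (not NaN).
* A calibration target of 0 yields slope 0; a positive target with no
  mass above threshold is reported infeasible, never silently truncated.
* `PIF(x, x)` is exactly 0 (same sums in numerator and denominator).
* Policies compose sequentially in file order; minimum price ∘ percent
  rise is not commutative, so the order is part of the policy definition.
* Discount-pattern band matrices (10×10 usual × sold price bands) are
  supported by expansion to synthetic transactions at band midpoints.

## Problem sizes

The test suite runs on populations of 360–1,440 synthetic individuals per
check, chosen to keep statistical assertions stable at fixed seeds; the
end-to-end comparison exercises all 18 fixture policies on about 20,000
individuals (1,112 per cell) and completes in well under a minute on one
CPU. The shipped fixture set includes three what-if scenarios whose
consumption-change percentages are inputs taken from the policy library
as printed (including a positive sign on the outlet-density scenario that
is inconsistent in direction with its label; it is reproduced as shipped).

## Known limitations

Survey under-reporting (~40%) is not corrected; market/supply-side
responses to price policies are ignored; harms to others and
consumption–purchase mismatch within households are out of scope; a
single lag structure covers all chronic conditions; joint mean-and-peak
risk is not modelled; and all default magnitudes are synthetic, so only
relative and structural conclusions transfer to real settings.
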