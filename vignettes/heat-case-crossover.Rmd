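---
title: "Case-crossover analysis of heat exposure and traumatic injury with heatcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-crossover analysis of heat exposure and traumatic injury with heatcc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatcc)
```

## The design and the model

`heatcc` implements a time-stratified case-crossover analysis of ambient heat
and acute occupational injury. Each injured worker serves as their own
control: the exposure on the injury day is compared with the exposure on
*referent days* — every other day in the injury's calendar month that falls
on the same weekday, at the same location. Because the comparison is within
person and within month, all time-invariant characteristics of the worker
and workplace (and slow seasonal trends, up to the month scale) are
controlled by design, and no denominator (population-at-risk) data are
needed. Choosing referents symmetrically from the full month stratum, both
before and after the event, avoids the overlap bias that afflicts
unidirectional referent windows.

A stratum is one injury day plus its three or four surviving referent days.
With exactly one case per stratum, the exact conditional likelihood of a
logistic model reduces to a softmax over the stratum's days:

$$\ell(\beta) \;=\; \sum_s \Big[\, x_{\text{case},s}^\top \beta \;-\;
\log \textstyle\sum_{j \in s} \exp\!\big(x_j^\top \beta\big) \Big],$$

so no tie-breaking machinery (Breslow or Efron approximations) is needed,
and "exact" estimation costs no more than a multinomial logit.
`clogit_newton()` maximises this likelihood by Newton–Raphson from
$\beta = 0$ with step-halving, using the analytic score and observed
information; standard errors come from the inverse observed information at
the optimum and confidence intervals are Wald intervals on the log-odds
scale. `fit_clogit()` wraps this behind the three exposure codings used in
the analyses: categorical (indicators for the `25-29`, `30-33` and `>=34`
Humidex categories, reference `<25`), dichotomous (`>=25` versus `<25`) and
continuous (per Humidex unit). Adjustment for duration of employment adds
the covariate in days, untransformed, so its odds ratio reads *per
additional day employed*.

## Exposure: Humidex on a gridded daily surface

Exposure is the daily maximum Humidex, an apparent-temperature index that
combines air temperature with dew-point-derived vapour pressure:

$$H = T + 0.5555\,(e - 10), \qquad
e = 6.11 \exp\!\Big[5417.753\Big(\tfrac{1}{273.16} -
\tfrac{1}{T_{d}\,[\mathrm{K}]}\Big)\Big]\ \text{hPa},$$

the standard Environment Canada (Masterton–Richardson) form; the constants
are pinned in one internal table. When the weather source supplies relative
humidity instead of dew point, `dewpoint_from_rh()` inverts the Magnus
approximation ($a = 17.625$, $b = 243.04\,^\circ$C) — the conversion is a
package choice, since gridded products differ in which humidity variable
they carry. Humidex values are classified into the a-priori occupational
heat-response categories `<25`, `25-29`, `30-33`, `>=34`; because the index
is continuous, the printed integer labels are realised as half-open
intervals $[25,30)$, $[30,34)$, $[34,\infty)$ so that every real value is
classified exactly once.

The exposure surface lives on a regular 1/16-degree latitude–longitude
centroid grid (`exposure_grid`). Injury locations are joined to the grid by
nearest centroid, with Euclidean distance computed in raw degree
coordinates; at mid-latitudes a 1/16-degree cell is only about 7.0 by
4.5 km, so degree-space and projected-space neighbours almost always agree,
and exact ties resolve deterministically to the lexicographically smallest
(lat, lon) centroid. A cell-day the grid does not cover is an error naming
the key (for the injury day the claim goes to a rejects report; a referent
day is dropped from its stratum with a logged count) — never a silent `NA`.

## Stratum construction and employment exclusions

`build_strata()` assembles, for each claim, the index day and its referent
days, each annotated with the cell's daily maximum Humidex, dry-air
temperature, exposure category, and the duration-of-employment covariate:
the self-reported duration at injury shifted by the signed day gap between
the referent and injury dates. Referent days are removed when the worker
could not have been at work: all of them when the claimant was not employed
by the employer of injury in the quarter of and the quarter before injury,
and any day preceding the reported employment start date (equivalently, any
day whose duration covariate would be negative). Referent days *after* the
injury are retained: with time-stratified selection and a rare outcome, the
bias from post-event referents is smaller than the overlap bias that
excluding them would introduce. Strata left with no referent are dropped
and counted; they carry no likelihood information.

## Secondary and sensitivity analyses

`run_secondary()` refits with the dichotomous and continuous codings,
restricts to May–September (the season when occupational heat rules apply),
and stratifies by cherry-harvest duties in June–July and apple-harvest
duties in August–October. Panels subset *claims* before stratum
construction, so referent days always come from the injury's own month and
strata are wholly in-window by construction.

`run_sensitivity_suite()` repeats the adjusted primary fit under each of a
set of exclusion rules (weekend injuries; public holidays, computed
algorithmically for the US federal calendar with observed-date shifts;
zip/city-resolution locations; healthcare-imputed locations; geocoding
accuracy below 0.80; injury times outside 5:30–16:30 or 5:30–12:30; more
than seven time-loss days; more than one day to first healthcare; deaths),
plus an exposure swap that replaces Humidex with maximum dry air
temperature while keeping the same category cutpoints. Each rule is a pure
predicate on claim fields, so rules compose order-independently. Missing
injury times are excluded by the time-window rules (the conservative
choice, logged); per-rule failures are isolated so the suite always
completes.

## The synthetic study generator

Because the motivating data (workers' compensation claims) are restricted,
the package ships a generator that reproduces the statistical structure the
analysis assumes, making every stage testable without any download.

* **Exposure field** (`simulate_exposure_field`): on the 1/16-degree grid,
  $t_{\max}(\text{cell}, d) = \mu + A \sin\!\big(2\pi (d - \phi)/365\big)
  + g\,(\text{lat} - \text{lat}_0) + \varepsilon$, with truncated-normal
  relative humidity, pushed through the same dew-point and Humidex code the
  pipeline uses. Defaults describe a semi-arid mid-latitude growing region:
  annual mean 16 °C, seasonal amplitude 13 °C peaking at day 205, gradient
  −1.5 °C per degree latitude, daily noise SD 3.25 °C, RH 45 ± 8 %.
* **Cohort** (`simulate_claims`): 60,000 workers with one seasonal
  employment spell each (hiring peaking in mid-May, geometric spell length
  with mean 160 days), injured on each employed day with odds
  $\text{baseline} \times \mathrm{OR}(\text{category}) \times
  \mathrm{OR}_{\text{dur}}^{\text{days employed}}$; the first injury ends
  the worker's at-risk time and becomes a claim. Default true effects are
  1.14 / 1.15 / 1.10 for the warm categories and 0.994 per day of
  employment, with a baseline of 0.0026 daily odds — chosen to land the
  cohort at the scale of the motivating study (about 12,000 claims over
  2000–2012) while keeping expected events below 0.2 per worker-month, the
  rare-event regime the design assumes (`sim_config()` enforces this bound).
* **Conditional simulator** (`simulate_strata`): draws strata directly —
  month, weekday and latitude are sampled (month and weekday weights follow
  the summer- and work-week-heavy injury profile of outdoor agriculture),
  the stratum's days get exposures from the field law, and the case day is
  selected by the exact softmax of the true log-odds. Conditioning each
  injury on its month-by-weekday stratum makes this *precisely* the
  data-generating process the estimator assumes, which is why the coverage,
  bias and type-I-error studies use it: any miscalibration they detect is
  attributable to the estimator, not to cohort-level artefacts.

The daily noise SD was calibrated (once, by a small Monte-Carlo sweep) so
that the mean of within-stratum standard deviations of daily maximum
Humidex is about 4.8 under the default configuration — the dispersion
observed in the motivating study, and the quantity that controls how much
information a stratum carries.

What the generator does *not* emulate: real spatial correlation of weather
(noise is independent across cell-days), multi-year employment histories
(every worker is a fresh seasonal hire, so the start-date exclusion removes
a larger share of referent days than in a workforce with long-tenured
workers), recurrent injuries, and reporting errors in duration or location.
Passing tests therefore demonstrate correctness of the machinery under the
model's assumptions, not robustness to violations of them.

### A deliberate discrepancy worth knowing about

The cohort generator ends a worker's at-risk time at the first injury while
the analysis, by design, keeps post-injury referent days. At the default
event rate (~7 % of at-risk months) this produces a small attenuation of
cohort-level estimates — most visibly in the duration-of-employment odds
ratio (fitted around 0.985–0.990 against a generating value of 0.994) and a
slight negative pull on the continuous-coding slope — exactly the
post-event-referent bias the case-crossover literature describes as
proportional to the outcome's unconditional probability. The package
quantifies this in its recovery tests rather than assuming it away: the
conditional simulator, which has no such selection, shows the estimator
itself is unbiased (mean log-OR bias below 0.01) with nominal 95 % coverage
and 5 % type-I error.

## Numerical choices

* Newton–Raphson from $\beta = 0$; convergence when the score's max-norm
  falls below $10^{-8}$; at most 100 iterations; step-halving accepts the
  first step that does not decrease the log-likelihood beyond its numerical
  resolution, and once the score is below $10^{-3}$ the undamped Newton
  step is taken (in the quadratic regime the expected gain can drop below
  floating-point resolution of a log-likelihood of magnitude $10^4$).
* Covariates are centred within stratum before evaluation — the conditional
  likelihood is exactly invariant to stratum-constant shifts, and centring
  prevents catastrophic cancellation in the score when a covariate such as
  employment duration has large between-stratum magnitude.
* Separation is detected (any $|\beta| > 15$ during iteration) and reported
  as an error naming the coefficient, never regularised silently. Covariates
  with no within-stratum variation anywhere are inestimable and reported as
  `NA`; strata whose rows are identical are removed from the likelihood
  (their contribution is constant) but kept in all day counts.
* Confidence intervals are Wald on the log-odds scale. Nothing in the
  published tables this mirrors suggests profile intervals, and at these
  stratum counts the two are indistinguishable.

## Problem sizes used in the test suite

The packaged verification runs at sizes chosen to make Monte-Carlo error
small relative to the properties being checked while keeping a full run in
the minutes range: the coverage study uses 1,000 replicates of 12,000
strata (coverage must land in 93–97 % per coefficient; 1,000 replicates put
the binomial noise near 0.7 %), the null calibration uses 2,000 replicates
of 1,500 strata (rejection rate 3–7 % per category), and the calendar check
of referent selection is exhaustive over 2000–2012. The acceptance script
re-runs the full synthetic study at its default scale and reports the
fitted odds ratios, dispersion, coverage and type-I error it computes.

## Known limitations

* Exposure lags are out of scope (only same-day exposure is modelled), as
  is generating the meteorological surface itself — the grid is an input.
* The quarter-employment exclusion is consumed as a precomputed flag;
  deriving it from wage records is outside the package.
* Geocoding and injury-location assignment happen upstream; the package
  takes coordinates, a location-basis label and an accuracy score as given.
* The holiday calendar is the algorithmic US federal set with observed-date
  shifts — an approximation of vendor holiday tables, adequate for
  day-level exclusion.
* Wald intervals can misbehave in panels with very few discordant strata
  (wide or `NA` category terms in small duty-stratified fits); the fitter
  reports rather than papers over these cases.
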