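---
title: "Methods: cohort life tables, jackknife inference and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort life tables, jackknife inference and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

`cohortlife` implements the female-based cohort life table for daily-census
rearing data. A cohort starts as `n_initial_eggs` eggs of one treatment;
every individual is followed daily until death, recording stage durations
(egg and five nymphal instars), fate (`adult`, `died_immature`, `lost`),
sex at emergence, adult longevity for females, and each female's daily egg
count. The analysis assumes:

- **Whole-day resolution.** Observations are a daily census, so all
  durations and ages are integer days. A female dying on day `d` counts as
  alive at ages `< d` and dead from `d` on (death-day exclusive). This
  convention shifts the mean generation time by at most half a day relative
  to the opposite choice; it is fixed, stated, and used everywhere.
- **Females drive the demography.** Survival `l_x = SURV * NSF_x / NF`
  tracks the eventual adult females: before the first emergence every
  eventual female is counted alive (they were alive as immatures), so
  `l_x = SURV` over the immature period. Males enter only through `SURV`
  and the sex ratio `SR`.
- **Individuals lost to handling are uninformative.** `apply_exclusions()`
  removes `lost` records and shrinks the initial-egg denominator by the
  same amount; immature deaths are *kept* and count against `SURV`. This
  mirrors the usual census bookkeeping in which the post-exclusion `n` only
  drops where real deaths occurred.

### The fecundity denominator

The mean eggs per female at age `x`, `NEGG_x`, is taken per **living**
female (`NSF_x`), not per initial female. This choice makes the algebraic
conservation identity

    sum_x l_x m_x = SURV * SR * (total eggs) / NF

hold exactly, which in turn reproduces the familiar identity
`R0 = SURV * SR * (mean total fecundity per female)` that published
parameter tables obey. The identity is asserted to 1e-12 in the test suite,
and it is the reason `R0` from this package can be checked against a
treatment's printed survival, sex ratio and fecundity without any raw data.

### Age origin

The default age origin is the egg (day 0 = oviposition of the focal egg),
the whole-life-cycle framing used for published survival/fecundity curves;
`adult_emergence` is available as an option. `R0` is invariant to the
origin; `T` shifts by the immature duration (exactly so when all females
share it). The fecundity CSV stores `age_day` as days since adult emergence
(1-based) — that is how daily records are taken at the bench — and the
schedule builder converts to the requested origin using each female's own
immature duration.

## The Euler–Lotka solver

`r_m` solves `sum_x exp(-r x) l_x m_x = 1`. With any reproduction at an age
`x > 0` the left side is strictly decreasing in `r`, so the root is unique.
The solver brackets it on `[-2, 2]` per day (a biologically absurd range for
a daily rate, hence safe), doubles the bracket geometrically in the rare
case the sign does not change, refines with `uniroot` at machine tolerance,
and polishes by bisection until the residual is at most `tol` (default
1e-10). Schedules are finite by construction — truncated at the last age
with a living female — so the "infinite" sums are exact finite sums and no
tail correction exists. Degenerate inputs are explicit errors: `R0 = 0`
(no reproduction) and all-reproduction-at-age-0 have no defined rate.

A note on the classical shortcut `r_m ≈ ln(R0)/T`: it is accurate only when
growth is slow or reproduction is concentrated. The suite asserts the 15%
relative-error bound on the low- and moderate-growth presets; for the
high-fecundity preset the approximation falls outside that band, which is a
property of the approximation (the spread of reproduction matters more the
faster the population grows), not of the solver.

## Jackknife inference and the Tukey comparison

For each treatment the leave-one-out jackknife reruns the entire pipeline —
census, schedules, all four parameters — per omitted unit, then forms
pseudo-values `pv_i = n*theta - (n-1)*theta_(-i)`, reporting their mean and
`se = sqrt(sum((pv - mean)^2)/(n(n-1)))`. Two deletion units are offered:

- `individual` (default): every post-exclusion record, immature deaths
  included. Rationale: `SURV` is part of `l_x`, so its sampling variability
  should propagate into the SEs; deleting only females would hold `SURV`
  fixed.
- `female`: the stricter female-only deletion of the classical R
  implementation of this analysis.

`lambda` is jackknifed from `lambda` replicates directly rather than as
`exp` of the `r_m` pseudo-values, because published tables report separate
SEs per parameter; the two routes differ only at second order. If a
deletion removes the last ovipositing female, that replicate has `R0 = 0`:
the `R0` pseudo-value is formed with `theta = 0`, while `T`/`r_m`/`lambda`
pseudo-values for that replicate are flagged missing and those estimates
carry a reduced `n` and a warning.

Treatments are compared per parameter by a one-way fixed-effects analysis
of the pseudo-values: pooled error variance with `df = sum(n_i - 1)`,
Tukey–Kramer studentized-range p-values (valid under unequal `n`), and a
compact letter display (insert-and-absorb; the highest mean takes "a").
With two groups this reduces exactly to the pooled two-sample t-test, which
the suite asserts.

## Stage-level tests

Heavily tied integer day counts (instar durations, oviposition and
postoviposition periods) are compared with the tie-corrected Kruskal–Wallis
test and DSCF pairwise comparisons: each pair re-ranked on its own,
`sqrt(2)|z|` referred to the studentized range with `k` groups and infinite
df — the asymptotic procedure of SAS `PROC NPAR1WAY`. No exact small-sample
DSCF tables are used; with tiny groups (n = 3 per group) the asymptotic
decision agrees with the exact permutation decision, which the suite checks
by full enumeration. Preoviposition period, adult longevity and total
fecundity use one-way ANOVA with Tukey–Kramer letters. Which variable gets
which test is fixed per variable, matching the test statistics convention
for this kind of data, rather than decided by a normality pre-test. All
letter displays use α = 0.05.

Two bookkeeping rules matter for the `n` columns: females that never laid
are excluded from the three period variables (no egg dates exist) but kept,
as zeros, in mean total fecundity and in longevity; per-stage duration means
cover the individuals that completed the stage.

## The synthetic generator and what a green test establishes

`simulate_cohort()` emulates the experiment the analysis assumes: integer
stage durations (shifted Poisson, minimum 1 day, truncated at mean + 6 SD so
supports are finite), per-stage survival, Bernoulli sex at emergence,
preoviposition/oviposition/postoviposition phases, and negative-binomial
daily egg counts (default dispersion 2.0) during the oviposition window.
Overdispersed counts, and an explicit probability of never ovipositing, are
included because real treatment tables show both (large fecundity SEs;
fewer layers than females). Every individual draws from its own RNG
substream derived from the root seed, so deleting an individual does not
perturb the others — the property that makes simulated jackknife
experiments clean.

`analytic_expectation()` computes the *exact* expected schedules implied by
a configuration — by convolving the finite duration distributions, not by
simulation — and the parameters those schedules imply. Because simulation
and oracle share the same truncated distribution tables, a deterministic
configuration makes them agree exactly, and stochastic configurations admit
law-of-large-numbers and coverage tests against a known truth.

The three diet presets (`paper_calibrated_configs()`) match their generative
means to published per-stage durations, reproductive-phase lengths and
fecundities, with egg-to-adult survival 0.95/0.95/1.0. Sex ratios are
back-derived from the `R0 = SURV*SR*fecundity` identity (0.5 and 11/19 for
the two productive diets); the aphid-only sex ratio is not recoverable
exactly from printed values and is set to 0.42. Daily egg means are chosen
so that `(1 - p_never) * mu * E(oviposition days)` reproduces the printed
mean fecundity per female.

What the generator does **not** emulate: environmental covariates
(temperature, humidity), density dependence, day-to-day correlation within
a female's laying record, age-dependent laying intensity within the window,
or gaps (zero days) inside the oviposition period. Consequently a green
parameter-recovery or coverage test establishes that the *pipeline* is
correct and calibrated for data with this structure — it does not certify
the generator as a model of any particular species, and quantities driven
by within-window timing (notably `T`) sit slightly away from published
values even at the calibrated means.

## Numerical choices

- Schedules are truncated at the last age with a living female; no
  smoothing or interpolation anywhere.
- `l_x` is computed as `SURV * (NSF/NF)` — the grouping keeps
  `l_x == SURV` bit-exact while all females are alive, which the
  step-function tests assert with `==`.
- Kruskal–Wallis uses the standard tie correction `1 - sum(t^3 - t)/(N^3 - N)`;
  an all-tied sample returns `H = 0`, `p = 1` rather than 0/0.
- Zero pooled variance in pairwise comparisons: equal means give `q = 0`
  (not significant), different means give `q = Inf` (significant), avoiding
  NaN decisions on degenerate fixtures.
- Reported numbers are kept at full precision in every object and file;
  rounding (durations 1 d.p., parameters 3 d.p., SEs one digit more) is
  applied only by `render_tables()`.

## Known limitations

- Female-based only; no two-sex or age-stage structured formulation.
- Jackknife confidence statements use the normal approximation on
  pseudo-values; with n = 20 cohorts the suite's calibration experiment
  shows mild conservatism rather than exact 95% coverage.
- DSCF is asymptotic; for very small groups it is validated against exact
  permutation decisions, not exact p-values.
- The preset calibration targets printed means, not the unpublished raw
  data; preset-based checks are qualitative (orderings, letters) except for
  the `R0` identity, which is exact by construction.
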