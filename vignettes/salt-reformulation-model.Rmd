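---
title: "Modelling the health impact of category-specific salt reformulation targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health impact of category-specific salt reformulation targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltimpact)
```

## The problem

Voluntary salt reformulation programmes set category-specific targets for
the salt content of processed foods: per-100 g targets for grocery
categories and per-serving targets for food eaten out of the home.
`saltimpact` estimates what full compliance with such targets would do to
population salt intake, systolic blood pressure (SBP), ischemic heart
disease (IHD) and ischemic stroke burden, quality-adjusted life years
(QALYs) and healthcare costs. The model has two stages:

1. **A static diet-survey microsimulation.** Per-person daily salt intake
   is computed from food-diary records (`grams/day x salt per 100 g / 100`),
   recomputed with every category's salt content replaced by its target,
   corrected for diary under-reporting, and summarised with survey weights.
2. **A proportional multistate lifetable.** The per-sex salt change is
   converted to an SBP shift, the shift to population impact fractions
   (PIFs) on disease incidence, and the PIFs are propagated through closed
   age/sex cohorts to the terminal age.

## Stage one: the diet scenario

Baseline intake sums a person's diary records that match a target
category; records flagged homemade, and records matching no category, are
excluded (a conservative choice — unmatched foods can contribute no
modelled benefit). Substitution is unconditional: a food already at or
below its target is set to the target, mirroring how a compliance scenario
is defined. Out-of-home records are treated as exactly one serving, so
their scenario salt equals the per-serving target irrespective of reported
grams; `apply_targets(servings_cap =)` offers an optional cap-based
multi-serving rule, but the one-record-one-serving assumption is the
default.

Diet diaries under-report intake. The correction factor per calibration
stratum (ages 19–34, 35–49, 50–64 by sex) is the ratio of a
urinary-sodium-based reference mean to the diary-estimated mean, and both
baseline and scenario intakes are multiplied by it. Two consequences are
built in and tested: relative change is exactly invariant to the factor,
and switching the adjustment off rescales absolute changes by the inverse
factor. Persons outside the calibrated age range take the nearest
stratum's factor — a minimal extrapolation. Confidence intervals use a
survey-weighted percentile bootstrap over persons (weights carried with
each resampled person); the interval method is a design choice, made
because it respects both the weighting and the right skew of intake.

## Stage two: risk and lifetable

**Salt to SBP.** Linear: 5.80 mmHg (95% CI 2.45–9.15) per 5.88 g/d salt
(100 mmol sodium). So a 1.34 g/d male reduction gives
`r round(delta_sbp(1.34), 2)` mmHg.

**SBP to incidence.** The population SBP distribution per age/sex is
normal; it is discretized into 1 mmHg bins (the PIF formula is
categorical, so discretization makes the computation exact to the
formula; bins of 2, 1, 0.5 and 0.25 mmHg give PIFs agreeing to ~1e-4).
Relative risk is flat at 1 up to the theoretical-minimum-risk level
(TMREL, 115 mmHg) and log-linear in SBP above it, with age-band slopes
supplied as data. A log-linear-above-threshold curve is the standard
comparative-risk-assessment reduction of a "rising, convex" risk curve;
since the exact curvature is not identified by published summaries, the
slope table is data, not code. The PIF is

$$\mathrm{PIF} = \frac{\sum_i p_i RR_i - \sum_i p'_i RR_i}{\sum_i p_i RR_i},$$

and scenario incidence is $I' = I(1 - \mathrm{PIF})$.

**Timing.** The salt change ramps linearly over 4 years; incidence
responds to the exposure of 5 years earlier, so the first incidence
change appears in simulation year 6 and the full effect from year 9.
Incidence and case-fatality trends are the annualised log-linear change
fitted to the ten pre-baseline years of rate indices, applied for
simulation years 1–10 and held constant thereafter. Baseline population
SBP is assumed not to drift otherwise.

**The lifetable.** Annual cycles, single-year ages, closed cohorts from
age 18 to a terminal age of 110, no half-cycle correction — the simplest
convention that makes results bit-for-bit reproducible. Rates become
probabilities as $q = 1 - e^{-\text{rate}}$. Each disease is a 3-state
process (healthy, diseased, dead-from-disease; remission zero). Within a
cycle, disease case fatality and other-cause mortality act as independent
exponentials, so hazards add. Scenario all-cause mortality is the
baseline rate plus the change in prevalence-weighted disease mortality —
the "proportional" coupling that lets small disease-specific changes feed
back into total survival. QALYs weight person-years by the age/sex
baseline utility minus *additive* decrements for each prevalent disease
(additivity across coexisting IHD and stroke is a choice; a
multiplicative rule differs only at second order at these prevalences),
clamped to [0, 1]. Costs are annual unit costs per prevalent case. QALYs
and costs are discounted from year 0 at 3.5% (1.5% and 0% as
comparators); case and death counts over the 20- and 30-year horizons are
reported undiscounted, since burden tables conventionally report counts
while discounting applies to valuation streams.

## Uncertainty

Monte Carlo draws are independent across parameters (no published
correlation structure; a known limitation). Families follow each
parameter's support and interval shape: the salt–SBP slope's published
interval is arithmetic-symmetric (5.80 ± 3.35), so it is drawn from a
normal truncated at zero — a CI-matched lognormal cannot reproduce both
published bounds; relative-risk multipliers are lognormal; utilities and
decrements beta; costs gamma; the per-sex intervention effect is normal
truncated at zero, with its interval taken from the diet-stage bootstrap
and treated as an independent input parameter. Every family is a monotone
transform of its own column of standard normals, so a fixed master seed
gives an identical draw matrix, degenerate intervals collapse to point
masses, and widening one interval widens the corresponding output
interval under common random numbers. The point estimate is the
central-parameter run, not the Monte Carlo mean. Intervals are 2.5th /
97.5th percentiles; 10,000 iterations suit a production run, and reduced
counts (the package defaults to 500 in `run_config()`) give percentile
ends stable to a few percent.

## The synthetic-data generator

The generator exists so the full pipeline runs, and is testable, without
restricted survey microdata. Its defaults emulate the study conditions of
a UK-style adult survey: ~600 adults aged 18–80; 108 categories with 24
out-of-home; reported (uncorrected) mean intake calibrated to 5.2 g/d
with ~25% of intake from the out-of-home sector; a true under-reporting
factor of 1.16 (so corrected intake sits near 6 g/d); and a mean salt
excess over target of 0.23, which implies a ~18.5% intake reduction
under full compliance — the magnitude a programme of this ambition
produces. Consumption volumes are log-normal within category (the
within-person day-to-day variance is exposed as `consumption_sdlog`
because published summaries do not pin it down); salt content is
`target x (1 + excess)` with excess drawn from a normal truncated at
zero, so the intervention effect is nonnegative by construction and the
generator has a closed-form expected intake used by calibration tests.
Reference intakes are the survey means times the configured true factor,
making correction-factor recovery exactly testable.

Epidemiology is generated on single-year ages 0–110 with Gompertz-like
age slopes; prevalence is produced by forward-simulating the 3-state
process with the generated incidence and case fatality, and all-cause
mortality is other-cause plus cause-specific — so the inputs pass the
engine validator with zero adjustments, by construction.

What the generator does *not* emulate: real food nomenclature, survey
design effects beyond weights (clustering, strata), correlated
consumption across categories, secular SBP drift, and multimorbidity
interactions. Passing tests therefore demonstrate the correctness of the
pipeline's logic under the assumed statistical structure, not the
accuracy of any particular national estimate.

## Numerical choices and degenerate inputs

- Exposure bins: 1 mmHg default, grid covering ±6 SD of both baseline and
  shifted means, masses renormalised to sum to one.
- PIF with zero denominator, estimated stratum mean of zero, all-zero
  weights, negative record quantities: hard errors naming the offending
  coordinates.
- A negative PIF (worsened exposure) is allowed; scenario incidence is
  clamped to [0, 1] with a warning.
- Horizons beyond the terminal age are truncated with a warning; strata
  with no persons are dropped from reference intakes with a warning.
- Problem sizes in the test suite (cohort engine to terminal age 75,
  bootstrap at tens of replicates, Monte Carlo at tens of iterations,
  a 200,000-individual microsimulation oracle) were chosen so the whole
  suite completes in well under a minute of engine time while keeping
  every stochastic check's error scale well below its tolerance.

## Known limitations

Only IHD and ischemic stroke are modelled; salt is linked to further
diseases, so health benefits are understated. Parameter draws are
independent. Diseases are independent endpoints with average severity.
Unmatched and homemade foods contribute no benefit — conservative. The
one-record-one-serving rule can mis-scale out-of-home salt for unusually
large recorded portions.
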