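---
title: "Methods: cost decomposition, stay-ratio scaling and discount scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost decomposition, stay-ratio scaling and discount scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endocost)
```

`endocost` compares the per-procedure economics of robotic-assisted and
laparoscopic surgery for early-stage endometrial cancer. This vignette is
the package's account of the model itself: what is assumed, which
parameters matter, how the numerics are handled, and where a genuinely open
design choice was settled one way rather than another.

## The cost model and its assumptions

Each procedure's cost is an exact four-term sum: theatre minutes times a
per-minute rate, per-use consumables, a straight-line equipment
depreciation share, and admission days times a per-day rate. The
assumptions this encodes:

* **Facility time is billed linearly.** The theatre rate (default
  €14.65/min) bundles the room, the full surgical and anaesthetic team and
  intra-operative medication, so there is no fixed per-case theatre fee and
  no separate staff micro-costing. Theatre minutes are total occupation,
  including field preparation and docking — occupied time is billed whether
  or not cutting has started.
* **Consumables arrive pre-prorated.** Limited-use instruments (typically
  10–18 licensed uses) enter the record at unit price divided by licensed
  uses. `uses_discount_equivalent()` converts a proposed life extension to
  the equivalent per-use discount; the proration itself is an ingest-time
  concern, not a stored price list.
* **Equipment is amortized per procedure.** The purchase price (defaults:
  €140,000 tower, €2,000,000 robotic platform) is spread over a
  procedure-count horizon, 1000 by default (ten years at about one hundred
  procedures a year). The share is constant within an arm, which is why
  its SD prints as zero in any arm summary. Annual platform maintenance can
  be recorded on the `equipment_spec` but defaults to zero and never enters
  the per-procedure share.
* **Everything is pre-tax euros**, with no inflation adjustment across the
  2022–2024 window the default parameters describe, and staff training is
  excluded (the reference rates describe surgeons past their learning
  curve).

All arithmetic is kept at full floating precision; euros are rounded
(half-up) only when a report is rendered with `render_euros()`. This
reproduces printed-style tables without accumulating rounding error, and it
explains the occasional ±€1–3 difference between a sum of rounded component
means and a rounded sum.

## The stay-ratio economy-of-scale model

The throughput ratio ρ = surgeries / admission days (equivalently 1/mean
stay) caps how many procedures a theatre plan can deliver while keeping the
mean stay at one day: `round(sessions × k × ρ)` per year, times the
amortization years. Capacity only re-amortizes the *equipment* term of the
cost; theatre, consumables and stay means are held fixed across `k` — the
model deliberately does not rescale theatre time when procedures are
stacked into a session, nor does it discount future cash flows.

Three numerical conventions matter here and are fixed:

* ρ is used at two-decimal precision (so 300 × 0.59 = 177, not 176.5 from
  the unrounded 0.588); the unrounded value is kept in the `raw` field.
* Annual capacity is rounded to the nearest whole procedure; the
  amortization-horizon capacity is exactly annual × years.
* The **stay component of the adjusted cost is the arm's observed mean stay
  cost**, not a forced one-day stay. Although the model is framed as
  "adjusted to a one-day stay", the one-day ideal acts through the
  *capacity cap*, not through the stay bill; only observed-stay arithmetic
  is internally consistent with the capacity-adjusted totals the model
  produces. A `stay_policy = "fixed_one_day"` flag provides the literal
  alternative for sensitivity analysis.
* The **percentage overrun uses the robotic cost as denominator**
  (overrun / robotic cost). This is the convention under which the three
  default models give 20.2%, 15.4% and 13.6%; dividing by the laparoscopic
  cost would give materially different figures, so the choice is documented
  and fixed rather than configurable.

The bundled parameters carry a reported robotic stay ratio of 0.88
alongside arm summaries whose mean stay (1.12 days) implies 1/1.12 ≈ 0.89.
Both are surfaced: reproduction mode uses the reported 0.88 via
`stay_ratio_override()`, cohort mode always recomputes the ratio from the
records, and neither is silently corrected to the other.

## Discount scenarios and break-even

Discounts apply multiplicatively to the platform purchase price (before
amortization) and to the consumables mean — never to theatre or stay costs,
which are not procurement levers. The discounted cost is affine and
strictly decreasing in each discount, so the break-even consumables
discount has a closed form; the test suite checks it against a grid search
at 10⁻⁴ resolution. The scenario grid compares each session-plan model's
robotic cost against that model's *own* laparoscopic reference (the
laparoscopic cost also falls slightly with `k` as its tower dilutes), not a
single flat reference line.

## Cohort statistics

The univariate routing is the conventional one for clinical cohort tables:

* **Normality gate**: one-sample Kolmogorov–Smirnov against a normal with
  the sample's own mean and SD. Estimating the parameters from the data
  makes this gate anti-conservative (it passes normality too readily); its
  alpha is therefore configurable (default 0.05). Both arms must pass for
  the t test to be used.
* **Student's t** uses pooled variance by default, with a Welch option.
* **"Wilcoxon"** is the two-sample rank-sum test: the arms are independent,
  so the signed-rank (paired) reading is not applicable. Small untied
  samples get the exact distribution; larger or tied samples the normal
  approximation with tie correction (the `stats::wilcox.test` defaults).
* **Categorical** variables use chi-square without continuity correction,
  switching to Fisher's exact test when any expected cell count is below
  five.
* **Perfect separation**: a predictor whose per-arm ranges do not overlap
  makes the arm-membership logistic regression non-identifiable, so such
  variables must be excluded from multivariate models.
  `detect_perfect_separation()` reports the midpoint threshold and is
  invariant to monotone transforms. The regression itself is routine
  maximum likelihood and is deliberately *not* part of this package's
  modelling surface; separation detection is the operative finding.

In two-arm cost data, separation is expected in the *direct-cost*
component (consumables + equipment share): the robotic equipment share and
consumables are categorically higher, so every robotic case exceeds every
laparoscopic one. Total cost, by contrast, carries the full theatre and
stay variance, whose overlap destroys separation — under the default
generator the total-cost separation rate across seeds is essentially zero
while the direct-cost rate is essentially one. The package's Monte-Carlo
separation check therefore runs on direct costs; `compare_cohort()` reports
the separation flag for both.

## The synthetic-cohort generator

The generator emulates two study arms for which only summary moments are
available (defaults: n = 75 laparoscopic / 78 robotic; duration 161 ± 60 vs
152 ± 43 min; stay 1.7 ± 1.02 vs 1.12 ± 0.46 days; consumables €1047 ± 314
vs €2057 ± 216; published complication rates and complexity-group splits).
Distributional shapes are modelling stand-ins, chosen once:

* Continuous variables are truncated normals (rejection sampling; lower
  bound 0, BMI ≥ 15 kg/m², age ≥ 18). The truncation-induced mean shift is
  below 0.5% at these parameter values and is accepted rather than
  re-centred (for the laparoscopic consumables it is ≈ €0.5).
* Stays are 1 + K days with K a non-negative count — every admission lasts
  at least one day, consistent with observed means barely above one. K is
  moment-matched: negative binomial with `mu = mean − 1`,
  `size = mu² / (sd² − mu)` in the overdispersed case (which covers both
  default arms), Poisson when the requested variance sits at or below the
  Poisson floor — that fallback is announced with a message, never silent —
  and degenerate all-ones for mean 1, SD 0.
* Variables are drawn independently; the source moments carry no covariance
  information. The arms are drawn sequentially (laparoscopic first) from
  the single seeded stream, so a cohort is fully reproducible from its
  seed; changing one arm's size shifts the other arm's draws, which is
  accepted.

What passing tests on this generator do and do not show: they demonstrate
that the pipeline recovers the moments and qualitative structure it was
fed (stay-ratio ≈ 0.59/0.89, Table-scale component means, direct-cost
separation, detectable stay difference), not that real cohorts follow
truncated normals or that real stay distributions are negative binomial.
Correlated real-world structure (longer theatre times with higher
consumables, complication-driven long stays) is absent by default; a
sensitivity analysis on that structure requires supplying your own cohort.

## Monte-Carlo checks as calibrated instruments

Stochastic checks in the test suite are stated in calibration form: a
sample mean at n = 10,000 lands within 2 SE of its target in about 95% of
draws, so the tests require that coverage rate across a dozen independent
seeded cohorts (e.g. at least 10 of 12 draws inside the band) rather than
staking the check on a single draw, for which a 1-in-20 miss is part of
correct behaviour. Detection-rate checks (stay-difference power across 200
seeds, direct-cost separation across 100) assert rates of at least 95%.
Problem sizes — 10,000 records per arm for moment recovery, 100–200 seeds
for rate checks, a 10⁻⁴ grid for the break-even cross-check — keep the
whole suite comfortably under a few minutes on one CPU while leaving the
bands statistically meaningful.

## Known limitations

* Cost-minimization assumes clinically equivalent outcomes; the package
  compares costs only and encodes no utility or survival weighting.
* Straight-line, procedure-count amortization; no discounting of future
  cash flows, no queueing or scheduling simulation behind the
  sessions-per-year cap.
* Single currency, pre-tax, no DRG/billing integration.
* The stay-ratio model treats the ratio as exogenous per arm; it does not
  model how stacking procedures might itself change stays or theatre
  times.
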