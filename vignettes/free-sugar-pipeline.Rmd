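---
title: "Stepwise sugar databases and free sugar intake analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise sugar databases and free sugar intake analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freesugar)
```

## The problem

National food composition tables rarely report sugar contents for every
food, and they never distinguish *added* sugar (sugars and syrups
introduced during processing or preparation) or *free* sugar (added sugar
plus the sugars naturally present in honey, syrups and fruit juices — the
WHO quantity) from the intrinsic sugar of whole foods and milk. Estimating
children's free sugar intake from weighed dietary records therefore
requires (i) imputing total sugar for foods whose saccharide contents are
unknown, (ii) deciding for every food how much of its sugar is added or
free, (iii) standard composition-table arithmetic over the records, and
(iv) an epidemiological analysis of who exceeds the WHO threshold of 10%
of energy from free sugar. This package implements all four stages as
testable components, plus a calibrated simulator that generates every
input, because individual-level survey data of this kind are not publicly
released.

## The stepwise composition engines

Total sugar is defined as the sum of the six mono- and disaccharides
(glucose, fructose, galactose, sucrose, lactose, maltose) per 100 g of
edible portion. For each food the engine tries an ordered list of rules
and the first applicable rule wins; the rule's position is stored as the
item's *step provenance*, so the finished database documents how every
value was obtained. The default 7-step total-sugar order is: saccharide
sum; available carbohydrate (carbohydrate minus dietary fiber) for items
flagged as essentially pure sugar; literature value; value of the linked
raw form rescaled by the dry-matter ratio
$(100 - w_\text{target})/(100 - w_\text{referred})$; value borrowed from a
nutritionally similar item; foreign-table saccharides (disaccharides
multiplied by 0.95 when the source expresses them as monosaccharide
equivalents); and finally 0 g for whatever remains. Added and free sugar
follow an 11-rule vocabulary on top of the assigned totals: definitional
zero for unprocessed foods, natural-free for juices/honey/syrups,
full assignment for pure added sugar, label values, recipe decomposition,
similar-item fractions, subtraction of an unsweetened counterpart,
subtraction of naturally occurring lactose, a configurable
fixed-proportion fallback (default 0.5 of total), foreign values, and a
residual zero.

Numerical choices worth stating:

* **Missing is not zero.** A missing saccharide makes the sum rule
  inapplicable and drives fallthrough; only the final residual rule
  converts absence into 0 g.
* **Capping.** Every estimate is capped at the item's available
  carbohydrate, and the chain $0 \le \text{added} \le \text{free} \le
  \text{total}$ is enforced by clamping (with a warning when clamping
  actually changes a value beyond $10^{-9}$): ratio adjustments must not
  produce physically impossible values.
* **Cross-references** are resolved recursively with memoisation; a
  dangling reference logs a warning and falls through to the next rule,
  whereas a genuine cycle is an error.
* **Configurable step ids.** The exact ordering of the added/free rules in
  published stepwise methods varies and is usually documented only in
  supplements, so `sugar_rules()` exposes the rule order; step identifiers
  are positions in that order.
* Values are kept at full floating precision; rounding (1 decimal for
  g/100 g, 2 decimals for odds ratios) happens only at render time.

## Intake estimation

Each record entry contributes `amount / 100 * content_per_100g` of every
nutrient. Per-child means are unweighted over the recorded days (two
weekdays with a nursery-school lunch and one weekend day); day weights
are available for sensitivity analyses but the primary estimate does not
weight, since the record design already fixes the weekday/weekend mix.
Percent of energy uses 4 kcal/g for carbohydrate, sugars and protein and
9 kcal/g for fat; the factor for sugars is configurable. Excessive intake
is `free sugar %E >= 10` with a closed lower bound. Food-group
contributions to free sugar are reported as the *mean of per-child
percentages*, not the ratio of group mean to overall mean — the two
disagree whenever intake and shares are correlated, and the per-child
average is the quantity that survey reports of this type tabulate.

## Covariate derivation

Screen time and outdoor playtime are week-weighted as
$5/7 \cdot \text{weekday} + 2/7 \cdot \text{weekend}$ and bucketed at the
conventional cutpoints (screen: 0.5 and 1 h/d; outdoor: 1 and 2 h/d);
sleep is nursery nap plus night sleep, cut at 10 h/d. All printed
"$\ge x$" boundaries are inclusive upward, uniformly. Adult weight status
uses WHO BMI boundaries 18.5 and 25 kg/m²; child weight status uses age-
and sex-specific BMI cutoffs mapped to those adult boundaries, supplied
as a lookup table. The published cutoff table is copyrighted, so the
package ships a clearly labelled synthetic stand-in
(`synthetic_child_bmi_cutoffs()`) with smooth, plausible values; real
analyses should substitute the published table. Household income is
equivalised by a configurable scale — square root of household size by
default, a standard choice when the source method is cited but not
printed — and cut at 2,380,000 and 3,340,000 yen/year. Occupation arrives
pre-coded with four classes; free-text coding is out of scope. Rows with
any missing covariate are dropped (complete-case analysis).

## Association analysis

Crude odds ratios come from category-wise 2×2 tables against each
variable's reference category: $\text{OR} = ad/bc$ with the Wald interval
$\exp(\ln \text{OR} \pm z \sqrt{1/a + 1/b + 1/c + 1/d})$, $z = 1.959964$.
Adjusted odds ratios come from one joint maximum-likelihood logistic fit
(IRLS via `glm`) with all covariates entered simultaneously under
reference-level indicator coding; Wald intervals use the observed
information. A zero-event cell makes the crude OR undefined and is
rendered as a dash rather than continuity-corrected, matching the
reporting convention of the motivating survey; a Haldane–Anscombe
correction is available behind a flag. Separation in the joint fit is
detected from diverging coefficients or exploding standard errors and the
affected categories are likewise reported undefined. The group-difference
tests in the intake table are pooled-variance two-sample t-tests by
default ("independent t-test" without qualification usually means the
pooled test in this literature); Welch is a flag. No multiple-testing
adjustment is applied, as none is conventional in this design.

## The synthetic-data generator

The generator emulates the study conditions rather than any particular
dataset:

* **Cohort design.** 332 children, 166 of each sex, 87/86/85/74 aged
  3/4/5/6 — drawn as exact counts at the default size. All other
  covariates are drawn independently from the published category counts
  used as marginals; independence is a deliberate simplification (no
  covariance structure is published) and a correlation hook would be the
  natural extension for stress tests.
* **Raw fields.** For every drawn category the generator synthesises raw
  questionnaire fields strictly inside the category's interval (e.g. a
  weekday/weekend screen-time pair whose 5/7–2/7 weighting lands in the
  drawn band), so covariate derivation must reproduce the generated
  category exactly — a round-trip the test suite exercises.
* **Outcome model.** The latent probability of excessive intake follows a
  logistic model whose log-odds-ratios default to the published adjusted
  estimates (zero where undefined). The intercept is root-found so the
  cohort-average probability equals the tail mass of the percent-energy
  distribution above 10%E (≈ 22%). This self-consistency matters: free
  sugar %E is modelled as a gamma distribution moment-matched to mean 7.8
  and SD 3.2 (right-skewed and positive; only mean and SD are published,
  so the shape is a modelling choice), truncated to [1.5, 25] %E, and
  sampled *conditionally* on the latent flag (above or below 10%E). With
  the intercept tied to the gamma tail, that conditioning is
  distortion-free and the unconditional %E law is exactly the calibrated
  gamma.
* **Records.** Each child-day draws a basket of staple foods and a basket
  of sugar-dense foods (confectionaries sampled most often, then
  sugar-sweetened beverages, sugars/jams, juices). The two baskets' gram
  amounts are rescaled by an exact 2×2 linear solve so the day's energy
  equals the child's energy target (normal, mean 1371, SD 231 kcal/d,
  truncated to 700–2200) and the free-sugar %E equals the child's target.
  Rescaling is cheap and exact where rejection sampling would be neither;
  a solution exists whenever the sugary basket's free-sugar energy share
  exceeds the target and the staple basket's share is below it, which the
  food-table design guarantees (with a bounded resample as a guard).

What the generator does **not** emulate: real Japanese food names and
recipes, within-child day-to-day variance beyond what a 3-day mean needs,
covariate correlations, measurement error in weighing, or seasonal menus.
Tests passing on synthetic data therefore demonstrate the correctness of
the pipeline's arithmetic and inference machinery under the study's
statistical structure — not the field validity of any particular sugar
database.

## Problem sizes and determinism

The test suite runs the full pipeline at cohort sizes 8–332, parameter
recovery at n = 50,000 (where every generating coefficient must fall
within 3 standard errors of its estimate), and Wald-CI coverage over 500
simulated 2×2 tables; the acceptance script pools 10 seeded cohorts of
332. All randomness flows through a single seed per run; truncated
distributions are drawn by inverse-CDF so the draw count is fixed, and
identical seeds reproduce every output byte-for-byte.

## Known limitations

* The 11 added/free rule definitions follow the general stepwise
  convention of the literature; a specific published supplement may order
  or phrase them differently, which is why the rule order is
  configuration, not code.
* The all-sugar-carbohydrate predicate (total-sugar step 2) is an input
  flag, not an inference — no published inference rule exists.
* Foreign-table borrowing assumes the source item has already been
  selected (import source first, nutrient similarity second); the
  selection itself is upstream of this package.
* The synthetic child BMI cutoffs are a stand-in; conclusions about child
  weight status transfer to real data only with the published table.
* Simulated crude/adjusted odds ratios at n = 332 have wide sampling
  variation; only the contingency arithmetic on the published counts — not
  a re-simulation — reproduces the published estimates exactly.
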