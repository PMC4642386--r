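---
title: "Claims-based adherence analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Claims-based adherence analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcadhere)
```

## The problem

Whether patients actually take the medications they are prescribed is hard to
observe directly, but pharmacy claims give an objective proxy: if a patient
keeps refilling a prescription on time, supply is in hand on most days; if
refills lapse, it is not. `pdcadhere` implements the standard claims-based
adherence pipeline around the **proportion of days covered (PDC)** and the
comparative statistics of a two-arm, two-period (baseline year / follow-up
year) quasi-experimental design, as used to evaluate whether giving patients
online access to their primary-care visit notes changed adherence to
antihypertensive and antihyperlipidemic medications.

The package covers five stages, each usable on its own:

1. validated readers/writers for fill records and a patient roster
   (`read_fills()`, `read_patients()`, `write_results()`);
2. the PDC engine (`covered_days()`, `compute_pdc()`);
3. cohort assembly with eligibility filters (`build_cohort()`);
4. effect estimation (`rr_unadjusted()`, `rr_adjusted()`,
   `transition_rr()`, `risk_difference_and_nnt()`, `baseline_table()`);
5. a mechanistic synthetic claims generator (`sim_config()`,
   `simulate_claims()`, `calibrate_effect()`), because real health-plan
   claims are proprietary and cannot ship with the package.

## The PDC model

For one patient and one therapeutic subclass, each fill contributes
`days_supply` days of coverage starting at its fill date. Working in integer
day offsets from the window start, with half-open intervals `[start, end)`,
the number of covered days is the size of the union of coverage intervals
clipped to the 365-day window, and

$$\mathrm{PDC} = \frac{\text{distinct covered days in window}}{365} \in [0, 1].$$

A patient filling several subclasses of one drug class (say an ACE inhibitor
and a thiazide) gets one PDC per subclass, averaged (unweighted) into a
class-level PDC. A patient is **adherent** in a period when the class PDC is
at least 0.80, the breakpoint conventional for these drug classes; the
comparison is inclusive (`PDC = 0.80` is adherent).

One sentence in the study report defines the PDC as days covered
*multiplied by the number of claims* over 365; taken literally this exceeds 1
for any patient with two claims and contradicts the report's own statement
that the PDC is bounded by 1. We treat that sentence as a drafting artifact
and implement the standard distinct-days PDC that the adherence literature
(and the bound) defines.

### Carryover policies

When a refill arrives before the previous supply runs out, two conventions
exist:

- **`shift_forward`** (default): the new supply is banked and starts the day
  the old supply is exhausted. This is the prevailing PDC convention; no
  supply is wasted, though coverage never extends past the window end.
- **`truncate_overlap`**: overlapping days are simply lost; coverage is the
  plain interval union.

Both are exposed so sensitivity to the convention is checkable; for the same
fills `shift_forward` coverage is always at least `truncate_overlap`
coverage. Internally both have closed vectorised forms (a running-maximum
recurrence for deferral; a sorted union scan otherwise), and the test suite
checks them against brute-force day-marking simulators on a thousand random
fill streams.

Each period is an independent 365-day observation unit: supply dispensed in
the baseline year does not seed the follow-up year. Because this is a
genuine modelling choice, it is a switch (`cross_period_carryover`, default
off) rather than a fixed rule. Period windows are fixed calendar windows
(the design's enrollment waves started March 1 and July 1), not anchored to
each patient's first fill.

We cap each subclass PDC at 1 structurally (distinct-day counting cannot
exceed the window) *before* averaging subclasses. Whether the original
analysis capped before or after averaging is not stated; with distinct-day
counting the question dissolves, since no subclass stream can exceed 1.

## Eligibility and cohorts

`build_cohort()` applies, in order: age 18-89 at the baseline window start;
enrollment spanning both periods (`enroll_start <=` baseline start and
`enroll_end >=` follow-up end); and at least one fill of the drug class in
each period. Membership is order-insensitive; only the attrition log depends
on the order. Age is evaluated at a fixed time point (baseline start) to
keep the filter deterministic. Patients appearing in the fills but not the
roster are a hard referential-integrity error rather than a silent drop.

## Effect estimation

**Unadjusted risk ratios.** For adherent counts `a/n1` (intervention) vs
`c/n2` (control), the RR is `(a/n1)/(c/n2)` with the Katz log-method CI

$$\exp\left(\ln \widehat{RR} \pm 1.96\sqrt{\tfrac1a - \tfrac1{n_1} + \tfrac1c - \tfrac1{n_2}}\right)$$

and a two-sided Wald p on the log scale, no continuity correction. This
choice is not arbitrary: applied to the published per-arm counts it
reproduces the published intervals (for example 447/561 vs 759/1008 gives
1.06, CI 1.00-1.12, p .04 at table rounding).

**Adjusted risk ratios.** The study report says "multivariable logistic
regression" yet prints risk ratios, without stating the transformation from
odds to risks. We estimate adjusted RRs directly with **modified Poisson
regression**: a log-link Poisson GLM on the binary outcome with an HC0
robust (sandwich) variance estimator, the standard approach for common
binary outcomes where odds ratios would overstate effects. Two exact
properties anchor it: with the group term only it reproduces the crude RR
(to 1e-8; the one-factor log-linear model is saturated), and on a
constructed stratified table with homogeneous stratum RRs it equals the
closed-form Mantel-Haenszel common RR. Printed adjusted values in the
original tables may differ in later decimals from any one estimator choice;
the published adjusted RRs were therefore treated as context, not as exact
targets. Members missing a requested covariate are excluded from the
adjusted model with a logged count (the roster permits a missing BMI; the
original analysis adjusted for BMI only in the antihypertensive model, and
the default covariate lists mirror that: diabetes + BMI + PCP visits/year
for antihypertensives, diabetes + PCP visits/year for antihyperlipidemics).

**Transition analysis.** Each cohort member is cross-classified by baseline
and follow-up adherence into four levels (nonadherent-to-adherent,
adherent-to-adherent, nonadherent-to-nonadherent, and the reference
adherent-to-nonadherent). The per-level effect is the **conditional pairwise
risk ratio**: among members in `{level, reference}`, the ratio of the
conditional probabilities of `level` between arms, fed through the same Katz
machinery. This definition reproduces five of the six published unadjusted
transition RRs exactly from the published counts (1.30, 1.05 for
antihypertensives; 0.88, 0.98, 0.88 for antihyperlipidemics). The sixth
(antihypertensive nonadherent-to-nonadherent, published 1.03) computes to
1.11 from its own printed counts under this — or any ratio-of-conditional-
probabilities — definition; the original estimator for that cell is unclear,
and `reproduce_study_tables()` flags it as a documented discrepancy rather
than a match or failure. Similarly, the published CI upper bound for the
1.30 estimate (1.56) is not the Katz bound on the printed counts (1.63); the
original CI method for transition rows is unstated, so point estimates are
the comparison surface there. A full K-category multinomial likelihood is
deliberately out of scope; the pairwise conditional estimator is the
implemented contract, and its adjusted version restricts the modified
Poisson model to the two levels involved.

**Risk difference and NNT.** `RD = a/n1 - c/n2` with a Wald CI; the number
needed to treat is `1/RD` computed from the unrounded RD and rounded to the
nearest integer, reported only for positive RD (63/561 vs 93/1008 gives
RD 2.0 percentage points, NNT 50).

**Baseline tables.** Symmetric continuous variables get a pooled two-sample
t test (mean/SD), asymmetric ones Kruskal-Wallis (median/IQR), categorical
ones Pearson's chi-square **without** continuity correction — the
uncorrected statistic reproduces the published diabetes comparison
(160/561 vs 231/1008, p .01); the Yates-corrected version does not. No
multiple-testing adjustment is applied anywhere, matching the original
analysis. Degenerate inputs (constant variable, empty category) yield
`p = NA` with `valid = FALSE` instead of an error.

## The synthetic claims generator

The generator exists so that every pipeline stage is testable without
proprietary claims data. It is mechanistic rather than curve-fit: data
arise from a refill process, and the analysis-level quantities (adherence
rates, transitions, effect sizes) are *emergent*.

- **Latent propensity.** Each patient x class has a propensity
  $\pi \in (0,1)$, the steady-state PDC their refill behaviour targets,
  drawn from a two-component scaled-Beta mixture: a high-adherence bulk
  (weight 0.75, support 0.82-1.00) and a low-adherence tail (support
  0.20-0.85). A single-parameter family cannot simultaneously give a mean
  PDC near 0.86 and a nonadherent fraction above 20%, which the published
  marginals require.
- **Refill process.** Per subclass stream (1-3 subclasses per class; 30- or
  90-day supplies), the first fill lands within a week of the period start;
  thereafter the next fill comes at the previous coverage end plus a
  zero-inflated negative-binomial gap. The on-time probability is
  $0.3\,\pi$ and the positive-gap mean is set so the long-run PDC of the
  stream equals $\pi$ exactly: $E[\text{gap}] = S(1-\pi)/\pi$ for supply
  $S$. At $\pi \to 1$ every gap is zero (PDC 1); at $\pi \to 0$ the stream
  reduces to its single initial fill (PDC $\approx S/365$).
- **Periods and the intervention.** Follow-up propensity is coupled to
  baseline through a Gaussian copula with correlation 0.8, so adherence
  transitions emerge from propensity autocorrelation instead of being
  imposed; calibration only ever targets the marginal rates. A per-class
  secular `drift` (both arms) reproduces the year-over-year adherence
  decline, and an intervention-only `effect_shift` carries the effect.
- **Covariates** are drawn from the published baseline distributions (age
  60.5 (SD 12.9) truncated to 18-89, BMI log-normal around a median of 31,
  PCP visits log-normal around 3.3/year, Charlson negative-binomial) and
  are independent of propensity by default, so crude and adjusted estimates
  coincide up to noise; a `confound_diabetes` knob ties diabetes to
  propensity when a divergence between the two estimators is wanted.

**Calibration.** `calibrate_effect()` bisects the drift (control rate) and
then the shift (intervention rate) against simulated follow-up rates, using
common random numbers so the simulated rate is a deterministic monotone
function of the offset and bisection is exact. The shipped defaults were
fixed once by calibrating to the published follow-up rates at n = 50,000
with a 0.5-percentage-point tolerance — 0.797/0.753 for antihypertensives
(drift -0.094, shift 0.156) and 0.776/0.773 for antihyperlipidemics (both
parameters 0, the difference being inside tolerance) — together with
bulk weight 0.75, which puts baseline adherence at 0.78 and mean PDC at
0.87. The published marginals are the study conditions; they were chosen
from those targets alone and not revisited.

**What the generator does not emulate.** No seasonality or calendar
effects, no dose changes, switching or discontinuation episodes, no
physician-level clustering, no portal-usage behaviour (the original design
kept non-viewers in the intervention arm), and no claim-level adjudication
fields. The refill-gap distribution is a stand-in: the study never
published claim-level interval data, so passing tests show that the
*pipeline* recovers configured truths from data with the right marginal and
transition structure — not that real claims look like this in fine detail.

## Numerical choices and degenerate inputs

- All date arithmetic is integer day offsets from the window start; dates in
  files are ISO-8601 only, making parsing locale-independent.
- Coverage intervals are half-open, so union lengths are additive and a fill
  on day `d` with supply `s` covers days `d ... d+s-1`.
- An empty fill stream has `covered_days = 0` (not an error); fills dated
  outside the window are dropped with a warning.
- A zero cell in a 2x2 yields a point estimate with non-finite CI/p flags,
  no continuity correction by default.
- GLM convergence uses a 1e-10 IRLS tolerance (tighter than the default so
  the crude-equivalence identity holds to 1e-8); non-convergence and
  rank-deficiency are errors naming the offending terms, never silent.
- `NNT` is computed from the unrounded RD; equal rates flag it undefined.
- The propensity-mixture quantile is tabulated on a 4096-point grid
  (interpolation error below 1e-3 on the propensity scale, negligible
  against refill-process noise).

## Problem sizes used in testing

The bundled checks run the oracle comparison on 1000 random fill streams,
CI coverage on 1000 simulated tables, effect recovery on one n = 50,000
end-to-end run (the size at which the calibration tolerance and sampling
error together bound the recovered RR within about 0.035 of the 1.058
target), and null-effect coverage on 500 replicates of a 570-patient
comparison. These sizes were chosen so each Monte-Carlo band is decisive
for the property it checks while the whole suite stays comfortably
interactive.

## Known limitations

- The published adjusted RRs cannot be reproduced exactly without the
  original patient-level covariates; the package demonstrates estimator
  correctness through equivalence and recovery properties instead.
- The pairwise conditional transition estimator is a contract choice; a
  joint multinomial fit could give slightly different adjusted transition
  effects.
- Subclasses are opaque labels; there is no therapeutic-class dictionary,
  NDC mapping, or claims adjudication detail.
- The two enrollment waves are pooled (as in the original analysis); no
  wave-specific adjustment is offered beyond per-wave window configuration.
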