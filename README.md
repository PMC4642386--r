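# pdcadhere

Claims-based medication adherence analysis in R: proportion of days covered
(PDC), the 80% adherence breakpoint, and the comparative statistics of a
two-arm pre/post (baseline year / follow-up year) quasi-experimental design.

## What it is for

Pharmacy claims are the standard objective window on whether patients keep
taking chronic medications: fill dates and days of supply determine, for
each day of an observation year, whether supply was in hand. `pdcadhere` is
aimed at health-services and epidemiology analysts who need to

- turn raw fill records into per-patient, per-drug-class PDC values
  (`PDC = distinct covered days / 365`, per therapeutic subclass, averaged
  across subclasses of a class) with explicit refill-carryover conventions;
- dichotomise adherence at the conventional `PDC >= 0.80` breakpoint;
- compare an intervention arm against a control arm: unadjusted risk ratios
  with Katz log-method 95% CIs,
  `exp(ln RR ± 1.96·sqrt(1/a − 1/n₁ + 1/c − 1/n₂))`; covariate-adjusted
  risk ratios by modified Poisson regression (log-link GLM with robust
  sandwich variance); four-level adherence-transition analysis
  (nonadherent→adherent, adherent→adherent, nonadherent→nonadherent versus
  the adherent→nonadherent reference) via conditional pairwise risk ratios;
  absolute risk difference and number needed to treat; and baseline
  characteristic tables (t test / Kruskal-Wallis / Pearson chi-square);
- generate realistic synthetic claims (`simulate_claims()`) whose refill
  mechanics are calibrated to published study conditions — mean PDC around
  0.86, 75-80% adherent, a small intervention effect on follow-up adherence
  for one drug class — so the whole pipeline is testable without
  proprietary health-plan data.

The methods vignette (`vignettes/adherence-methods.Rmd`) documents the
model, every tunable parameter, the generator's mechanism and calibration,
and the design decisions.

## Worked example

Simulate a study at the published scale (756 intervention / 1391 control
patients, two 365-day periods, two drug classes), run the full analysis,
and read off the follow-up comparison for antihypertensives:

```r
library(pdcadhere)

cfg <- sim_config(seed = 2026)
sim <- simulate_claims(cfg)
res <- run_analysis(run_config(sim$patients, sim$fills))

co <- res$cohorts$antihypertensive
ri <- adherence_rate(co, "follow_up", "intervention")
rc <- adherence_rate(co, "follow_up", "control")
sprintf("follow-up adherence: intervention %d/%d (%s%%), control %d/%d (%s%%)",
        ri$count, ri$n, format_rate(ri$proportion),
        rc$count, rc$n, format_rate(rc$proportion))
#> "follow-up adherence: intervention 462/574 (80.5%), control 771/1025 (75.2%)"

fu <- subset(res$effects, class == "antihypertensive" & period == "follow_up")
sprintf("crude RR %s (%s-%s), p %s",
        format_rr(fu$estimate[!fu$adjusted]), format_rr(fu$ci_low[!fu$adjusted]),
        format_rr(fu$ci_high[!fu$adjusted]), format_p(fu$p[!fu$adjusted]))
#> "crude RR 1.07 (1.01-1.13), p .01"
```

The simulated intervention arm is about 5 percentage points more adherent
at follow-up, a crude risk ratio of 1.07 — one seed's draw around the
calibrated true effect of 1.058. The transition analysis emerges from the
same mechanism (propensity autocorrelation between years, not imposed
counts):

```r
res$transitions$antihypertensive
#> # A tibble: 8 × 3
#>   group        level                          n
#>   <chr>        <chr>                      <int>
#> 1 intervention nonadherent_to_adherent       56
#> 2 control      nonadherent_to_adherent       74
#> 3 intervention adherent_to_adherent         406
#> 4 control      adherent_to_adherent         697
#> 5 intervention nonadherent_to_nonadherent    74
#> 6 control      nonadherent_to_nonadherent   166
#> 7 intervention adherent_to_nonadherent      38
#> 8 control      adherent_to_nonadherent      88
```

Against the reference level, previously nonadherent intervention patients
were more likely to become adherent:

```r
tr <- subset(res$effects, class == "antihypertensive" & !adjusted &
             comparison == "nonadherent_to_adherent_vs_adherent_to_nonadherent")
sprintf("nonadherent-to-adherent conditional RR %s (%s-%s)",
        format_rr(tr$estimate), format_rr(tr$ci_low), format_rr(tr$ci_high))
#> "nonadherent-to-adherent conditional RR 1.30 (1.03-1.65)"
```

Because the original claim-level data are proprietary, the published
unadjusted effects are instead reproducible from the published per-arm
counts, which ship with the package:

```r
reproduce_study_tables()[, c("class", "contrast", "computed", "published", "status")]
```

Every row matches at table rounding (e.g. follow-up antihypertensive RR
1.0582 → 1.06; transition RRs 1.30/1.05/0.88; NNT 50) except the one
transition cell whose published value is not a ratio of its own printed
conditional probabilities; that row is flagged `documented_discrepancy`.

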