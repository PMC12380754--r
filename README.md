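# pvkit

Signal detection and time-to-onset analysis for spontaneous
adverse-event reporting system (SRS) data, such as FAERS quarterly
extracts, with a synthetic-report generator for end-to-end validation.

Pharmacovigilance studies mine passive reporting databases for drug-event
pairs that are reported disproportionately often. `pvkit` packages that
workflow for analysts who want it reproducible and testable: ingestion of
the FAERS `$`-delimited ASCII dialect (or a generic per-table CSV
dialect), case-level deduplication, restriction to primary-suspect
reports, 2×2 contingency tables at MedDRA preferred-term (PT) or
system-organ-class (SOC) level, four disproportionality algorithms with a
consensus screening rule, Weibull time-to-onset modelling, cross-database
signal overlap, and the set/graph/enrichment mechanics of a
network-pharmacology follow-up on user-supplied gene lists.

## The statistics

For each drug-event pair, with `a` reports carrying both the target drug
and the event, `b` the drug with other events, `c` the event with other
drugs and `d` neither (`N = a+b+c+d`):

- **ROR** `= ad/bc`, with 95% CI
  `exp(ln ROR ± 1.96 √(1/a+1/b+1/c+1/d))`; Haldane–Anscombe +0.5 on
  zero-cell tables.
- **PRR** `= [a/(a+b)] / [c/(c+d)]` with the 1-df chi-squared
  `N(ad−bc)² / [(a+b)(c+d)(a+c)(b+d)]` and Bonferroni-adjusted p-values.
- **BCPNN information component** `IC = log₂ P(drug,event)/(P(drug)P(event))`
  via the closed-form posterior moments (standard prior constants);
  `IC025 = E(IC) − 2√V(IC)`.
- **MGPS / EBGM**: DuMouchel's gamma-Poisson shrinker. The relative
  reporting rate λ has a two-component gamma mixture prior fitted by
  maximizing the negative-binomial mixture marginal likelihood;
  `EBGM = 2^{E[log₂ λ | a]}` and `EBGM05` is the posterior 5th
  percentile.

A pair is a **significant signal** when all four algorithms exceed their
standard thresholds (`a ≥ 3` & ROR CI-low > 1; PRR ≥ 2 & χ² ≥ 4 & a ≥ 3;
IC025 > 0; EBGM05 ≥ 2), with a Bonferroni gate at PT level.

Time to onset (therapy start to event date, after date hygiene) is
summarized by quartiles and 30-day bins, and fitted with a Weibull MLE:
a shape CI entirely below 1 is the *early-failure* pattern (risk
concentrated early in treatment).

## Worked example

```r
library(pvkit)

# a synthetic database of 20,000 reports, one planted signal at RR = 10
cfg <- sim_config(n_reports = 20000, n_drugs = 10, n_events = 100,
                  signal_pairs = data.frame(drug = 1, event = 1, rr = 10),
                  seed = 4001)
coh   <- generate_reports(cfg)
clean <- as_clean_reports(deduplicate(coh$data))
tabs  <- build_tables(clean, "DRUG_001", level = "PT")
sig   <- compute_signals(tabs)          # fits the MGPS prior internally
v     <- classify_signals(sig)

subset(merge(sig, v[c("label", "classification")], by = "label"),
       classification == "significant",
       select = c(label, a, ror, prr, ic025, ebgm05))
#>        label   a      ror      prr    ic025   ebgm05
#> 1 EVENT_0001 382 11.86163 9.726202 2.188295 5.250018
```

The planted pair is the only label passing all four algorithms: it was
reported 382 times against an expectation of about 73 under independence,
an observed reporting odds ratio near 12, information component lower
bound 2.2 bits, and a shrunken relative reporting rate (EBGM05) above 5.

Onset-time analysis on the same cohort:

```r
tto <- compute_tto(clean, drug_names = "DRUG_001")
fit <- weibull_fit(tto$records$days)
fit
#> <weibull_fit> shape 0.867 [0.838, 0.897], scale 10.26 [9.72, 10.84] days,
#>   pattern: early_failure (n=1943)
```

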