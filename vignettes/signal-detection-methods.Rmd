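---
title: "Disproportionality signal detection and time-to-onset analysis with pvkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and time-to-onset analysis with pvkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvkit)
```

## The problem

Spontaneous reporting systems (SRS) such as FAERS collect voluntary
reports of suspected adverse drug events. They have no denominator — no
exposure counts, no population at risk — so absolute risks cannot be
estimated. What can be estimated is *disproportionality*: whether a
drug-event pair is reported more often than the database's own reporting
background predicts. `pvkit` implements the standard four-algorithm
workflow used in contemporary pharmacovigilance studies of single drugs
(here modelled on echinocandin antifungal surveillance), together with
the data-hygiene steps that precede it and the time-to-onset and
network-pharmacology analyses that usually follow it.

## Data model and hygiene

Reports arrive as relational tables keyed by a report-version identifier
(`primaryid`), with a case identifier (`caseid`) grouping successive
versions of the same case. `read_faers_quarter()` parses the
`$`-delimited quarterly ASCII layout; rows whose field count disagrees
with the header are skipped and counted rather than failing the load,
because real extracts contain malformed lines and an analyst needs the
loss accounted, not fatal. `deduplicate()` applies the published FDA
rule: one report per case, keeping the latest receipt date and breaking
ties by the numerically larger report identifier.

Drug-name matching is a deliberate lowest common denominator:
case-insensitive substring search of the generic and trade names against
the verbatim name field. Dictionary normalization (RxNorm and the like)
is out of scope; the verbatim field is what a reporting-system query
actually sees. Only reports with the target drug in the *primary
suspect* role enter the numerator population, which removes most (not
all) confounding by co-medication.

Partial dates travel as `YYYYMMDD` / `YYYYMM` / `YYYY` strings. A date
is usable for onset arithmetic only at day resolution; year-level dates
still support year filtering. This representation mirrors the source
format and makes the exclusion rules exact and testable.

## The four algorithms

All four operate on the 2×2 report-level table (a report counts once per
event label regardless of how many of its terms map there — the
`counting = "pairs"` option exists for tables published with pair-level
counting, at the cost of pair-valued margins).

The frequentist pair: the reporting odds ratio with Rothman's Wald
interval, and the proportional reporting ratio with the one-degree
chi-squared. The source tables for this workflow reference but do not
print their formulas, so the standard literature forms are used and
tested against independent arithmetic oracles. Zero cells get the
Haldane–Anscombe +0.5 on all four cells, applied only when a zero is
present and only to the ratio estimates; the chi-squared always uses raw
counts (Yates' correction is available by flag but off by default, since
the conventional PRR ≥ 2 & χ² ≥ 4 thresholds assume the uncorrected
statistic).

The Bayesian pair:

- **BCPNN information component**, in the closed form of the original
  publication with prior constants α₁ = β₁ = 1, α = β = 2, γ₁₁ = 1 and γ
  scaled so the prior IC expectation is zero. `IC025 = E(IC) − 2√V(IC)`.
  The constants are exposed in a config argument but there is no reason
  to change them in routine use.
- **MGPS**: the gamma-Poisson shrinker. Observed counts are Poisson with
  mean λE, E = (a+b)(a+c)/N, and λ carries a two-component gamma mixture
  prior fitted by maximum marginal likelihood (negative-binomial
  mixture). The posterior for each pair is again a gamma mixture; `EBGM`
  is the posterior geometric mean via the digamma identity and `EBGM05`
  the posterior 5th percentile by monotone root-finding on the mixture
  CDF — exact at this scale, so quantile approximations are not used.

The mixture likelihood is multimodal: besides label switching it has a
degenerate mode that parks one component at zero weight, which
under-shrinks isolated strong signals. The fitter therefore runs a fixed
battery of four starts (DuMouchel's published start, its label swap, a
null-dominant start and a diffuse one) and keeps the best converged
optimum, with jittered restarts as a fallback. Fits on fewer than ~20
tables trigger a warning; hyperparameters estimated from a handful of
cells are not meaningful.

Bonferroni adjustment is applied to the chi-squared p-values with family
size equal to the number of labels tested in that database view at that
level, and the family size is recorded with the results. Which p-values
the original workflow adjusted is not stated anywhere authoritative;
adjusting the only frequentist test p-value is the defensible reading.

## Consensus screening

A label is a *significant* signal when all four algorithms pass their
standard thresholds (a ≥ 3 with ROR CI-low > 1; PRR ≥ 2, χ² ≥ 4, a ≥ 3;
IC025 > 0; EBGM05 ≥ 2). At SOC level a single passing algorithm already
marks the class *positive*; at PT level the all-four rule (plus the
Bonferroni gate, which applies at PT level only) is the published
convention and anything short of it is reported negative. The rule is
monotone — improving any one statistic can never demote a significant
signal — and that property is tested.

Manual curation of signals ("unrelated to therapy", "indication", driven
by the underlying disease) cannot be reproduced from any published list,
so `apply_exclusions()` makes it explicit: a user-supplied blocklist of
case-insensitive glob patterns with reason tags, which *marks* rows and
never deletes them. Cross-database agreement is summarized by
`overlap_sets()`, which returns every exclusive Venn region so that the
region sizes provably partition the union.

## Time to onset

Onset is the calendar-day difference between the earliest complete
therapy start among the matching primary-suspect drug entries and the
event date. Every input report is accounted for: it yields either a
record or an exclusion tagged `incomplete_date`, `event_before_start` or
`unparseable`. Summaries use type-7 (linear interpolation) quantiles —
the source method is unstated, and type-7 is R's default and the most
common choice. "Month" means 30 days for binning; both are arguments.

The Weibull shape β is the clinically interpretable quantity: β < 1 with
the whole CI below 1 is the *early-failure* pattern (hazard decreasing
with time on drug), CI above 1 *wear-out*, anything else *random*. The
MLE is a Newton iteration on the profile likelihood of β (the scale has
a closed form given β), with Wald 95% intervals from the observed
information on the log-parameter scale — the CI construction of the
source analysis is unstated, and the log-scale Wald interval respects
positivity at negligible cost. Zero-day onsets are kept as 0 in
summaries and bins but replaced by 0.5 day inside the likelihood, whose
support is t > 0; the replacement value is an argument. Kaplan–Meier
cumulative incidence is included because the workflow plots it; with no
censoring it reduces to the empirical CDF (tested), and censoring
support is retained for reuse. Across-SOC comparisons use the
tie-corrected Kruskal–Wallis test, with the degenerate all-identical
case defined as H = 0, p = 1.

## Network-pharmacology mechanics

The downstream mechanism analysis is computable once its inputs are
fixed, and only the computation is in scope: gene lists, scored target
tables, a scored interaction edge list and GMT annotation sets are
user-supplied files; the package never queries an online service, which
is what makes the stage reproducible. Provided are threshold filtering
of scored tables, set intersection with the Venn percentage of the
union, confidence filtering of the interaction network (inclusive at
the cutoff), betweenness-centrality hub ranking (Brandes, normalized;
ranking within one graph is normalization-invariant; ties broken
alphabetically), and hypergeometric over-representation with
Benjamini–Hochberg adjustment, upper tail only, annotation sets trimmed
to the universe before testing and zero-overlap sets reported at p = 1.

## The synthetic generator

Because no SRS extract can be redistributed, every stage is validated on
synthetic cohorts with known ground truth. The generator emulates:

- one suspect drug per report, drawn uniformly (the analysis restricts
  to primary-suspect reports, so multi-drug confounding is deliberately
  not simulated);
- 1–3 distinct event terms per report (FAERS averages roughly 2.5) from
  an event multinomial drawn once per configuration from a symmetric
  Dirichlet(1) — uniform margins would make the chi-squared degenerate
  across pairs;
- planted signals: for designated (drug, event) pairs the conditional
  event probability is multiplied by the relative-risk factor and the
  row renormalized, so the realized marginal relative risk sits slightly
  below the multiplier;
- Weibull onset times, default shape 0.8 and scale 10 days (median
  about 6 days, an early-failure regime matching published echinocandin
  onset summaries), with therapy start, event and receipt dates laid
  out consistently;
- demographic missingness at realistic rates (weight ~70%, age ~20%,
  sex ~12%), duplicate case versions with strictly later receipt dates
  and perturbed reaction lists, and date corruption (year-only,
  year-month, missing, inverted), all recorded in the truth metadata.

What it does **not** emulate: polypharmacy and indication channeling,
reporter stimulation (notoriety bias), terminology drift, and any
realistic joint dependence between demographics and events. Passing
tests on these cohorts therefore demonstrate the *correctness of the
computations and rules*, not the clinical validity of signals mined from
any real database. All distributional choices are stand-ins and are
labelled as such in `truth$notes`.

Determinism: a configuration plus seed reproduces the cohort
byte-for-byte; the duplicate/corruption/onset substreams derive child
seeds from the config seed.

## Validation scale and numerical choices

The test suite checks, at sizes chosen to keep the full run around two
minutes on one CPU: oracle equality of all four statistics on 120
generated tables (independent arithmetic, expected-count chi-squared,
term-by-term IC, and numerical quadrature of the gamma-Poisson
posterior, to three significant figures); null calibration on 20
databases of 50,000 reports (consensus flags ≤ 1% of labels, IC025 > 0
in ≤ 5%); recovery of a planted tenfold signal with expected count ≥ 20
in ≥ 95% of 20 replicates; Weibull shape recovery at the published
study size (n = 657, 100 replicates: mean absolute relative error < 5%,
near-nominal CI coverage); exact round trips of write → read →
deduplicate; and brute-force agreement of betweenness and
hypergeometric enrichment. The same quantities are recomputed from
scratch by `scripts/acceptance.R`.

Numerical notes: t^β sums in the Weibull likelihood are computed on a
rescaled exponential scale to avoid overflow; contingency cells are
promoted to double before products (a four-cell product overflows
32-bit integers already at moderate database sizes); the EBGM05 root
finder brackets the quantile by doubling and reports a diagnostic error
if bracketing fails rather than returning a wrong quantile.

## Known limitations

- No stratified MGPS (age/sex/year strata in the expected counts) and no
  regression-based confounding adjustment.
- Percentage conventions in published summary tables vary by source and
  column; the tally-denominator convention implemented here reproduces
  the standard layout but cannot match tables whose printed percentages
  are internally inconsistent.
- The blocklist mechanism makes exclusion screening explicit but cannot
  recover any study's unpublished manual curation, so published positive
  signal *counts* are not reproducible targets.
- Betweenness normalization conventions differ across tools; hub
  *rankings* are unaffected within a single graph.
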