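---
title: "Disproportionality signal detection on spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Spontaneous reporting systems such as FAERS collect unsolicited reports of
suspected adverse drug events. They have no denominator (no count of exposed
patients), so absolute risks cannot be estimated. What *can* be estimated is
disproportionality: whether a drug–event pair is reported more often than
expected if drug and event were mentioned independently across the database.
`pvsignal` implements the full workflow — raw quarterly-file ingestion
through classified signal tables — for a target drug analysed as the
*primary suspect* (PS), with teriparatide as the bundled worked case study.

## Data model

A case report is one deduplicated safety report: demographics and reporter
fields, a list of drug entries (name, active ingredient, role code PS/SS/C/I,
route, therapy start date), reaction preferred terms (PTs), outcome codes,
and indication terms. The package keeps these as linked tables
(`faers_cases`) keyed by `primaryid`, mirroring the relational layout of the
source files rather than nesting them, which keeps 10^4–10^6-row collections
cheap to filter and join.

Only the post-2012Q4 extract schema (`primaryid`/`caseid`/`caseversion`) is
supported. The legacy ISR-keyed layout would double the parser surface for
data that modern analyses rarely revisit, and the synthetic generator emits
the modern schema only.

### Deduplication

FAERS distributes follow-up versions of a case under the same `caseid` with
an incremented `caseversion`. Public descriptions of analyses rarely state
the exact rule, so the package fixes one and records it in run metadata:
keep the highest `caseversion`; break ties by the latest receipt date,
then by the largest `primaryid`. The rule is deterministic and idempotent,
and an FDA deleted-case list can be applied on top. Both behaviours are
options because practice varies between analyses.

### Counting unit

All 2×2 tables count **distinct (report, term) pairs**: a report mentioning
the same PT twice contributes once; at SOC level a report with two PTs of
the same SOC contributes once to that SOC. This matches the convention in
which a database of ~17 million reports yields ~50 million "adverse events".
Whether published tables use the pair total or the report total for *n* is
usually unstated; the pair convention keeps each level internally consistent
(SOC-level `d` derives from the SOC-level `n`) and is recorded in output
metadata. Report-level counting can be obtained by restricting each report
to its distinct term set, which is what the distinct-pair rule already does
per term.

Subgroup analyses (built-ins: healthcare-professional reporters, females,
age ≥ 45) recompute all margins *within* the subgroup, so the comparator is
the same-subgroup non-target pairs. Reports with missing age fail the age
predicate and drop out of age-restricted subgroups.

## The four statistics

For a 2×2 table with cells `a` (target drug & event), `b`, `c`, `d` and
`n = a+b+c+d`:

* **ROR** `= ad/bc`, Wald 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`.
* **PRR** `= [a/(a+b)]/[c/(c+d)]`, CI
  `exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`, reported with the
  Pearson χ² of the table. χ² uses the Yates continuity correction by
  default — the convention of the PRR signal criterion in the
  pharmacovigilance literature — with the uncorrected statistic behind a
  flag.
* **BCPNN IC**: the information component
  `IC = log2 p(drug,event)/(p(drug)p(event))` under independent Beta
  posteriors with the standard uniform-margin priors
  (`α1 = β1 = γ11 = 1`, `α = β = 2`; the joint prior total is chosen per
  table so the prior IC is centred on independence). The default output is
  the classical closed-form moment approximation (log of posterior means,
  delta-method variance), with `IC025 = E(IC) − 2√V(IC)`.
* **MGPS/EBGM**: empirical-Bayes shrinkage of the relative reporting rate
  `λ = a/E`, `E = (a+b)(a+c)/n`, under a two-component gamma mixture prior
  fitted to *all* drug–event cells (including zeros). `EBGM` is the
  posterior geometric mean `exp(E[ln λ])` — matching the estimator's name —
  and `EBGM05`/`EBGM95` are exact posterior quantiles. The arithmetic
  posterior mean is also reported for diagnostics.

### Exact versus approximate BCPNN moments

`ic_bcpnn(..., moments = "exact")` returns the *exact* first two moments of
the same Beta model via digamma/trigamma identities
(`E ln Beta(u,v) = ψ(u) − ψ(u+v)`). The closed-form approximation carries a
known downward-bias term of order `1/(2 ln2 (a + γ11))`, negligible for
large cells but visible for small `a`. The approximation remains the
default because it is the form in routine pharmacovigilance use; the exact
moments exist so that calibration tests can compare against Monte-Carlo
sampling of the Beta posteriors at high precision, which the approximation
by construction cannot satisfy.

### Zero cells

ROR, PRR and χ² receive the Haldane–Anscombe correction: if any cell is
zero, 0.5 is added to all four cells (recorded in output). An all-zero
table yields an undefined marker (`NA`), never a number. BCPNN and MGPS
handle `a = 0` natively and receive no correction.

### MGPS numerics

The marginal likelihood of the cell counts is a two-component negative
binomial mixture. It is maximized on transformed parameters (log for the
four gamma parameters, logit for the mixing weight) with L-BFGS-B inside
the box `[-12, 12]`, i.e. parameters confined to `(e^-12, e^12)`: a
variance-zero component — which arises naturally when the data are exactly
Poisson, as in the synthetic null — is represented at the box boundary
instead of diverging. Optimization starts from the classical
`(0.2, 0.1, 2, 4, 1/3)` plus four jittered restarts; the best likelihood
wins and the optimizer status sets `converged`. All-zero counts are
rejected (the mixture is unidentifiable), and an optional zero-truncated
likelihood supports databases where `a = 0` cells are unavailable. For very
large databases `squash_cells()` collapses identical `(a, binned E)`
strata into weighted cells.

Posterior quantiles solve the monotone mixture-gamma CDF by `uniroot`
bracketed between the two component quantiles, to 10⁻⁹ tolerance.

### Thresholds

Defaults: ROR lower CI bound > 1; PRR ≥ 2 with χ² ≥ 4; IC025 > 0 (strict,
so an IC025 of exactly 0 is not a signal); EBGM05 ≥ 2; and a minimum case
count `a ≥ 3`. The minimum-count rule gates **all four** flags: the count
requirement is part of what the field means by "signal", and applying it
only to the frequentist pair would let a single Bayesian flag bypass it.
The combined flag defaults to ALL (every criterion met), the conservative
choice when the goal is a cross-validated signal list; ANY and
per-algorithm reporting are configurable. An undefined statistic makes its
flag false.

## Descriptive characteristics

`summarize_characteristics()` reproduces the standard clinical table with
explicit denominator policies:

* year, gender, age bands, reporter, country, route, indications: percent
  of **total reports**;
* outcomes: percent of **outcome records**, because multi-outcome reports
  contribute one record per outcome (this is why published outcome columns
  sum to 100 on a smaller denominator than the report total);
* time to onset: percent of reports carrying at least one therapy-start or
  event date record, with an in-section Unknown bucket; reports with no
  date record at all leave the section entirely.

Age bands are half-open on the printed labels: `[0,18)`, `[18,45)`,
`[45,65)`, `[65,75)`, `[75,∞)`. Onset bands are `[0,7)`, `[7,28)`,
`[28,60)`, `[60,∞)` whole days from the earliest day-precision therapy
start of the target PS drug to a day-precision event date; negative gaps
and reduced-precision dates are Unknown. Route is taken from the target PS
drug entry with unknown routes folded into Other (the published route
sections sum exactly to the report total with no Unknown row, which is
only consistent with that folding). Percentages round half-up to two
decimals.

One published inconsistency is deliberately not replicated: the bundled
case study's indication percentages imply an unstated denominator
(67,224/107,123 = 62.75%, printed 62.11), and two prose percentages
disagree with their own table. The package always recomputes percentages
from counts under the policies above.

## The synthetic generator

`generate_quarter()` emits a complete quarterly file set plus ground truth.
It emulates the features the pipeline must survive: multi-drug multi-PT
reports with role codes, power-law drug and event frequencies, duplicate
case versions, a deleted-case list, missing and reduced-precision dates,
FAERS age-unit codes, and planted drug–PT associations. Signals are
planted **multiplicatively on the PT-selection probability** — the same
relative reporting rate λ that MGPS estimates — so parameter recovery is
well-defined; after renormalization, the realized marginal enrichment of a
planted pair is somewhat below its nominal `rr` (the manifest records the
realized exposure counts for exact assertions).

What it does *not* emulate, and what passing tests therefore do not show:
verbatim drug-name misspellings (synonym matching is exercised only
structurally), reporting-rate drift over calendar time, correlated
co-reporting beyond the planted pairs, multi-quarter accumulation, and
real MedDRA structure (the toy PT→SOC map is round-robin). Results on real
FAERS data additionally depend on name cleaning and dictionary quality.

Default conditions: 50,000 reports, 40 drugs (target share 5%), 120 PTs
across 12 SOCs, three ten-fold planted pairs at a common, mid-frequency
and rare PT, mean 2 drugs and 3 PTs per report, 2% duplicate versions, 1%
deleted cases — a desk-scale stand-in for a database three orders of
magnitude larger, at which all four algorithms have ample power for a
ten-fold signal. Validation in the test suite runs the generator at 300 to
50,000 reports depending on what a property needs, and MGPS
parameter-recovery simulations use 20,000 cells per replicate.

## Determinism

Given a configuration and seed, generation is byte-identical and the
pipeline writes byte-identical CSVs. The only stochastic component of the
analysis itself is the jittered-restart MGPS fit, seeded from the run
configuration. Run metadata records every default in effect (dedup rule,
counting unit, zero policy, thresholds, fitted prior, dictionary-version
string if the user supplies one) so results are auditable.

## Limitations

Disproportionality is association, not causation, and shares the known
biases of spontaneous data (under- and selective reporting, stimulated
reporting waves, confounding by indication). The package deliberately
excludes regression-based confounder adjustment, multi-axial MedDRA
mapping, drug–drug interaction signals, time-stratified tables and
multiple-testing correction: per-pair thresholds are the convention the
implemented battery reproduces.
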