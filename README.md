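# pvsignal

Pharmacovigilance signal detection on spontaneous adverse-event report
databases distributed in the FAERS quarterly ASCII format.

Spontaneous reporting systems have no exposure denominator, so drug safety
signals are mined by *disproportionality*: for each drug–event pair, the
2×2 table

|                  | event of interest | other events | total |
|------------------|-------------------|--------------|-------|
| target drug (PS) | a                 | b            | a + b |
| all other drugs  | c                 | d            | c + d |

is summarized by four complementary statistics:

* **ROR** = ad/bc with Wald 95% CI;
* **PRR** = [a/(a+b)] / [c/(c+d)] with CI and Pearson χ² (Yates-corrected
  by default);
* **BCPNN IC** = log₂ of the shrunk observed-to-expected joint reporting
  probability, with its lower credibility bound IC025;
* **MGPS EBGM** = empirical-Bayes geometric mean of the relative reporting
  rate λ = a/E, E = (a+b)(a+c)/n, under a two-component gamma mixture
  prior fitted to all drug–event cells, with posterior quantile EBGM05.

A pair is a signal (default policy) when all four criteria hold: ROR lower
CI bound > 1, PRR ≥ 2 with χ² ≥ 4, IC025 > 0, EBGM05 ≥ 2, and a ≥ 3 case
reports.

The package covers the full workflow for a target drug analysed as primary
suspect — quarterly-file parsing, case-version deduplication,
primary-suspect filtering with a synonym list, PT→SOC mapping from a
user-supplied table (MedDRA is licensed and not bundled), PT- and
SOC-level contingency tables, subgroup analyses, descriptive
clinical-characteristics tables, and classified signal tables — plus a
synthetic FAERS-like generator with planted signals so the whole pipeline
is testable without downloading FAERS. The bundled case study is
teriparatide (synonyms TERIPARATIDE, FORTEO, FORSTEO, BONSITY).

## Worked example

Generate a 20,000-report synthetic database with three ten-fold planted
drug–PT associations and run the pipeline:

```r
library(pvsignal)

cfg <- run_config(
  synth   = synth_config(n_reports = 20000, seed = 42),
  out_dir = "demo_run", seed = 1)
res <- run_pipeline(cfg)

res$top_pt[1:5, c("term","a","ror","prr","chi2","ic","ic025",
                  "ebgm","ebgm05","signal")]
#>    term   a  ror  prr    chi2    ic  ic025 ebgm ebgm05 signal
#>  PT_024 173 7.25 6.82  661.72 2.409  2.160 5.36  5.341   TRUE
#>  PT_096  97 7.03 6.80  365.36 2.376  2.048 5.36  5.341   TRUE
#>  PT_006 332 7.44 6.59 1240.50 2.389  2.206 5.36  5.341   TRUE
#>  PT_025  32 1.32 1.32    2.03 0.363 -0.157 1.00  0.939  FALSE
#>  PT_092  17 1.52 1.51    2.32 0.524 -0.180 1.00  0.935  FALSE
```

The three planted pairs (PT_006, PT_024, PT_096) head the EBGM ranking and
are the only flagged signals; the unplanted terms shrink to EBGM ≈ 1. The
run directory contains `characteristics.csv`, `pt_signals.csv`,
`soc_signals.csv`, `waterfall.csv` (all PTs, EBGM-descending),
`top30_pt.csv`, one score table per subgroup, and `run_metadata.json`
recording every default in effect. The descriptive table uses the field's
denominator conventions, e.g.

```r
ch <- res$characteristics
ch[ch$section == "Gender" & ch$subgroup == "all", ]
#>  category count denominator percent
#>    Female   762         881   86.49
#>      Male    97         881   11.01
#>   Unknown    22         881    2.50
```

Any published 2×2 can be spot-checked directly. Reconstructing the cells
of the teriparatide / blood-calcium-increased pair from its published
margins:

```r
stats_2x2(1988, 340702, 5777, 50521241)[
  , c("ror","ror_lo95","ror_hi95","prr","chi2","ic","ic025")]
#>    ror ror_lo95 ror_hi95   prr  chi2    ic ic025
#>  51.03    48.49     53.7 50.74 72088 5.221 5.149
```

matching the published ROR 51.02 (48.46–53.72), PRR 50.73, IC 5.22 (5.15).

The same battery is available from a shell:

```sh
Rscript inst/cli/pvsignal.R stats --a 10 --b 20 --c 30 --d 240
Rscript inst/cli/pvsignal.R generate --config gen.yaml --out synth_dir
Rscript inst/cli/pvsignal.R run --config run.yaml --out out_dir
```

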