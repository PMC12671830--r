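# faersped

Pharmacovigilance signal detection for TNF-α inhibitors in children, built
on the FAERS (FDA Adverse Event Reporting System) quarterly data model.

## The problem

TNF-α inhibitors — infliximab, etanercept, adalimumab, golimumab and
certolizumab — are mainstays of pediatric inflammatory bowel disease and
juvenile idiopathic arthritis, yet children are barely represented in
pre-marketing trials. Spontaneous-report databases such as FAERS are the
main source of post-marketing pediatric safety evidence, but analysing
them requires a long chain of unglamorous steps done exactly right:
parsing the quarterly `$`-delimited tables, collapsing duplicate report
versions, restricting to primary-suspect drugs, normalising ages reported
in years/months/weeks/days, filtering out indication terms misreported as
reactions, and only then computing disproportionality statistics.

`faersped` packages that chain for analysts running pediatric safety
surveillance of the TNF-α inhibitor class: ingestion, curation,
signal detection, age-stratified and time-to-onset summaries, an
era-split sensitivity analysis — plus a synthetic FAERS generator with
planted associations of known strength, so that every stage of the
pipeline is testable without downloading the real archives.

## The statistic

Signals are screened with the reporting odds ratio. For a drug–event pair
the curated reports form a fourfold table — `a` target-drug reports with
the event, `b` without, `c`/`d` the same for the comparator universe —
and

```
ROR    = (a·d) / (b·c)
95% CI = exp( ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d) )
χ²     = N·(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))
```

A pair is flagged as a risk signal when it has ≥ 3 reports, lower 95%
CI bound > 1 and χ² > 4 (an optional ROR > 2 criterion is available).
Tables with a zero cell are reported as undefined rather than
continuity-corrected (a Haldane–Anscombe flag exists). The risk-signal
detection ratio (RSR) is the share of a drug's observed preferred terms
that are flagged. No multiple-testing adjustment is applied — the
conventional, deliberately transparent screen of disproportionality
practice; treat flags as hypotheses, not confirmed risks.

## Worked example

```r
library(faersped)

cfg     <- synthetic_config(seed = 42)          # study-scale defaults
bundles <- generate_faers(cfg)                  # FAERS-dialect quarters
pt_soc  <- read_pt_soc(system.file("extdata", "synthetic_pt_soc.tsv",
                                   package = "faersped"))
cohort  <- curate_cohort(bundles, pt_to_soc = pt_soc)
cohort
#> FAERS curated cohort
#>   pediatric reports: 6424
#>   all-age reports:   8568
#>   ...
#>   attrition:
#>     raw_reports                     10999
#>     duplicate_versions                999
#>     deleted_cases                     204
#>     deduplicated                     9796
#>     ps_excluded_pre_approval          881
#>     ...
#>     pediatric                        6424
```

10,999 raw DEMO rows collapse to 9,796 unique cases (999 duplicate
versions, 204 deleted cases); pre-approval golimumab/certolizumab reports
drop out; indication-only and product-issues-only reports are excluded;
6,424 reports are pediatric (< 18 years). The signal scan then recovers
the association the generator planted (infliximab × Clostridium difficile
infection at an expected ROR of 9.85):

```r
signals <- signal_scan(cohort)
signals[drug == "infliximab" & pt == "Clostridium difficile infection",
        .(n, ror, ci_low, ci_high, chi2, is_signal)]
#>      n      ror   ci_low  ci_high     chi2 is_signal
#> 1: 225 9.749163 7.595224 12.51394 450.0201      TRUE

planted_truth(cfg)$expected_ror
#> [1] 9.849498
```

`demographics_table()`, `stratum_compare()`, `onset_by_agent()` and
`era_compare()` produce the stratified, time-to-onset and era-split
summaries; `run_pipeline(cfg, "all", outdir = "out")` writes the full set
of CSV outputs plus a manifest with the attrition chain and content
hashes. A thin command-line wrapper lives at
`inst/scripts/faersped`.

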