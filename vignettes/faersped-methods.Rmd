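---
title: "Methods: pediatric TNF-α inhibitor surveillance with faersped"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pediatric TNF-α inhibitor surveillance with faersped}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersped)
```

## The analysis model

`faersped` implements case/non-case disproportionality analysis over
spontaneous adverse-event reports. The unit of analysis is the
*deduplicated report*: one case identifier, its latest report version,
one primary-suspect (PS) drug mapped to one of the five TNF-α inhibitors,
and a set of MedDRA preferred terms (PTs). For a drug–event question the
curated universe is partitioned into the fourfold table and the reporting
odds ratio computed as

$$\mathrm{ROR} = \frac{a\,d}{b\,c},\qquad
95\%\ \mathrm{CI} = \exp\!\Big(\ln \mathrm{ROR} \pm
1.96\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\Big),$$

with the Pearson $\chi^2$ on the same table. The ROR is a reporting
association measure, not an incidence ratio: it assumes only that, absent
a true reporting association, the odds of a given event are the same for
target and comparator reports. It inherits every bias of spontaneous
reporting (notoriety, channeling, under-reporting), which is why the
package treats flags as screening output.

Two comparator universes are supported, because the choice is a genuine
design fork in class-restricted datasets:

* **within_class** (default for per-agent questions): the curated reports
  of the other four agents. Internal benchmarking against
  pharmacologically similar drugs mitigates confounding by indication,
  at the price of masking class-wide effects.
* **external_background**: a supplied (PT → report count, total) table,
  required for pooled-class questions where no within-class comparator
  exists. The pipeline feeds it with the curated *adult* (≥ 18 y) reports
  of the same agents, so the pediatric class signal is benchmarked
  against adult reporting of the same drugs.

Neither mode is asserted to be "the" correct universe; both are exposed
and the outputs label which was used.

## Curation rules and their rationale

* **Deduplication**: per case identifier keep the most recent FDA receipt
  date, highest report-version id on ties; then remove cases on the
  quarterly deleted-report lists. Partial receipt dates (`YYYY`,
  `YYYYMM`) are compared at their available precision with missing
  components ranked lowest, which makes the order total and the survivor
  deterministic.
* **Primary suspect only**: a report enters the cohort only through a PS
  drug row mapping to exactly one study agent (whole-token synonym match
  after uppercasing and punctuation stripping; ambiguous multi-agent
  names are excluded and logged). Reports received before an agent's
  approval quarter are dropped — golimumab (2009) and certolizumab
  (2008) would otherwise accrue impossible early reports.
* **Age**: FAERS ages arrive in decades/years/months/weeks/days/hours and
  are normalised to years (365.25-day year); ages < 0 or > 120 y are
  implausible and treated as missing. The pediatric filter is strict
  (`age < 18`), and missing ages are excluded rather than imputed.
  Strata are the half-open intervals [0,4), [4,12), [12,18), read off
  the integer stratum labels 0–3 / 4–11 / 12–17 so that the three strata
  partition [0,18) exactly.
* **Indication filtering**: PTs on the agent's indication-exclusion list
  are dropped *per PT*, not per report — the reading that matches
  removing indication terms "from the analysis" while keeping the
  report's genuine reactions. The lists ship as editable data
  (IBD terms for infliximab/adalimumab, JIA-spectrum terms for the
  subcutaneous agents), because approved indications are facts about
  labels, not code. Reports left with no PTs are excluded and tallied.
* **Off-label-only retention**: a report whose only PT is "Off-label use"
  is kept. Golimumab has no pediatric approval, so its pediatric
  exposure is inherently off-label; dropping those reports would delete
  the only exposure evidence for that agent, and the same rule is applied
  to all five agents for comparability.
* **Product-issues-only exclusion**: reports whose remaining PTs all map
  to the Product Issues SOC describe device or administration problems,
  not medicinal adverse events, and leave the disproportionality
  universe.
* **Reporter classes** collapse the raw occupation codes as MD →
  Physician, PH → Pharmacist, {OT, RN, HP} → Other health professional,
  CN → Consumer, everything else (including lawyers) → Unknown/other.

Every exclusion is tallied, and the attrition identity
`raw = retained + Σ exclusions` is enforced by tests, so the flow chart
of a run can be reconstructed from its manifest alone.

## Signal criteria

Defaults: `n ≥ 3`, lower 95% CI > 1, χ² > 4; the stricter `ROR > 2`
screen is available behind a flag but off by default, since the core
criterion set is the conservative conjunction in routine use. Zero-cell
tables are *undefined* — serialised as "/" — rather than silently
continuity-corrected; `haldane = TRUE` opts into the 0.5 correction.
χ² is Pearson without Yates correction by default (a `yates` flag
exists). No multiple-testing adjustment is applied across the thousands
of drug–event pairs; this mirrors standard disproportionality practice
but means the family-wise false-positive rate is uncontrolled, and the
vignette's advice is to read the signal table as a ranked shortlist.

## Time-to-onset and era analyses

Onset is the day difference from the earliest day-precision therapy start
of the PS drug to the day-precision event date; partial dates are
excluded (no imputation), events before therapy start are implausible and
tallied separately. Quartiles use linear interpolation between order
statistics (R's default type 7), stated here because the convention
changes medians on small strata. Onset histograms use 30-day bins to 360
days with an open tail.

The era split partitions reports at receipt quarter 2014Q1 (configurable)
and recomputes per-PT RORs in each era; the top-50 PTs by pooled report
count are paired and compared with a two-sided Wilcoxon signed-rank test.
The test drops zero differences, uses average ranks for ties, enumerates
all $2^n$ sign assignments exactly when $n \le 12$ without ties, and
otherwise applies the normal approximation with tie and continuity
correction — the exact route doubles as the oracle for the approximate
one in the test suite.

## The synthetic generator

The generator emulates the structural hazards of the real archives: the
seven-table quarterly layout with `$` delimiters, duplicate report
versions (same case, later receipt, higher id), deleted-case lists, ages
in mixed units with missingness, an adult share to exercise the pediatric
filter, primary-suspect rows among concomitant distractor drugs, brand
and generic name variants with dose suffixes, indication terms leaking
into the reaction table, off-label-only and product-issues-only reports,
and therapy/event dates with a lognormal onset delay and missing
timelines.

Its statistical core is deliberately minimal: each vocabulary PT enters a
report independently with its baseline probability, and a planted
(agent, PT) pair multiplies the odds by θ. Because sampling is
independent Bernoulli per report, the expected ROR of a planted pair has
the closed form implemented in `planted_truth()` — the baseline odds
ratio θ, shrunk by the off-label-only mixture fraction, since those
reports survive curation but cannot carry other PTs. Two generator
details protect this closed form: reports that would otherwise lose all
PTs to the indication/product-issues filters receive a fallback PT
("Drug ineffective") instead of being excluded, and the forced special
report types are drawn independently of agent, so curation thins all
arms equally. Consequently, do not plant associations on the fallback PT.

Defaults were fixed once as the study conditions: 2,000 reports per agent
over 2004Q1–2024Q3; stratum weights 0.071/0.241/0.688 matching the
marginal pediatric age distribution of TNF-inhibitor reports; 10%
duplicate versions; 2% deleted; 5% missing age; 20% adults; 8%
off-label-only; 25% missing event timelines; one planted pair,
infliximab × Clostridium difficile infection at θ = 10 (the headline
infliximab association, and an agent unaffected by approval-quarter
thinning). The validation studies in the test suite and acceptance
script use 200 replicates for CI coverage of the planted truth and 60
replicates for null calibration — sizes chosen to estimate a ~95%
coverage and a <5% flag rate with adequate precision.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: correlated PTs within a report (real
reports cluster clinically), secular trends in reporting volume and
vocabulary, agent-specific age and outcome profiles, MedDRA version
drift, free-text drug-name noise beyond dose suffixes, and real
marginal PT frequencies. Results on synthetic archives validate the
*machinery*, not the clinical conclusions one would draw from FAERS
itself.

## Numerical and degenerate-input choices

* Percentages round half away from zero (one decimal in demographic
  tables, two in quoted shares), matching how published report tables
  round; base R's round-half-to-even would disagree on exact halves.
* Report ids are compared numerically when both are digit strings,
  lexicographically otherwise.
* Empty inputs return empty, typed outputs (empty cohort → all-zero
  demographics table; no onset values → `n = 0` summary) rather than
  errors.
* Ranking tiebreaks (signal prioritisation, top-PT lists) fall back to
  the alphabetical PT name so every ordering is deterministic.
* All randomness flows through the single seed recorded in the run
  manifest; re-running a configuration reproduces outputs byte for byte.

## Known limitations

The package screens reporting disproportionality; it cannot estimate
incidence (no denominators), establish causality, or correct reporting
biases. The comparator-universe question for class-level statistics has
no canonical answer within a single-class dataset — the adult-background
default is one defensible choice, and conclusions sensitive to it should
be checked under the alternative. Indication-exclusion lists are
necessarily incomplete data and their per-PT semantics (rather than
whole-report exclusion) is a documented interpretation. Partial-date
handling in deduplication (missing components lowest) is a convention,
not a FAERS specification.
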