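Package: faersped
Title: Pediatric Pharmacovigilance Signal Detection from FAERS Quarterly Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-marketing safety surveillance of TNF-alpha
    inhibitors (infliximab, etanercept, adalimumab, golimumab, certolizumab)
    in children using FAERS-style quarterly report tables. Parses the
    '$'-delimited DEMO/DRUG/REAC/OUTC/THER/INDI/RPSR layout together with
    deleted-case lists, deduplicates reports by case identifier and FDA
    receipt date, curates a pediatric primary-suspect cohort with age-unit
    normalisation and indication/product-issue filtering, and screens
    drug-event pairs by reporting odds ratio (ROR) with Woolf 95% confidence
    intervals and Pearson chi-square signal criteria. Includes age-stratified
    and system-organ-class summaries, time-to-onset analysis, an era-split
    sensitivity analysis with a paired Wilcoxon signed-rank test, and a
    synthetic FAERS generator with planted drug-event associations of known
    reporting odds ratio for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
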