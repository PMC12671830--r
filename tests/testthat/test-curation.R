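test_that("deduplication keeps the latest receipt, highest primaryid on ties, and honours the deleted list", {
  demo <- data.table::data.table(
    primaryid = c("P1", "P2"), caseid = c("C1", "C1"),
    fda_dt = c("20100101", "20110101"))
  expect_identical(deduplicate(demo), "P2")
  demo2 <- data.table::data.table(
    primaryid = c("3", "9"), caseid = c("C1", "C1"),
    fda_dt = c("20110101", "20110101"))
  expect_identical(deduplicate(demo2), "9")
  # numeric, not lexicographic, id comparison when ids are digits
  demo3 <- data.table::data.table(
    primaryid = c("10", "9"), caseid = c("C1", "C1"),
    fda_dt = c("20110101", "20110101"))
  expect_identical(deduplicate(demo3), "10")
  expect_identical(deduplicate(demo2, deleted = "C1"), character(0))
  expect_identical(deduplicate(demo2[0]), character(0))
})

test_that("deduplication is idempotent and multiset-stable", {
  set.seed(5)
  demo <- data.table::data.table(
    primaryid = as.character(sample(1000:9999, 60)),
    caseid = as.character(sample(1:20, 60, replace = TRUE)),
    fda_dt = format(as.Date("2010-01-01") + sample(0:2000, 60, TRUE),
                    "%Y%m%d"))
  once <- deduplicate(demo)
  expect_identical(deduplicate(demo[primaryid %in% once]), once)
  # duplicating every input row changes nothing
  expect_identical(deduplicate(rbind(demo, demo)), once)
  # shuffling rows changes nothing
  expect_identical(deduplicate(demo[sample(.N)]), once)
  # exactly one survivor per caseid
  expect_identical(length(once), data.table::uniqueN(demo$caseid))
})

test_that("partial receipt dates compare at available precision, missing lowest", {
  demo <- data.table::data.table(
    primaryid = c("1", "2"), caseid = c("C", "C"),
    fda_dt = c("2011", "20110101"))
  expect_identical(deduplicate(demo), "2")  # year-only sorts below Jan 1
  demo2 <- data.table::data.table(
    primaryid = c("5", "2"), caseid = c("C", "C"),
    fda_dt = c("", "20110101"))
  expect_identical(deduplicate(demo2), "2")
})

test_that("age unit conversion matches the stated factors", {
  expect_equal(to_years(6, "MON"), 0.5)
  expect_equal(to_years(17, "YR"), 17)
  expect_equal(to_years(730.5, "DY"), 2)
  expect_equal(to_years(1.5, "DEC"), 15)
  expect_equal(to_years(52.178571, "WK"), 1, tolerance = 1e-6)
  expect_equal(to_years(8766, "HR"), 1)
  expect_true(is.na(to_years(-5, "YR")))
  expect_true(is.na(to_years("x", "YR")))
  expect_true(is.na(to_years(5, "??")))
})

test_that("pediatric selection is strict at 18 and tallies exclusions", {
  keep <- select_pediatric(c(17.99, 18, NA, -1, 130, 0))
  expect_identical(as.logical(keep), c(TRUE, FALSE, FALSE, FALSE, FALSE,
                                       TRUE))
  tal <- attr(keep, "tally")
  expect_identical(tal[["retained"]], 2L)
  expect_identical(tal[["missing"]], 1L)
  expect_identical(tal[["implausible"]], 2L)
  expect_identical(tal[["adult"]], 1L)
})

test_that("stratum assignment partitions [0, 18) with half-open bounds", {
  expect_identical(as.character(assign_stratum(c(3.9, 4, 11.99, 12, 17.9))),
                   c("0-3", "4-11", "4-11", "12-17", "12-17"))
  ages <- seq(0, 17.995, by = 0.005)
  s <- assign_stratum(ages)
  expect_false(anyNA(s))          # exhaustive
  expect_identical(nlevels(s), 3L) # disjoint by construction of cut()
  expect_error(assign_stratum(18), "\\[0, 18\\)")
})

test_that("drug mapping normalises names and resolves whole-token synonyms", {
  expect_identical(unname(map_drug("HUMIRA")[1]), "adalimumab")
  expect_identical(unname(map_drug("REMICADE 100MG")[1]), "infliximab")
  expect_identical(unname(map_drug("remicade.")[1]), "infliximab")
  expect_true(is.na(map_drug("ASPIRIN")[1]))
  expect_true(is.na(map_drug("REMICADEX")[1]))   # no substring matches
  amb <- map_drug("REMICADE AND HUMIRA")
  expect_true(is.na(amb[1]))
  expect_identical(attr(amb, "ambiguous"), "REMICADE AND HUMIRA")
})

test_that("primary-suspect restriction records the PS agent and drops pre-approval reports", {
  demo <- data.table::data.table(
    primaryid = c("1", "2", "3"),
    fda_dt = c("20100101", "20100101", "20081001"))
  drug <- data.table::data.table(
    primaryid = c("1", "1", "2", "2", "3"),
    role_cod = c("PS", "SS", "PS", "C", "PS"),
    drugname = c("ENBREL", "HUMIRA", "ASPIRIN", "REMICADE", "SIMPONI"),
    prod_ai = "")
  out <- restrict_primary_suspect(demo, drug)
  expect_identical(out$primaryid, "1")
  expect_identical(out$agent, "etanercept")
  tal <- attr(out, "tally")
  expect_identical(tal[["no_ps_target"]], 1L)   # report 2: PS not a target
  expect_identical(tal[["pre_approval"]], 1L)   # report 3: Simponi 2008Q4
})

test_that("PT filters drop indication terms, exclude product-issues-only, keep off-label-only", {
  cfg <- curation_config()
  ptsoc <- fixture_pt_soc()
  r <- apply_pt_filters(c("Crohn's disease", "Pyrexia"), "infliximab",
                        cfg, ptsoc)
  expect_true(r$keep)
  expect_identical(r$pts, "Pyrexia")
  r2 <- apply_pt_filters("Device leakage", "infliximab", cfg, ptsoc)
  expect_false(r2$keep)
  expect_identical(r2$reason, "product_issues_only")
  r3 <- apply_pt_filters("Off-label use", "golimumab", cfg, ptsoc)
  expect_true(r3$keep)
  r4 <- apply_pt_filters("Crohn's disease", "infliximab", cfg, ptsoc)
  expect_false(r4$keep)
  expect_identical(r4$reason, "all_indication")
  cfg_off <- curation_config(offlabel_retention = FALSE)
  expect_false(apply_pt_filters("Off-label use", "golimumab", cfg_off,
                                ptsoc)$keep)
})

test_that("reporter occupation codes collapse to report-table categories", {
  demo <- fixture_tables()$demo
  expect_identical(faersped:::reporter_class_of(c("MD", "PH", "OT", "RN",
                                                  "HP", "CN", "LW", "")),
                   c("Physician", "Pharmacist", "Other health professional",
                     "Other health professional",
                     "Other health professional", "Consumer",
                     "Unknown/other", "Unknown/other"))
})

test_that("cohort curation conserves the attrition chain on synthetic data", {
  cfg <- small_config(seed = 9)
  bundles <- generate_faers(cfg)
  coh <- curate_cohort(bundles, pt_to_soc = fixture_pt_soc())
  at <- coh$attrition
  expect_identical(at[["raw_reports"]],
                   at[["duplicate_versions"]] + at[["deleted_cases"]] +
                     at[["deduplicated"]])
  expect_identical(at[["deduplicated"]],
                   at[["ps_restricted"]] + at[["ps_excluded_no_target"]] +
                     at[["ps_excluded_ambiguous"]] +
                     at[["ps_excluded_pre_approval"]])
  expect_identical(at[["ps_restricted"]],
                   at[["post_pt_filter"]] + at[["excluded_no_reactions"]] +
                     at[["excluded_all_indication"]] +
                     at[["excluded_product_issues_only"]] +
                     at[["excluded_offlabel_only"]])
  expect_identical(at[["post_pt_filter"]],
                   at[["pediatric"]] + at[["excluded_age_missing"]] +
                     at[["excluded_adult"]])
  # every pediatric case is strictly under 18 with a stratum
  expect_true(all(coh$cases$age_years < 18))
  expect_false(anyNA(coh$cases$stratum))
  # indication PTs never survive the per-PT filter
  for (ag in names(coh$config$indication_exclusion)) {
    sub <- coh$cases[agent == ag]
    expect_false(any(unlist(sub$pts) %in%
                       coh$config$indication_exclusion[[ag]]))
  }
})
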