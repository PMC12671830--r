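test_that("generation is byte-identical for a fixed config and seed", {
  cfg <- small_config(seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_faers(generate_faers(cfg), d1)
  write_faers(generate_faers(cfg), d2)
  f1 <- list.files(d1)
  expect_identical(f1, list.files(d2))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # a different seed changes the output
  d3 <- withr::local_tempdir()
  write_faers(generate_faers(cfg, seed = 78), d3)
  expect_false(identical(readLines(file.path(d1, f1[1])),
                         readLines(file.path(d3, f1[1]))))
})

test_that("duplicate versions inflate DEMO but dedup recovers every case once", {
  cfg <- small_config(seed = 13, duplicate_fraction = 0.5,
                      deleted_fraction = 0)
  bundles <- generate_faers(cfg)
  demo <- data.table::rbindlist(lapply(bundles,
                                       function(b) b$tables$demo))
  n <- as.integer(sum(cfg$n_cases))
  expect_gt(nrow(demo), n * 1.4)
  expect_lt(nrow(demo), n * 1.6)
  survivors <- deduplicate(demo)
  expect_identical(length(survivors), n)
  # the survivor of a duplicated case is the later, higher-id version
  truth <- attr(bundles, "truth")$cases
  dup_case <- truth[duplicated == TRUE]$caseid[1]
  expect_true(paste0(dup_case, "2") %in% survivors)
})

test_that("deleted cases are listed and excluded by deduplication", {
  cfg <- small_config(seed = 14, deleted_fraction = 0.1)
  bundles <- generate_faers(cfg)
  truth <- attr(bundles, "truth")$cases
  listed <- unlist(lapply(bundles, `[[`, "deleted_caseids"))
  expect_setequal(listed, truth[deleted == TRUE]$caseid)
  demo <- data.table::rbindlist(lapply(bundles,
                                       function(b) b$tables$demo))
  survivors <- deduplicate(demo, listed)
  expect_identical(length(survivors), sum(!truth$deleted))
})

test_that("off-label-only reports occur at the configured rate and survive curation", {
  cfg <- small_config(seed = 15, offlabel_only_fraction = 0.1)
  bundles <- generate_faers(cfg)
  truth <- attr(bundles, "truth")$cases
  n <- nrow(truth)
  n_off <- sum(truth$rtype == "offlabel_only")
  expect_lt(abs(n_off - 0.1 * n), 4 * sqrt(n * 0.1 * 0.9))
  coh <- curate_cohort(bundles, pt_to_soc = fixture_pt_soc())
  only_off <- vapply(coh$cases$pts,
                     function(p) identical(p, "Off-label use"), TRUE)
  expect_gt(sum(only_off), 0)
})

test_that("planted-truth expected RORs follow the odds-multiplier algebra", {
  # theta = 1 everywhere: expected ROR 1
  cfg_null <- small_config(
    seed = 1, offlabel_only_fraction = 0,
    planted = data.frame(agent = "etanercept", pt = "Pyrexia", theta = 1))
  expect_equal(planted_truth(cfg_null)$expected_ror, 1)
  # baseline 0.1 shifted to p_t = 0.5 is an odds multiplier of 9
  vocab <- synthetic_vocabulary()
  vocab[vocab$pt == "Headache", "baseline_prob"] <- 0.1
  cfg9 <- small_config(
    seed = 1, vocabulary = vocab, offlabel_only_fraction = 0,
    planted = data.frame(agent = "adalimumab", pt = "Headache", theta = 9))
  tr <- planted_truth(cfg9)
  expect_equal(tr$p_target, 0.5)
  expect_equal(tr$expected_ror, 9)
  # the off-label-only mixture shrinks both arms' probabilities
  cfg_mix <- small_config(
    seed = 1, offlabel_only_fraction = 0.2,
    planted = data.frame(agent = "adalimumab", pt = "Headache", theta = 5))
  tr_mix <- planted_truth(cfg_mix)
  pi_n <- 1 - 0.2 - cfg_mix$indication_only_fraction -
    cfg_mix$product_issue_only_fraction
  expect_equal(tr_mix$p_comparator, 0.06 * pi_n / (pi_n + 0.2))
})

test_that("ages are emitted in mixed units and recover the intended years", {
  cfg <- small_config(seed = 16, missing_age_fraction = 0)
  bundles <- generate_faers(cfg)
  truth <- attr(bundles, "truth")$cases
  expect_setequal(unique(truth$age_cod), c("YR", "MON", "WK", "DY"))
  got <- to_years(truth$age, truth$age_cod)
  expect_equal(got, truth$age_years_true, tolerance = 0.01)
})

test_that("generated quarters carry consistent identifiers", {
  cfg <- small_config(seed = 17)
  bundles <- generate_faers(cfg)
  for (b in bundles[1:5]) {
    expect_match(b$quarter_id, "^[0-9]{4}Q[1-4]$")
    demo <- b$tables$demo
    pd <- parse_date(demo$fda_dt)
    expect_true(all(quarter_of(pd$year, pd$month) == b$quarter_id))
    # every non-DEMO row points at a DEMO report of the same bundle
    for (tb in c("drug", "reac", "outc", "ther", "indi")) {
      expect_true(all(b$tables[[tb]]$primaryid %in% demo$primaryid))
    }
  }
})
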