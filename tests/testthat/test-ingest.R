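test_that("a fixture quarter is parsed with the exact row counts", {
  dir <- withr::local_tempdir()
  write_fixture_quarter(dir)
  q <- read_quarter(dir, "2010Q2")
  expect_s3_class(q, "faers_quarter")
  expect_identical(nrow(q$tables$demo), 3L)
  expect_identical(nrow(q$tables$drug), 4L)
  expect_identical(nrow(q$tables$reac), 5L)
  expect_identical(nrow(q$tables$outc), 2L)
  expect_identical(q$deleted_caseids, character(0))
})

test_that("rows violating enumerated domains are excluded and logged", {
  dir <- withr::local_tempdir()
  tabs <- fixture_tables()
  tabs$drug <- rbind(tabs$drug, data.table::data.table(
    primaryid = "1001", caseid = "100", drug_seq = "3", role_cod = "XX",
    drugname = "SOMETHING", prod_ai = ""))
  write_fixture_quarter(dir, tables = tabs)
  q <- read_quarter(dir, "2010Q2")
  expect_identical(nrow(q$tables$drug), 4L)
  expect_true(any(grepl("invalid role_cod", q$log$messages)))
})

test_that("malformed lines are skipped and reported with line numbers", {
  dir <- withr::local_tempdir()
  write_fixture_quarter(dir)
  f <- file.path(dir, "DEMO10Q2.txt")
  cat("too$few$fields\n", file = f, append = TRUE)
  q <- read_quarter(dir, "2010Q2")
  expect_identical(nrow(q$tables$demo), 3L)
  expect_identical(q$log$malformed$demo, 5L)  # header + 3 rows + bad line
})

test_that("missing required tables are fatal; optional ones default empty", {
  dir <- withr::local_tempdir()
  write_fixture_quarter(dir)
  file.remove(file.path(dir, "OUTC10Q2.txt"))
  q <- read_quarter(dir, "2010Q2")
  expect_identical(nrow(q$tables$outc), 0L)
  file.remove(file.path(dir, "REAC10Q2.txt"))
  expect_error(read_quarter(dir, "2010Q2"), "REAC")
})

test_that("orphan rows are flagged at parse, not dropped", {
  dir <- withr::local_tempdir()
  tabs <- fixture_tables()
  tabs$reac <- rbind(tabs$reac, data.table::data.table(
    primaryid = "9999", caseid = "999", pt = "Pyrexia"))
  write_fixture_quarter(dir, tables = tabs)
  q <- read_quarter(dir, "2010Q2")
  expect_identical(nrow(q$tables$reac), 6L)
  expect_identical(sum(q$tables$reac$orphan), 1L)
})

test_that("LAERS-era column aliases are mapped", {
  dir <- withr::local_tempdir()
  tabs <- fixture_tables()
  data.table::setnames(tabs$demo, c("primaryid", "caseid", "sex"),
                       c("ISR", "CASE", "GNDR_COD"))
  write_fixture_quarter(dir, tables = tabs)
  q <- read_quarter(dir, "2010Q2")
  expect_true(all(c("primaryid", "caseid", "sex") %in%
                    names(q$tables$demo)))
  expect_identical(q$tables$demo$primaryid, c("1001", "2001", "3001"))
})

test_that("deleted-case lists attach to the bundle; empty file gives empty set", {
  dir <- withr::local_tempdir()
  write_fixture_quarter(dir, deleted = c("200", "300"))
  q <- read_quarter(dir, "2010Q2")
  expect_setequal(q$deleted_caseids, c("200", "300"))
  dir2 <- withr::local_tempdir()
  write_fixture_quarter(dir2, deleted = character(0))
  expect_identical(read_quarter(dir2, "2010Q2")$deleted_caseids,
                   character(0))
})

test_that("write/read round-trip preserves record multisets", {
  dir <- withr::local_tempdir()
  cfg <- small_config(seed = 42)
  bundles <- generate_faers(cfg)
  write_faers(bundles, dir)
  back <- read_quarters(dir)
  expect_identical(length(back), length(bundles))
  sort_tab <- function(tab) {
    tab <- data.table::as.data.table(tab)
    if ("orphan" %in% names(tab)) tab[, orphan := NULL]
    data.table::setorderv(tab, names(tab))[]
  }
  for (k in seq_along(bundles)) {
    expect_identical(back[[k]]$quarter_id, bundles[[k]]$quarter_id)
    for (tb in names(bundles[[k]]$tables)) {
      expect_equal(sort_tab(back[[k]]$tables[[tb]]),
                   sort_tab(bundles[[k]]$tables[[tb]]),
                   ignore_attr = TRUE)
    }
    expect_identical(back[[k]]$deleted_caseids,
                     bundles[[k]]$deleted_caseids)
  }
})

test_that("parsing is insensitive to input row order", {
  dir <- withr::local_tempdir()
  write_fixture_quarter(dir)
  f <- file.path(dir, "REAC10Q2.txt")
  lines <- readLines(f)
  set.seed(1)
  writeLines(c(lines[1], sample(lines[-1])), f)
  q <- read_quarter(dir, "2010Q2")
  got <- sort(paste(q$tables$reac$primaryid, q$tables$reac$pt))
  want <- sort(paste(fixture_tables()$reac$primaryid,
                     fixture_tables()$reac$pt))
  expect_identical(got, want)
})

test_that("partial and impossible dates parse with correct precision", {
  pd <- parse_date(c("20100401", "201004", "2010", "", "20101340",
                     "20100229", "20120229", "abc"))
  expect_identical(pd$precision,
                   c("day", "month", "year", NA, NA, NA, "day", NA))
  expect_identical(pd$date[1], as.Date("2010-04-01"))
  expect_identical(pd$date[7], as.Date("2012-02-29"))
  expect_identical(attr(pd, "n_invalid"), 3L)
  # missing components sort lowest: YYYY < YYYY-01-01
  expect_lt(pd$key[3], parse_date("20100101")$key)
})
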