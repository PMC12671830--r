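# independent, literal transcription of the printed formulas, kept apart
# from the vectorised implementation it checks
oracle_ror <- function(a, b, c, d) {
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror, lo = exp(log(ror) - 1.96 * se),
       hi = exp(log(ror) + 1.96 * se))
}
oracle_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

test_that("fourfold tables count at the report level", {
  cases <- data.table::data.table(
    primaryid = as.character(1:8),
    agent = c(rep("X", 3), rep("Y", 5)),
    pts = list(c("q", "r"), "q", "r", "q", "r", "r", "s", "s"))
  tab <- build_table(cases, "X", "q")
  expect_identical(unclass(tab)[c("a", "b", "c", "d")],
                   list(a = 2L, b = 1L, c = 1L, d = 4L))
  # duplicate PT on one report counts once
  cases$pts[[1]] <- c("q", "q", "r")
  tab2 <- build_table(cases, "X", "q")
  expect_identical(tab2$a, 2L)
  # class-level question has no within-class comparator
  expect_error(build_table(cases, "class", "q"), "comparator")
  # external background supplies the comparator counts
  bg <- list(pt_counts = c(q = 10), total = 100)
  tab3 <- build_table(cases, "class", "q", "external_background", bg)
  expect_identical(unclass(tab3)[c("a", "b", "c", "d")],
                   list(a = 3L, b = 5L, c = 10, d = 90))
})

test_that("ROR and CI reproduce hand-computed values and mark zero cells", {
  r <- ror_ci(5, 5, 5, 5)
  expect_equal(r$ror, 1)
  expect_true(r$ci_low < 1 && r$ci_high > 1)
  r2 <- ror_ci(10, 90, 10, 900)
  expect_equal(r2$ror, 10)
  expect_equal(r2$ci_low, 4.054, tolerance = 1e-3)
  expect_equal(r2$ci_high, 24.67, tolerance = 1e-3)
  r3 <- ror_ci(0, 10, 5, 100)
  expect_true(is.na(r3$ror))
  expect_identical(r3$undefined_reason, "zero cell")
  # optional continuity correction defines the zero-cell case
  r4 <- ror_ci(0, 10, 5, 100, haldane = TRUE)
  expect_false(is.na(r4$ror))
  expect_equal(r4$ror, (0.5 * 100.5) / (10.5 * 5.5))
})

test_that("chi-square matches the closed form and stats::chisq.test", {
  expect_equal(chi_square(5, 5, 5, 5), 0)
  expect_equal(chi_square(10, 90, 10, 900), 36.778, tolerance = 1e-3)
  # symmetry under swapping rows and columns
  expect_equal(chi_square(10, 90, 10, 900), chi_square(10, 10, 90, 900))
  ref <- suppressWarnings(stats::chisq.test(
    matrix(c(3, 7, 11, 5), 2, byrow = TRUE), correct = FALSE))
  expect_equal(chi_square(3, 7, 11, 5), unname(ref$statistic))
  ref_y <- suppressWarnings(stats::chisq.test(
    matrix(c(3, 7, 11, 5), 2, byrow = TRUE), correct = TRUE))
  expect_equal(chi_square(3, 7, 11, 5, yates = TRUE),
               unname(ref_y$statistic))
  expect_true(is.na(chi_square(0, 0, 5, 5)))
})

test_that("formula identities hold on random tables", {
  set.seed(101)
  for (i in 1:200) {
    t <- as.list(sample(1:50, 4, replace = TRUE))
    names(t) <- c("a", "b", "c", "d")
    r <- ror_ci(t$a, t$b, t$c, t$d)
    # reciprocity: swapping target and comparator inverts the ROR
    r_swap <- ror_ci(t$c, t$d, t$a, t$b)
    expect_equal(r$ror * r_swap$ror, 1, tolerance = 1e-12)
    # exact log-symmetry of the CI around the estimate
    expect_equal(log(r$ci_high) - log(r$ror), log(r$ror) - log(r$ci_low),
                 tolerance = 1e-12)
    # agreement with the literal formulas
    o <- oracle_ror(t$a, t$b, t$c, t$d)
    expect_equal(r$ror, o$ror, tolerance = 1e-12)
    expect_equal(r$ci_low, o$lo, tolerance = 1e-12)
    expect_equal(chi_square(t$a, t$b, t$c, t$d),
                 oracle_chi2(t$a, t$b, t$c, t$d), tolerance = 1e-12)
  }
  # monotonicity: increasing a with b, c, d fixed increases the ROR
  rors <- ror_ci(1:20, 50, 10, 500)$ror
  expect_true(all(diff(rors) > 0))
})

test_that("signal criteria combine as stated and tightening never adds signals", {
  crit <- signal_criteria()
  expect_true(classify_signal(3134, 10.09, 9.66, 500, crit))
  expect_false(classify_signal(2, 50, 5, 100, crit))     # min-cases rule
  expect_false(classify_signal(100, 1.5, 0.99, 10, crit)) # CI rule
  expect_false(classify_signal(100, NA, NA, NA, crit))    # undefined
  set.seed(7)
  n <- sample(1:10, 50, replace = TRUE)
  ror <- exp(stats::rnorm(50))
  ci_low <- ror * exp(-abs(stats::rnorm(50)))
  chi2 <- stats::rchisq(50, 1)
  base <- classify_signal(n, ror, ci_low, chi2, crit)
  for (tighter in list(signal_criteria(min_cases = 5),
                       signal_criteria(require_chi2_gt = 6),
                       signal_criteria(require_ror_gt = 2))) {
    expect_true(all(classify_signal(n, ror, ci_low, chi2, tighter) <= base))
  }
})

test_that("risk-signal detection ratio is the stated percentage", {
  expect_equal(rsr(852, 4520), 18.85)
  expect_equal(rsr(0, 100), 0)
  expect_equal(rsr(2944, 14002), 21.03)
  expect_true(is.na(rsr(5, 0)))
})

test_that("signal prioritisation sorts by volume, recurrence, then name", {
  sig <- data.table::data.table(
    pt = c("b", "a", "c", "c", "a", "b"),
    drug = rep(c("X", "Y"), each = 3),
    n = c(5, 10, 4, 4, 10, 5),
    is_signal = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  ranked <- prioritize(sig)
  expect_identical(ranked$pt, c("a", "b", "c"))
  expect_identical(ranked$n_total, c(20, 10, 8))
  # equal volume: more flagging agents first
  sig2 <- data.table::data.table(
    pt = c("p", "p", "q", "q"), drug = c("X", "Y", "X", "Y"),
    n = c(5, 5, 5, 5), is_signal = c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(prioritize(sig2)$pt, c("p", "q"))
})

test_that("the pooled scan matches per-pair tables and flags the planted pair", {
  cfg <- small_config(seed = 21)
  bundles <- generate_faers(cfg)
  coh <- curate_cohort(bundles, pt_to_soc = fixture_pt_soc())
  s <- signal_scan(coh)
  row <- s[drug == "infliximab" & pt == "Clostridium difficile infection"]
  tab <- build_table(coh$cases, "infliximab",
                     "Clostridium difficile infection")
  expect_identical(row$n, tab$a)
  expect_equal(row$ror, ror_ci(tab)$ror)
  expect_true(row$is_signal)
  # undefined rows are serialised as "/"
  f <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(s, f)
  out <- data.table::fread(f, colClasses = "character")
  if (any(is.na(s$ror))) expect_true("/" %in% out$ror)
})
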