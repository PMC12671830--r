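
#' Split a cohort into reporting eras
#'
#' Partitions reports by FDA receipt quarter into an early and a recent
#' phase (default cut: quarters before 2014Q1 are early). The partition is
#' exhaustive and disjoint over reports with a parseable receipt year.
#'
#' @param cases cases table with a \code{quarter} column.
#' @param cutoff_quarter first quarter of the recent era (default
#'   \code{"2014Q1"}).
#' @return list \code{(early, recent)} of cases tables.
#' @export
split_eras <- function(cases, cutoff_quarter = "2014Q1") {
  cases <- data.table::as.data.table(cases)
  qi <- quarter_index(cases$quarter)
  cut <- quarter_index(cutoff_quarter)
  list(early = cases[!is.na(qi) & qi < cut],
       recent = cases[!is.na(qi) & qi >= cut])
}

# exact two-sided p for the signed-rank statistic by enumeration of all
# 2^n sign assignments (used for n <= 12 without ties)
wilcoxon_exact_p <- function(w_obs, ranks) {
  n <- length(ranks)
  sums <- 0
  for (r in ranks) sums <- c(sums, sums + r)  # distribution of W over subsets
  total <- 2^n
  # two-sided: double the smaller tail around the mean n(n+1)/4
  mu <- sum(ranks) / 2
  lo <- sum(sums <= min(w_obs, 2 * mu - w_obs)) / total
  hi <- sum(sums >= max(w_obs, 2 * mu - w_obs)) / total
  min(1, lo + hi)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired observations. Zero differences
#' are dropped; tied absolute differences receive average ranks. For
#' n <= 12 surviving pairs without ties the p-value is computed by exact
#' enumeration of all sign assignments; otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with \code{W} (sum of positive ranks), \code{Z}
#'   (normal-approximation deviate, with sign of W - E[W]), \code{p}
#'   (two-sided), \code{median_diff} (median of x - y over all pairs),
#'   \code{n} (pairs used) and \code{method}.
#' @export
#' @examples
#' paired_wilcoxon(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1)) # p = 2/64
paired_wilcoxon <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  median_diff <- stats::median(d)
  dz <- d[d != 0]
  n <- length(dz)
  if (n == 0L) {
    return(list(W = 0, Z = 0, p = 1, median_diff = median_diff, n = 0L,
                method = "degenerate (all differences zero)"))
  }
  r <- rank(abs(dz))
  W <- sum(r[dz > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / 48
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_term)
  has_ties <- any(duplicated(abs(dz)))
  if (n <= 12L && !has_ties) {
    p <- wilcoxon_exact_p(W, r)
    Z <- if (sigma > 0) (W - mu) / sigma else 0
    method <- "exact enumeration"
  } else {
    cc <- 0.5 * sign(W - mu)
    Z <- if (sigma > 0) (W - mu - cc) / sigma else 0
    p <- min(1, 2 * stats::pnorm(-abs(Z)))
    method <- "normal approximation (tie + continuity correction)"
  }
  list(W = W, Z = Z, p = p, median_diff = median_diff, n = n,
       method = method)
}

#' Era-split sensitivity analysis of PT-level RORs
#'
#' Recomputes per-PT RORs separately for the early and recent reporting
#' eras and compares them as paired observations over the most frequently
#' reported PTs (pooled-era report counts; ties broken alphabetically),
#' with a two-sided paired Wilcoxon signed-rank test. Assesses whether
#' longer market exposure in the early era materially shifts the signal
#' ranking.
#'
#' @param cohort a \code{faers_cohort}.
#' @param drug agent name or \code{"class"}.
#' @param comparator_mode as in [build_table()]; for \code{"class"} use
#'   \code{"external_background"}.
#' @param background_early,background_recent background count objects per
#'   era (external mode only). When \code{drug = "class"} and none are
#'   given, the cohort's curated adult reports (per era) are used.
#' @param top_n number of PTs to pair (default 50).
#' @param cutoff_quarter era cut (default \code{"2014Q1"}).
#' @return list with \code{table} (pt, n and ROR/CI per era, delta,
#'   ci_overlap) and \code{wilcoxon} (the [paired_wilcoxon()] result over
#'   PTs with both RORs defined).
#' @export
era_compare <- function(cohort, drug = "class",
                        comparator_mode = c("external_background",
                                            "within_class"),
                        background_early = NULL, background_recent = NULL,
                        top_n = 50L, cutoff_quarter = "2014Q1") {
  comparator_mode <- match.arg(comparator_mode)
  eras <- split_eras(cohort$cases, cutoff_quarter)
  if (comparator_mode == "external_background" &&
      is.null(background_early)) {
    adults <- split_eras(cohort$all_cases[is.na(age_years) |
                                            age_years >= 18],
                         cutoff_quarter)
    background_early <- background_from_cases(adults$early)
    background_recent <- background_from_cases(adults$recent)
  }
  target <- function(cases) {
    if (identical(drug, "class")) cases else cases[agent == drug]
  }
  pooled <- data.table::rbindlist(lapply(eras, target))
  pt_counts <- sort(table(unlist(lapply(pooled$pts, unique))),
                    decreasing = TRUE)
  ord <- order(-as.numeric(pt_counts), names(pt_counts))
  top_pts <- names(pt_counts)[ord][seq_len(min(top_n, length(pt_counts)))]

  scan_era <- function(cases, background) {
    sub <- cohort
    sub$cases <- cases
    signal_scan(sub, drugs = drug, comparator_mode = comparator_mode,
                background = background)
  }
  s_early <- scan_era(eras$early, background_early)
  s_recent <- scan_era(eras$recent, background_recent)
  tab <- data.table::data.table(pt = top_pts)
  me <- match(top_pts, s_early$pt)
  mr <- match(top_pts, s_recent$pt)
  tab[, `:=`(n_early = s_early$n[me], ror_early = s_early$ror[me],
             ci_low_early = s_early$ci_low[me],
             ci_high_early = s_early$ci_high[me],
             n_recent = s_recent$n[mr], ror_recent = s_recent$ror[mr],
             ci_low_recent = s_recent$ci_low[mr],
             ci_high_recent = s_recent$ci_high[mr])]
  tab[, delta := ror_early - ror_recent]
  tab[, ci_overlap := !is.na(ci_low_early) & !is.na(ci_low_recent) &
        ci_low_early <= ci_high_recent & ci_low_recent <= ci_high_early]
  ok <- !is.na(tab$ror_early) & !is.na(tab$ror_recent)
  wil <- if (sum(ok) >= 2L) {
    paired_wilcoxon(tab$ror_early[ok], tab$ror_recent[ok])
  } else {
    list(W = NA_real_, Z = NA_real_, p = NA_real_,
         median_diff = NA_real_, n = sum(ok), method = "insufficient pairs")
  }
  list(table = tab[], wilcoxon = wil)
}
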