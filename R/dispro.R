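
#' Signal criteria
#'
#' A drug-event pair is flagged as a risk signal when all enabled criteria
#' hold: at least \code{min_cases} reports, lower 95% CI bound above 1,
#' Pearson chi-square above \code{require_chi2_gt}, and optionally ROR
#' above \code{require_ror_gt}. The defaults (n >= 3, CI_low > 1,
#' chi-square > 4, no ROR threshold) are the conventional conservative
#' screen; pairs with an undefined ROR (zero cell) are never signals.
#'
#' @param min_cases minimum report count (default 3).
#' @param require_ci_low_gt_1 require lower CI bound > 1 (default TRUE).
#' @param require_chi2_gt chi-square threshold, or \code{NA} to disable
#'   (default 4).
#' @param require_ror_gt ROR threshold, or \code{NA} to disable (default
#'   \code{NA}; set 2 for the stricter screen).
#' @return a \code{signal_criteria} list.
#' @export
signal_criteria <- function(min_cases = 3, require_ci_low_gt_1 = TRUE,
                            require_chi2_gt = 4, require_ror_gt = NA_real_) {
  structure(list(min_cases = min_cases,
                 require_ci_low_gt_1 = isTRUE(require_ci_low_gt_1),
                 require_chi2_gt = require_chi2_gt,
                 require_ror_gt = require_ror_gt),
            class = "signal_criteria")
}

#' Build the fourfold contingency table for one drug-event question
#'
#' Counts at the report level (a report with the PT counts once however
#' often the PT is listed): \code{a} target-drug reports with the event,
#' \code{b} target-drug reports without it, \code{c}/\code{d} the same for
#' the comparator universe. With \code{comparator_mode = "within_class"}
#' the comparator is the curated reports of all other agents; with
#' \code{"external_background"} the comparator counts come from a supplied
#' background table (needed for class-level questions, where no other
#' agents remain inside the curated set).
#'
#' @param cases cohort cases table (one row per report, columns
#'   \code{agent} and list-column \code{pts}).
#' @param drug one agent name, or \code{"class"} for all five pooled.
#' @param pt target preferred term.
#' @param comparator_mode \code{"within_class"} or
#'   \code{"external_background"}.
#' @param background for external mode: list with \code{pt_counts} (named
#'   numeric, reports per PT) and \code{total} (total reports).
#' @return a \code{contingency_table}: list \code{(a, b, c, d)}.
#' @export
build_table <- function(cases, drug, pt,
                        comparator_mode = c("within_class",
                                            "external_background"),
                        background = NULL) {
  comparator_mode <- match.arg(comparator_mode)
  cases <- data.table::as.data.table(cases)
  is_target <- if (identical(drug, "class")) rep(TRUE, nrow(cases)) else
    cases$agent == drug
  has_pt <- vapply(cases$pts, function(p) pt %in% p, TRUE)
  a <- sum(is_target & has_pt)
  b <- sum(is_target & !has_pt)
  if (comparator_mode == "within_class") {
    if (all(is_target)) {
      stop("within_class comparator is empty: target covers every report")
    }
    cc <- sum(!is_target & has_pt)
    d <- sum(!is_target & !has_pt)
  } else {
    if (is.null(background) || is.null(background$total)) {
      stop("external_background mode needs a background count table")
    }
    cc <- unname(background$pt_counts[pt])
    if (is.na(cc)) cc <- 0
    d <- background$total - cc
  }
  if (cc + d <= 0) stop("comparator universe is empty")
  structure(list(a = a, b = b, c = cc, d = d), class = "contingency_table")
}

#' Background counts from a set of reports
#'
#' Turns a cases table (e.g. the curated adult reports) into the
#' \code{(pt_counts, total)} background object consumed by
#' [build_table()]'s external mode.
#'
#' @param cases cohort cases table with list-column \code{pts}.
#' @return list with \code{pt_counts} and \code{total}.
#' @export
background_from_cases <- function(cases) {
  cases <- data.table::as.data.table(cases)
  pts <- unlist(lapply(cases$pts, unique), use.names = FALSE)
  list(pt_counts = c(table(pts)), total = nrow(cases))
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' ROR = (a d) / (b c); the confidence interval is computed on the log
#' scale, \code{exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))}. Any zero
#' cell leaves the ROR undefined (reported as such, no continuity
#' correction by default); setting \code{haldane = TRUE} applies the
#' Haldane-Anscombe 0.5 correction to every cell instead.
#'
#' @param a,b,c,d cell counts (vectors allowed), or pass a
#'   \code{contingency_table} as \code{a}.
#' @param z normal quantile (default 1.96 for 95%).
#' @param haldane apply the 0.5 continuity correction to zero-cell tables.
#' @return data.table with \code{ror}, \code{ci_low}, \code{ci_high},
#'   \code{undefined_reason} (\code{NA} or \code{"zero cell"}).
#' @export
#' @examples
#' ror_ci(10, 90, 10, 900) # ROR 10, CI about (4.05, 24.67)
ror_ci <- function(a, b = NULL, c = NULL, d = NULL, z = 1.96,
                   haldane = FALSE) {
  if (inherits(a, "contingency_table")) {
    t <- a; a <- t$a; b <- t$b; c <- t$c; d <- t$d
  }
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (haldane) {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
    zero <- rep(FALSE, length(a))
  }
  ror <- ci_low <- ci_high <- rep(NA_real_, length(a))
  ok <- !zero
  lr <- log(a[ok]) + log(d[ok]) - log(b[ok]) - log(c[ok])
  se <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
  ror[ok] <- exp(lr)
  ci_low[ok] <- exp(lr - z * se)
  ci_high[ok] <- exp(lr + z * se)
  data.table::data.table(
    ror = ror, ci_low = ci_low, ci_high = ci_high,
    undefined_reason = ifelse(zero, "zero cell", NA_character_))
}

#' Pearson chi-square for a 2x2 table
#'
#' \code{N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, optionally with the
#' Yates continuity correction. Undefined (NA) when any margin is zero.
#'
#' @inheritParams ror_ci
#' @param yates apply Yates continuity correction (default FALSE).
#' @return numeric vector of statistics.
#' @export
#' @examples
#' chi_square(10, 90, 10, 900) # 36.78
chi_square <- function(a, b = NULL, c = NULL, d = NULL, yates = FALSE) {
  if (inherits(a, "contingency_table")) {
    t <- a; a <- t$a; b <- t$b; c <- t$c; d <- t$d
  }
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  m <- (a + b) * (c + d) * (a + c) * (b + d)
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(0, dev - n / 2)
  out <- n * dev^2 / m
  out[m == 0] <- NA_real_
  out
}

#' Apply signal criteria to computed results
#'
#' @param n report count (cell a).
#' @param ror,ci_low,chi2 computed statistics (NA when undefined).
#' @param criteria a [signal_criteria()].
#' @return logical signal flag vector (undefined ROR -> FALSE).
#' @export
classify_signal <- function(n, ror, ci_low, chi2,
                            criteria = signal_criteria()) {
  flag <- !is.na(ror) & n >= criteria$min_cases
  if (criteria$require_ci_low_gt_1) flag <- flag & !is.na(ci_low) & ci_low > 1
  if (!is.na(criteria$require_chi2_gt)) {
    flag <- flag & !is.na(chi2) & chi2 > criteria$require_chi2_gt
  }
  if (!is.na(criteria$require_ror_gt)) {
    flag <- flag & ror > criteria$require_ror_gt
  }
  flag
}

#' Risk-signal detection ratio
#'
#' The share of a drug's observed PTs that are flagged as risk signals,
#' reported as a percent.
#'
#' @param signal_count number of signal-flagged PTs.
#' @param pt_count number of distinct PTs observed for the drug (> 0).
#' @param decimals decimal places (default 2).
#' @return percent, \code{NA} when \code{pt_count} is 0.
#' @export
#' @examples
#' rsr(852, 4520) # 18.85
rsr <- function(signal_count, pt_count, decimals = 2L) {
  proportion(signal_count, pt_count, decimals)
}

#' Scan all drug-event pairs for signals
#'
#' Builds the fourfold table and computes ROR, 95% CI, chi-square and the
#' signal flag for every (drug, PT) pair observed in the cohort — the
#' machine-readable analogue of a per-drug signal table.
#'
#' @param cohort a \code{faers_cohort}, or a cases table.
#' @param drugs agents to scan (default: all present).
#' @param comparator_mode,background as in [build_table()].
#' @param criteria a [signal_criteria()].
#' @param z normal quantile for the CI.
#' @return data.table with columns \code{drug}, \code{soc}, \code{pt},
#'   \code{n}, \code{ror}, \code{ci_low}, \code{ci_high}, \code{chi2},
#'   \code{is_signal}, \code{undefined_reason}.
#' @export
signal_scan <- function(cohort, drugs = NULL,
                        comparator_mode = c("within_class",
                                            "external_background"),
                        background = NULL,
                        criteria = signal_criteria(), z = 1.96) {
  comparator_mode <- match.arg(comparator_mode)
  cases <- if (inherits(cohort, "faers_cohort")) cohort$cases else
    data.table::as.data.table(cohort)
  pt_to_soc <- if (inherits(cohort, "faers_cohort")) cohort$pt_to_soc else
    character(0)
  if (is.null(drugs)) drugs <- sort(unique(cases$agent))
  # long report-PT incidence
  long <- data.table::data.table(
    primaryid = rep(cases$primaryid, lengths(cases$pts)),
    agent = rep(cases$agent, lengths(cases$pts)),
    pt = unlist(cases$pts, use.names = FALSE))
  long <- unique(long)
  n_by_agent <- cases[, list(n_reports = .N), by = agent]
  out <- list()
  for (dg in drugs) {
    target_n <- if (identical(dg, "class")) nrow(cases) else
      n_by_agent[agent == dg]$n_reports
    if (!length(target_n) || target_n == 0L) next
    tgt <- if (identical(dg, "class")) long else long[agent == dg]
    a_tab <- tgt[, list(a = .N), by = pt]
    if (comparator_mode == "within_class") {
      if (identical(dg, "class")) {
        stop("within_class comparator is empty for the pooled class; ",
             "supply an external background")
      }
      cmp <- long[agent != dg][, list(c = .N), by = pt]
      cmp_total <- nrow(cases) - target_n
      if (cmp_total <= 0) stop("comparator universe is empty")
    } else {
      if (is.null(background)) stop("external_background mode needs counts")
      cmp <- data.table::data.table(pt = names(background$pt_counts),
                                    c = as.numeric(background$pt_counts))
      cmp_total <- background$total
    }
    res <- merge(a_tab, cmp, by = "pt", all.x = TRUE)
    res[is.na(c), c := 0]
    res[, `:=`(b = target_n - a, d = cmp_total - c)]
    stats <- ror_ci(res$a, res$b, res$c, res$d, z = z)
    res[, `:=`(ror = stats$ror, ci_low = stats$ci_low,
               ci_high = stats$ci_high,
               undefined_reason = stats$undefined_reason)]
    res[, chi2 := chi_square(a, b, c, d)]
    res[, is_signal := classify_signal(a, ror, ci_low, chi2, criteria)]
    res[, drug := dg]
    out[[dg]] <- res
  }
  res <- data.table::rbindlist(out)
  if (!nrow(res)) return(res)
  res[, soc := {
    s <- unname(pt_to_soc[pt]); s[is.na(s)] <- "UNMAPPED"; s
  }]
  res[, n := a]
  data.table::setcolorder(res, c("drug", "soc", "pt", "n", "ror", "ci_low",
                                 "ci_high", "chi2", "is_signal",
                                 "undefined_reason"))
  data.table::setorder(res, drug, -n, pt)
  res[]
}

#' Prioritize signals for reporting
#'
#' Ranks PTs by (1) total pediatric report volume across agents and (2)
#' how many agents flag the PT as a signal, with the PT name as a
#' deterministic alphabetical tiebreak — surfacing both high-prevalence
#' and pan-class concerns.
#'
#' @param signals output of [signal_scan()].
#' @return data.table \code{(pt, n_total, n_agents_signal)} in rank order.
#' @export
prioritize <- function(signals) {
  signals <- data.table::as.data.table(signals)
  agg <- signals[, list(n_total = sum(n),
                        n_agents_signal = sum(is_signal)), by = pt]
  data.table::setorder(agg, -n_total, -n_agents_signal, pt)
  agg[]
}

#' Serialise a signal table in report shape
#'
#' Writes the CSV used for per-drug signal tables; undefined RORs are
#' rendered as \code{"/"} in the ror and CI columns, matching
#' pharmacovigilance reporting convention for zero-count cells.
#'
#' @param signals output of [signal_scan()].
#' @param path output CSV path.
#' @return invisibly, the formatted data.table.
#' @export
write_signal_csv <- function(signals, path) {
  s <- data.table::as.data.table(signals)
  fmt <- function(x) ifelse(is.na(x), "/", formatC(x, digits = 4,
                                                   format = "fg"))
  out <- s[, list(drug, soc, pt, n, ror = fmt(ror), ci_low = fmt(ci_low),
                  ci_high = fmt(ci_high), chi2 = fmt(chi2), is_signal)]
  data.table::fwrite(out, path)
  invisible(out)
}
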