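
# Table-1 style category orders
outcome_categories <- list(
  Death = "DE", `Life-Threatening` = "LT", Disability = "DS",
  Hospitalization = "HO", Other = c("CA", "RI", "OT"))
severe_outcome_codes <- c("DE", "LT", "DS", "HO")

#' Demographic and outcome summary of the pediatric cohort
#'
#' One column per agent plus a pooled column, with counts and percents for
#' sex, age strata, reporter class and clinical outcomes. FAERS outcome
#' codes are multi-valued, so outcome rows are non-exclusive category
#' counts over cases (a case with both HO and LT contributes to both
#' rows); "Unknown" counts cases with no outcome code at all. The severe
#' share uses the conventional definition: death, life-threatening,
#' disability or hospitalization.
#'
#' @param cases pediatric cases table of a \code{faers_cohort}.
#' @param decimals decimal places for percents (default 1).
#' @return data.table in long form: \code{block}, \code{category},
#'   \code{drug} (agent or \code{"all"}), \code{n}, \code{pct}; plus the
#'   severe-outcome share per drug under block \code{"severe"}.
#' @export
demographics_table <- function(cases, decimals = 1L) {
  cases <- data.table::as.data.table(cases)
  agents <- sort(unique(cases$agent))
  groups <- c(list(all = cases),
              stats::setNames(lapply(agents, function(a) cases[agent == a]),
                              agents))
  rows <- list()
  add <- function(block, category, drug, n, total) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      block = block, category = category, drug = drug, n = n,
      pct = proportion(n, total, decimals))
  }
  for (g in names(groups)) {
    dat <- groups[[g]]
    total <- nrow(dat)
    for (s in c("M", "F", "UNK")) add("sex", s, g, sum(dat$sex == s), total)
    for (s in levels(dat$stratum)) {
      add("stratum", s, g, sum(dat$stratum == s, na.rm = TRUE), total)
    }
    for (rc in c("Physician", "Pharmacist", "Other health professional",
                 "Consumer", "Unknown/other")) {
      add("reporter", rc, g, sum(dat$reporter_class == rc), total)
    }
    oc <- dat$outcomes
    has_code <- function(codes) {
      vapply(oc, function(o) !is.null(o) && any(codes %in% o), TRUE)
    }
    for (cat in names(outcome_categories)) {
      add("outcome", cat, g, if (total) sum(has_code(outcome_categories[[cat]])) else 0L, total)
    }
    n_unknown <- if (total) sum(vapply(oc, is.null, TRUE)) else 0L
    add("outcome", "Unknown", g, n_unknown, total)
    n_severe <- if (total) sum(has_code(severe_outcome_codes)) else 0L
    add("severe", "Severe outcome", g, n_severe, total)
  }
  data.table::rbindlist(rows)
}

#' Aggregate signals to system organ classes
#'
#' Counts, per SOC, the signal rows, the distinct signal PTs and the
#' total reports behind them. PTs absent from the mapping land in
#' \code{"UNMAPPED"}.
#'
#' @param signals output of [signal_scan()] (already carries SOC labels).
#' @param signals_only restrict to rows flagged as signals (default TRUE).
#' @return data.table \code{(soc, n_signal_rows, n_distinct_pts,
#'   n_reports)}, ordered by report volume.
#' @export
soc_aggregate <- function(signals, signals_only = TRUE) {
  s <- data.table::as.data.table(signals)
  if (signals_only) s <- s[is_signal == TRUE]
  out <- s[, list(n_signal_rows = .N,
                  n_distinct_pts = data.table::uniqueN(pt),
                  n_reports = sum(n)), by = soc]
  data.table::setorder(out, -n_reports, soc)
  out[]
}

#' Age-stratum SOC proportions and top adverse events
#'
#' For each age stratum: the share of its cases involving each SOC (a case
#' counts towards a SOC when any of its PTs maps there, so shares need not
#' sum to 1), and the stratum's most frequent adverse events.
#'
#' @param cases pediatric cases table with \code{stratum} and list-columns
#'   \code{pts}/\code{socs}.
#' @param top_n number of top PTs per stratum (default 10; ties at the
#'   boundary are broken alphabetically).
#' @param decimals decimals for proportions (default 2).
#' @return list with \code{soc} (stratum, soc, case_count, proportion) and
#'   \code{top_pts} (stratum, rank, pt, case_count).
#' @export
stratum_compare <- function(cases, top_n = 10L, decimals = 2L) {
  cases <- data.table::as.data.table(cases)
  cases <- cases[!is.na(stratum)]
  soc_long <- data.table::data.table(
    stratum = rep(cases$stratum, lengths(cases$socs)),
    soc = unlist(cases$socs, use.names = FALSE))
  totals <- cases[, list(total = .N), by = stratum]
  soc_tab <- soc_long[, list(case_count = .N), by = list(stratum, soc)]
  soc_tab <- merge(soc_tab, totals, by = "stratum")
  soc_tab[, proportion := proportion(case_count, total, decimals)]
  data.table::setorder(soc_tab, stratum, -case_count, soc)

  pt_long <- data.table::data.table(
    stratum = rep(cases$stratum, lengths(cases$pts)),
    pt = unlist(cases$pts, use.names = FALSE))
  pt_tab <- pt_long[, list(case_count = .N), by = list(stratum, pt)]
  data.table::setorder(pt_tab, stratum, -case_count, pt)
  top <- pt_tab[, utils::head(.SD, top_n), by = stratum]
  top[, rank := seq_len(.N), by = stratum]
  list(soc = soc_tab[, list(stratum, soc, case_count, total, proportion)],
       top_pts = top[, list(stratum, rank, pt, case_count)])
}

#' Days from therapy start to event onset
#'
#' Both dates must be known to day precision; no imputation is attempted
#' for partial dates, mirroring the exclusion of reports with missing
#' event timelines. Events dated before therapy start are implausible and
#' excluded.
#'
#' @param therapy_start,event_dt \code{Date} vectors (NA when absent or
#'   not day-precise).
#' @return integer vector of day differences (\code{NA} where excluded),
#'   with attribute \code{"tally"} counting \code{with_onset},
#'   \code{missing} and \code{implausible}.
#' @export
onset_days <- function(therapy_start, event_dt) {
  missing <- is.na(therapy_start) | is.na(event_dt)
  days <- as.integer(event_dt - therapy_start)
  implausible <- !missing & days < 0
  days[missing | implausible] <- NA_integer_
  attr(days, "tally") <- c(with_onset = sum(!missing & !implausible),
                           missing = sum(missing),
                           implausible = sum(implausible))
  days
}

#' Summarise time-to-onset
#'
#' Median and interquartile range (linear interpolation between order
#' statistics, quantile type 7) plus counts in 30-day bins up to 360 days
#' and an open tail.
#'
#' @param days numeric vector of onset days (NAs dropped).
#' @return list with \code{n}, \code{median}, \code{q1}, \code{q3} and
#'   \code{bins} (data.table \code{(bin, n)}).
#' @export
onset_summary <- function(days) {
  days <- days[!is.na(days)]
  edges <- c(0, seq(30, 360, by = 30), Inf)
  labels <- c(sprintf("(%d,%d]", utils::head(edges[-length(edges)], -1),
                      utils::head(edges[-1], -1)), "(360,Inf]")
  if (!length(days)) {
    return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                bins = data.table::data.table(bin = labels,
                                              n = rep(0L, length(labels)))))
  }
  q <- stats::quantile(days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  cuts <- cut(days, breaks = edges, right = TRUE, include.lowest = TRUE,
              labels = labels)
  bins <- data.table::data.table(bin = labels,
                                 n = as.integer(table(cuts)[labels]))
  list(n = length(days), median = q[2L], q1 = q[1L], q3 = q[3L], bins = bins)
}

#' Per-agent and pooled onset summaries for a cohort
#'
#' @param cohort a \code{faers_cohort}.
#' @return data.table with one row per agent plus \code{"all"}: n with
#'   onset, median, q1, q3, and the exclusion tallies.
#' @export
onset_by_agent <- function(cohort) {
  cases <- cohort$cases
  groups <- c(list(all = cases),
              split(cases, cases$agent))
  rows <- lapply(names(groups), function(g) {
    dat <- groups[[g]]
    dd <- onset_days(dat$therapy_start, dat$event_date)
    tal <- attr(dd, "tally")
    s <- onset_summary(dd)
    data.table::data.table(drug = g, n_with_onset = s$n,
                           median_days = s$median, q1 = s$q1, q3 = s$q3,
                           n_missing = tal[["missing"]],
                           n_implausible = tal[["implausible"]])
  })
  data.table::rbindlist(rows)
}
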