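
#' Curation configuration
#'
#' Bundles the tunable rules applied between raw quarters and the analysis
#' cohort. The indication-exclusion lists mitigate indication bias
#' (manifestations of the treated disease reported as reactions): PTs on an
#' agent's list are removed from that agent's reports before
#' disproportionality analysis. Reports left with no PTs are excluded,
#' except that a report whose only PT is "Off-label use" is retained
#' (golimumab has no pediatric approval, so pediatric exposure is
#' inherently off-label; the rule is applied to all agents for
#' comparability). Reports whose remaining PTs all belong to the Product
#' Issues SOC are excluded as hardware/administration errors rather than
#' medicinal adverse events.
#'
#' @param indication_exclusion named list agent -> character vector of PTs.
#'   The default seeds each agent with its FDA-approved indications
#'   (IBD terms for infliximab; JIA and related arthritis/psoriasis terms
#'   for the others); the list is data, meant to be edited.
#' @param offlabel_retention keep off-label-only reports (default TRUE).
#' @param product_issues_soc_label SOC label treated as Product Issues.
#' @param age_max_plausible ages above this (years) are implausible and
#'   treated as missing (default 120).
#' @return a \code{curation_config} list.
#' @export
curation_config <- function(indication_exclusion = default_indication_exclusion(),
                            offlabel_retention = TRUE,
                            product_issues_soc_label = "Product issues",
                            age_max_plausible = 120) {
  structure(list(indication_exclusion = lapply(indication_exclusion, as.character),
                 offlabel_retention = isTRUE(offlabel_retention),
                 product_issues_soc_label = product_issues_soc_label,
                 age_max_plausible = age_max_plausible),
            class = "curation_config")
}

#' @rdname curation_config
#' @export
default_indication_exclusion <- function() {
  ibd <- c("Crohn's disease", "Ulcerative colitis", "Inflammatory bowel disease")
  jia <- c("Juvenile idiopathic arthritis", "Rheumatoid arthritis",
           "Psoriasis", "Psoriatic arthropathy", "Ankylosing spondylitis")
  list(infliximab = c(ibd, jia),
       etanercept = jia,
       adalimumab = c(ibd, jia),
       golimumab = c(jia, "Ulcerative colitis"),
       certolizumab = c(jia, "Crohn's disease"))
}

#' Deduplicate FAERS reports
#'
#' FAERS carries multiple versions of one case (same \code{caseid},
#' different \code{primaryid}). Per caseid, the version with the most
#' recent FDA receipt date is retained; when receipt dates tie, the highest
#' primaryid wins. Cases on the deleted-report lists are then removed
#' entirely. Partial receipt dates are compared at their available
#' precision with missing components as the lowest value, so the order is
#' total and the result deterministic.
#'
#' @param demo data.table/data.frame with columns \code{primaryid},
#'   \code{caseid}, \code{fda_dt} (digit strings).
#' @param deleted character vector of caseids to drop.
#' @return character vector of surviving primaryids (one per surviving
#'   caseid), sorted.
#' @export
deduplicate <- function(demo, deleted = character(0)) {
  demo <- data.table::as.data.table(demo)
  if (nrow(demo) == 0L) return(character(0))
  d <- unique(demo[, list(primaryid = as.character(primaryid),
                          caseid = as.character(caseid),
                          fda_dt = as.character(fda_dt))])
  d[, fda_key := parse_date(fda_dt)$key]
  d[is.na(fda_key), fda_key := -Inf]
  d[, pid_rank := id_rank_value(primaryid)]
  data.table::setorder(d, caseid, -fda_key, -pid_rank)
  keep <- d[!duplicated(caseid)]
  keep <- keep[!(caseid %in% as.character(deleted))]
  sort(keep$primaryid)
}

#' Convert FAERS age values to years
#'
#' FAERS ages come with a unit code: decades (DEC), years (YR), months
#' (MON), weeks (WK), days (DY) or hours (HR). Everything is normalised to
#' years (365.25-day year, 8,766-hour year), e.g. 6 months = 0.5 years.
#' Negative or non-numeric values yield \code{NA} and those records are
#' excluded from age-stratified analyses.
#'
#' @param age_value numeric (or numeric-like character) vector.
#' @param age_code character vector of unit codes.
#' @return numeric vector of ages in years (\code{NA} when missing,
#'   negative, non-numeric, or the unit is unknown).
#' @export
#' @examples
#' to_years(6, "MON")    # 0.5
#' to_years(730.5, "DY") # 2
to_years <- function(age_value, age_code) {
  v <- suppressWarnings(as.numeric(age_value))
  code <- toupper(as.character(age_code))
  mult <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 7 / 365.25,
            DY = 1 / 365.25, HR = 1 / 8766)
  out <- v * unname(mult[code])
  out[is.na(v) | v < 0 | !(code %in% names(mult))] <- NA_real_
  out
}

#' Pediatric age filter
#'
#' Keeps cases with \code{0 <= age_years < 18}; missing and implausible
#' ages (negative, or above the plausibility ceiling) are excluded and
#' tallied.
#'
#' @param age_years numeric vector.
#' @param age_max_plausible plausibility ceiling in years.
#' @return logical keep-vector with attribute \code{"tally"}: named counts
#'   of \code{retained}, \code{missing}, \code{implausible}, \code{adult}.
#' @export
select_pediatric <- function(age_years, age_max_plausible = 120) {
  missing <- is.na(age_years)
  implausible <- !missing & (age_years < 0 | age_years > age_max_plausible)
  adult <- !missing & !implausible & age_years >= 18
  keep <- !missing & !implausible & !adult
  attr(keep, "tally") <- c(retained = sum(keep), missing = sum(missing),
                           implausible = sum(implausible), adult = sum(adult))
  keep
}

#' Assign pediatric age strata
#'
#' Partition of [0, 18) into the three study strata, read as half-open
#' integer-age intervals: [0,4) -> "0-3", [4,12) -> "4-11",
#' [12,18) -> "12-17".
#'
#' @param age_years numeric vector with values in [0, 18).
#' @return factor with levels \code{"0-3"}, \code{"4-11"}, \code{"12-17"}.
#' @export
assign_stratum <- function(age_years) {
  if (any(!is.na(age_years) & (age_years < 0 | age_years >= 18))) {
    stop("assign_stratum: ages must lie in [0, 18)")
  }
  cut(age_years, breaks = c(0, 4, 12, 18), right = FALSE,
      labels = c("0-3", "4-11", "12-17"))
}

# Table-1 reporter categories from raw FAERS occupation codes.
reporter_class_of <- function(occp_cod) {
  code <- toupper(trimws(as.character(occp_cod)))
  out <- rep("Unknown/other", length(code))
  out[code == "MD"] <- "Physician"
  out[code == "PH"] <- "Pharmacist"
  out[code %in% c("OT", "RN", "HP")] <- "Other health professional"
  out[code == "CN"] <- "Consumer"
  out
}

#' Restrict reports to primary-suspect target drugs
#'
#' A report enters the cohort only if a drug row with role code PS (primary
#' suspect) maps to exactly one of the five study agents; the mapped agent
#' is recorded. Reports whose PS drugs map to two different agents are
#' ambiguous and excluded. Reports received before the agent's approval
#' quarter are excluded (pre-approval reports cannot concern the agent).
#'
#' @param demo deduplicated DEMO rows (one per report) with
#'   \code{primaryid}, \code{fda_dt}.
#' @param drug DRUG rows with \code{primaryid}, \code{role_cod},
#'   \code{drugname}, optional \code{prod_ai}.
#' @param dictionary a \code{drug_dictionary}.
#' @return data.table \code{(primaryid, agent)} for retained reports, with
#'   attribute \code{"tally"} counting exclusions (\code{no_ps_target},
#'   \code{ambiguous}, \code{pre_approval}).
#' @export
restrict_primary_suspect <- function(demo, drug,
                                     dictionary = default_drug_dictionary()) {
  demo <- data.table::as.data.table(demo)
  drug <- data.table::as.data.table(drug)
  ps <- drug[toupper(role_cod) == "PS" & primaryid %in% demo$primaryid]
  agent <- map_drug(ps$drugname, dictionary)
  if ("prod_ai" %in% names(ps)) {
    miss <- is.na(agent) & !is.na(ps$prod_ai) & nzchar(ps$prod_ai)
    if (any(miss)) agent[miss] <- map_drug(ps$prod_ai[miss], dictionary)
  }
  ps[, agent := agent]
  per_report <- ps[!is.na(agent),
                   list(n_agents = data.table::uniqueN(agent),
                        agent = agent[1L]), by = primaryid]
  n_total <- nrow(demo)
  kept <- per_report[n_agents == 1L, list(primaryid, agent)]
  n_ambiguous <- nrow(per_report) - nrow(kept)
  # approval-quarter rule
  dd <- parse_date(demo$fda_dt)
  demo_q <- quarter_of(dd$year, dd$month)
  kept[, quarter := demo_q[match(primaryid, demo$primaryid)]]
  appr <- vapply(dictionary, function(d) quarter_index(d$approval_quarter), 0L)
  pre <- !is.na(kept$quarter) &
    quarter_index(kept$quarter) < appr[kept$agent]
  n_pre <- sum(pre)
  out <- kept[!pre, list(primaryid, agent)]
  attr(out, "tally") <- c(no_ps_target = n_total - nrow(per_report),
                          ambiguous = n_ambiguous, pre_approval = n_pre)
  out[]
}

#' Apply PT-level filters to one report's reaction list
#'
#' Implements the reaction-level curation rules: (1) PTs on the report
#' agent's indication-exclusion list are dropped; (2) a report whose
#' remaining PTs all map to the Product Issues SOC is excluded; (3) a
#' report whose only PT is "Off-label use" is retained (when
#' \code{offlabel_retention} is on); (4) a report with no remaining PTs is
#' excluded.
#'
#' @param pts character vector of the report's PTs.
#' @param agent the report's agent.
#' @param config a \code{curation_config}.
#' @param pt_to_soc named character vector PT -> SOC (unmapped PTs keep the
#'   report and land in the \code{"UNMAPPED"} SOC downstream).
#' @return list \code{(keep, pts, reason)}: whether the report survives,
#'   its filtered PT list, and an exclusion reason among
#'   \code{"all_indication"}, \code{"product_issues_only"},
#'   \code{"offlabel_only_dropped"} or \code{NA}.
#' @export
apply_pt_filters <- function(pts, agent, config = curation_config(),
                             pt_to_soc = character(0)) {
  pts <- unique(as.character(pts))
  excl <- config$indication_exclusion[[agent]]
  kept <- setdiff(pts, excl)
  if (!length(kept)) {
    return(list(keep = FALSE, pts = character(0), reason = "all_indication"))
  }
  if (identical(kept, "Off-label use")) {
    if (config$offlabel_retention) {
      return(list(keep = TRUE, pts = kept, reason = NA_character_))
    }
    return(list(keep = FALSE, pts = kept, reason = "offlabel_only_dropped"))
  }
  socs <- pt_to_soc[kept]
  if (length(kept) && all(!is.na(socs) & socs == config$product_issues_soc_label)) {
    return(list(keep = FALSE, pts = kept, reason = "product_issues_only"))
  }
  list(keep = TRUE, pts = kept, reason = NA_character_)
}

#' Read a PT -> SOC mapping table
#'
#' Two-column tab-separated file with header \code{pt<TAB>soc}. MedDRA is
#' licensed, so the mapping is always user-supplied data (the package ships
#' a small synthetic hierarchy for its generator at
#' \code{system.file("extdata", "synthetic_pt_soc.tsv", package = "faersped")}).
#'
#' @param path TSV path.
#' @return named character vector PT -> SOC.
#' @export
read_pt_soc <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  names(tab) <- tolower(names(tab))
  stopifnot(all(c("pt", "soc") %in% names(tab)))
  stats::setNames(tab$soc, tab$pt)
}

#' Curate an analysis cohort from raw quarters
#'
#' Runs the full curation flow over a list of quarter bundles:
#' deduplication (latest receipt date, highest primaryid on ties, deleted
#' cases removed), primary-suspect restriction to the five agents with
#' approval-quarter cut-offs, age normalisation to years, PT-level
#' indication / product-issues / off-label filters, and the pediatric
#' (< 18 years) selection. Orphan reaction/drug rows flagged at parse time
#' are dropped here.
#'
#' Every exclusion is tallied so the attrition chain is conserved:
#' raw case count = retained + sum over exclusion reasons.
#'
#' @param bundles list of \code{faers_quarter} objects (or one bundle).
#' @param dictionary a \code{drug_dictionary}.
#' @param config a \code{curation_config}.
#' @param pt_to_soc named character vector PT -> SOC.
#' @return a \code{faers_cohort}: list with \code{cases} (pediatric
#'   analysis set, one row per report with agent, age, stratum, sex,
#'   reporter class, dates and list-columns \code{pts}, \code{socs},
#'   \code{outcomes}), \code{all_cases} (same columns, all ages — the
#'   external comparator pool), and \code{attrition} (named counts along
#'   the flow).
#' @export
curate_cohort <- function(bundles, dictionary = default_drug_dictionary(),
                          config = curation_config(),
                          pt_to_soc = character(0)) {
  if (inherits(bundles, "faers_quarter")) bundles <- list(bundles)
  grab <- function(tb) {
    data.table::rbindlist(lapply(bundles, function(b) b$tables[[tb]]),
                          fill = TRUE)
  }
  demo <- grab("demo"); drug <- grab("drug"); reac <- grab("reac")
  outc <- grab("outc"); ther <- grab("ther")
  deleted <- unique(unlist(lapply(bundles, `[[`, "deleted_caseids")))
  attrition <- c(raw_reports = nrow(demo))

  # drop orphan rows flagged at parse time
  for (nm in c("drug", "reac", "outc", "ther")) {
    tab <- get(nm)
    if ("orphan" %in% names(tab)) assign(nm, tab[orphan == FALSE | is.na(orphan)])
  }

  survivors <- deduplicate(demo, deleted)
  n_cases <- length(unique(demo$caseid))
  attrition["duplicate_versions"] <- nrow(demo) - n_cases
  attrition["deleted_cases"] <- n_cases - length(survivors)
  attrition["deduplicated"] <- length(survivors)
  demo <- demo[primaryid %in% survivors]
  demo <- demo[!duplicated(primaryid)]

  ps <- restrict_primary_suspect(demo, drug, dictionary)
  ps_tally <- attr(ps, "tally")
  attrition["ps_excluded_no_target"] <- ps_tally[["no_ps_target"]]
  attrition["ps_excluded_ambiguous"] <- ps_tally[["ambiguous"]]
  attrition["ps_excluded_pre_approval"] <- ps_tally[["pre_approval"]]
  attrition["ps_restricted"] <- nrow(ps)
  demo <- demo[primaryid %in% ps$primaryid]
  demo[, agent := ps$agent[match(primaryid, ps$primaryid)]]

  # dates, age, demographics
  fd <- parse_date(demo$fda_dt)
  ed <- parse_date(demo$event_dt)
  demo[, `:=`(fda_key = fd$key, fda_year = fd$year,
              quarter = quarter_of(fd$year, fd$month),
              event_date = ed$date, event_precision = ed$precision)]
  demo[, age_years := to_years(age, age_cod)]
  demo[!is.na(age_years) & age_years > config$age_max_plausible,
       age_years := NA_real_]
  demo[, sex := {
    s <- toupper(trimws(sex)); s[!(s %in% c("M", "F"))] <- "UNK"; s
  }]
  demo[, reporter_class := reporter_class_of(occp_cod)]

  # reaction lists + PT filters (vectorised form of apply_pt_filters)
  rl <- unique(reac[primaryid %in% demo$primaryid,
                    list(primaryid, pt)])
  rl[, agent := demo$agent[match(primaryid, demo$primaryid)]]
  n_with_reac <- data.table::uniqueN(rl$primaryid)
  attrition["excluded_no_reactions"] <- nrow(demo) - n_with_reac
  excl_pairs <- data.table::rbindlist(lapply(
    names(config$indication_exclusion),
    function(ag) data.table::data.table(
      agent = ag, pt = config$indication_exclusion[[ag]])))
  if (nrow(excl_pairs)) {
    rl[, is_ind := paste(agent, pt, sep = "\r") %in%
         paste(excl_pairs$agent, excl_pairs$pt, sep = "\r")]
  } else rl[, is_ind := FALSE]
  kept_rl <- rl[is_ind == FALSE]
  pi_label <- config$product_issues_soc_label
  kept_rl[, is_pi := {
    s <- unname(pt_to_soc[pt]); !is.na(s) & s == pi_label
  }]
  agg <- kept_rl[, list(n_kept = .N, all_pi = all(is_pi),
                        only_offlabel = .N == 1L && pt[1L] == "Off-label use"),
                 by = primaryid]
  status <- rep("all_indication", nrow(demo))
  m <- match(demo$primaryid, agg$primaryid)
  has <- !is.na(m)
  status[has & agg$only_offlabel[m]] <-
    if (config$offlabel_retention) "keep" else "offlabel_only_dropped"
  normal_has <- has & !agg$only_offlabel[m]
  status[normal_has] <- ifelse(agg$all_pi[m[normal_has]],
                               "product_issues_only", "keep")
  status[!(demo$primaryid %in% rl$primaryid)] <- "no_reactions"
  attrition["excluded_all_indication"] <- sum(status == "all_indication")
  attrition["excluded_product_issues_only"] <-
    sum(status == "product_issues_only")
  attrition["excluded_offlabel_only"] <-
    sum(status == "offlabel_only_dropped")
  demo <- demo[status == "keep"]
  pts_split <- split(kept_rl$pt, kept_rl$primaryid)
  demo[, pts := pts_split[primaryid]]
  demo[, socs := lapply(pts, function(p) {
    s <- unname(pt_to_soc[p]); s[is.na(s)] <- "UNMAPPED"; unique(s)
  })]
  attrition["post_pt_filter"] <- nrow(demo)

  # outcomes and therapy start (earliest day-precision start of a PS drug)
  outc_kept <- outc[primaryid %in% demo$primaryid]
  oc_by_report <- outc_kept[, list(outcomes = list(unique(toupper(outc_cod)))),
                            by = primaryid]
  demo[, outcomes := oc_by_report$outcomes[match(primaryid,
                                                 oc_by_report$primaryid)]]
  ps_seq <- drug[toupper(role_cod) == "PS" & primaryid %in% demo$primaryid,
                 list(primaryid, drug_seq)]
  ther_ps <- ther[primaryid %in% demo$primaryid]
  if (nrow(ther_ps)) {
    ther_ps <- merge(ther_ps, ps_seq,
                     by.x = c("primaryid", "dsg_drug_seq"),
                     by.y = c("primaryid", "drug_seq"))
    sd <- parse_date(ther_ps$start_dt)
    ther_ps[, start_date := sd$date]  # day precision only
    starts <- ther_ps[!is.na(start_date),
                      list(therapy_start = min(start_date)), by = primaryid]
    demo[, therapy_start := starts$therapy_start[match(primaryid,
                                                       starts$primaryid)]]
  } else {
    demo[, therapy_start := as.Date(NA)]
  }

  # pediatric selection
  keep_ped <- select_pediatric(demo$age_years, config$age_max_plausible)
  tal <- attr(keep_ped, "tally")
  attrition["excluded_age_missing"] <- tal[["missing"]] + tal[["implausible"]]
  attrition["excluded_adult"] <- tal[["adult"]]
  all_cases <- demo
  cases <- demo[keep_ped]
  cases[, stratum := assign_stratum(age_years)]
  attrition["pediatric"] <- nrow(cases)

  structure(list(cases = cases[], all_cases = all_cases[],
                 attrition = attrition,
                 config = config, dictionary = dictionary,
                 pt_to_soc = pt_to_soc),
            class = "faers_cohort")
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat("FAERS curated cohort\n")
  cat("  pediatric reports:", nrow(x$cases), "\n")
  cat("  all-age reports:  ", nrow(x$all_cases), "\n")
  tab <- table(x$cases$agent)
  for (ag in names(tab)) cat(sprintf("    %-13s %6d\n", ag, tab[[ag]]))
  cat("  attrition:\n")
  for (nm in names(x$attrition)) {
    cat(sprintf("    %-28s %8d\n", nm, x$attrition[[nm]]))
  }
  invisible(x)
}
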