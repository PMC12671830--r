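
#' Toy PT -> SOC vocabulary for the synthetic generator
#'
#' About 35 preferred terms across 10 system organ classes, including the
#' headline pediatric TNF-inhibitor terms (injection site pain, pyrexia,
#' uveitis, Clostridium difficile infection, off-label use), a Product
#' issues SOC, and the indication PTs (so indication filtering can be
#' exercised). \code{baseline_prob} is the per-report probability that a
#' normally generated report lists the PT. "Drug ineffective" doubles as
#' the fallback PT guaranteeing every report at least one analysable
#' reaction; do not plant associations on it.
#'
#' @return data.table \code{(pt, soc, baseline_prob)}.
#' @export
synthetic_vocabulary <- function() {
  v <- rbind(
    data.frame(pt = c("Injection site pain", "Injection site erythema",
                      "Pyrexia", "Fatigue", "Malaise", "Drug ineffective"),
               soc = "General disorders and administration site conditions",
               baseline_prob = c(0.08, 0.04, 0.06, 0.04, 0.03, 0.05)),
    data.frame(pt = c("Nasopharyngitis", "Influenza", "Sinusitis",
                      "Clostridium difficile infection",
                      "Upper respiratory tract infection"),
               soc = "Infections and infestations",
               baseline_prob = c(0.05, 0.03, 0.02, 0.02, 0.04)),
    data.frame(pt = c("Abdominal pain", "Diarrhoea", "Vomiting", "Nausea",
                      "Haematochezia", "Frequent bowel movements"),
               soc = "Gastrointestinal disorders",
               baseline_prob = c(0.06, 0.05, 0.04, 0.05, 0.015, 0.01)),
    data.frame(pt = c("Off-label use", "Overdose",
                      "Incorrect dose administered"),
               soc = "Injury, poisoning and procedural complications",
               baseline_prob = c(0.06, 0.01, 0.015)),
    data.frame(pt = c("Uveitis", "Conjunctivitis"),
               soc = "Eye disorders", baseline_prob = c(0.012, 0.02)),
    data.frame(pt = c("Headache", "Dizziness"),
               soc = "Nervous system disorders",
               baseline_prob = c(0.06, 0.03)),
    data.frame(pt = c("Arthralgia", "Back pain"),
               soc = "Musculoskeletal and connective tissue disorders",
               baseline_prob = c(0.05, 0.02)),
    data.frame(pt = c("Rash", "Pruritus", "Urticaria"),
               soc = "Skin and subcutaneous tissue disorders",
               baseline_prob = c(0.05, 0.03, 0.02)),
    data.frame(pt = c("Device leakage", "Device malfunction"),
               soc = "Product issues", baseline_prob = c(0.012, 0.012)),
    # indication PTs: never sampled as independent reactions (an agent's
    # treated disease shows up on that agent's own reports, via the
    # indication_reac_prob mechanism), but they need SOC mappings
    data.frame(pt = c("Crohn's disease", "Ulcerative colitis",
                      "Juvenile idiopathic arthritis",
                      "Rheumatoid arthritis", "Psoriasis"),
               soc = c("Gastrointestinal disorders",
                       "Gastrointestinal disorders",
                       "Musculoskeletal and connective tissue disorders",
                       "Musculoskeletal and connective tissue disorders",
                       "Skin and subcutaneous tissue disorders"),
               baseline_prob = 0))
  data.table::as.data.table(v)
}

#' Synthetic-FAERS generator configuration
#'
#' Defines the generative model behind the synthetic quarterly bundles.
#' Each report draws an agent, an age (three pediatric strata plus an
#' adult share, ages emitted in mixed units to exercise unit conversion),
#' sex, reporter occupation, receipt/therapy/event dates, outcome codes,
#' and a reaction list in which every vocabulary PT enters independently
#' with its baseline probability — except for planted (agent, PT) pairs,
#' whose odds are multiplied by \code{theta}. Duplicate report versions,
#' deleted cases, missing ages and missing event timelines are injected at
#' the configured rates. Special report types (off-label-only,
#' indication-only, product-issues-only) are drawn independently of agent
#' so their downstream exclusion cannot distort reporting odds ratios.
#'
#' Defaults: 2,000 cases per agent over 2004Q1-2024Q3; stratum weights
#' 0.071/0.241/0.688 (the marginal pediatric age distribution of TNF-
#' inhibitor reports); 10% duplicate versions; 2% deleted cases; 5%
#' missing age; 20% adult reports; 8% off-label-only reports; one planted
#' association, infliximab x Clostridium difficile infection at odds
#' multiplier 10.
#'
#' @param n_cases named integer vector, reports per agent.
#' @param quarters character vector of quarter labels to spread cases over.
#' @param vocabulary data.table \code{(pt, soc, baseline_prob)}.
#' @param planted data.frame \code{(agent, pt, theta)} of odds multipliers.
#' @param duplicate_fraction probability a case gets a second report
#'   version (same caseid, later receipt date, higher primaryid).
#' @param deleted_fraction probability a case lands on the deleted list.
#' @param missing_age_fraction probability the age fields are blank.
#' @param adult_fraction probability a report is an adult (18-80 y).
#' @param stratum_weights probabilities of the 0-3 / 4-11 / 12-17 strata
#'   (given pediatric).
#' @param offlabel_only_fraction probability a report's only PT is
#'   "Off-label use".
#' @param indication_only_fraction probability a report's only PT is the
#'   agent's indication (excluded at curation).
#' @param product_issue_only_fraction probability a report's only PT is a
#'   Product issues term (excluded at curation).
#' @param timeline_missing_fraction probability the event date is absent
#'   (excludes the report from time-to-onset analysis).
#' @param indication_reac_prob probability a normal report also lists its
#'   own agent's indication PT as a reaction (indication
#'   misclassification; dropped again by the PT-level curation filter).
#' @param onset_meanlog,onset_sdlog lognormal parameters of the
#'   therapy-start-to-event delay in days.
#' @param sex_probs,occp_probs,outcome_probs categorical probabilities.
#' @param indication_pts named list agent -> indication PT written to INDI
#'   (and occasionally to REAC via the vocabulary baseline).
#' @param seed integer seed; generation is fully reproducible.
#' @return a \code{synthetic_config} list.
#' @export
synthetic_config <- function(
    n_cases = c(infliximab = 2000, etanercept = 2000, adalimumab = 2000,
                golimumab = 2000, certolizumab = 2000),
    quarters = quarter_seq("2004Q1", "2024Q3"),
    vocabulary = synthetic_vocabulary(),
    planted = data.frame(agent = "infliximab",
                         pt = "Clostridium difficile infection",
                         theta = 10),
    duplicate_fraction = 0.10,
    deleted_fraction = 0.02,
    missing_age_fraction = 0.05,
    adult_fraction = 0.20,
    stratum_weights = c(0.071, 0.241, 0.688),
    offlabel_only_fraction = 0.08,
    indication_only_fraction = 0.02,
    product_issue_only_fraction = 0.02,
    timeline_missing_fraction = 0.25,
    indication_reac_prob = 0.03,
    onset_meanlog = log(90), onset_sdlog = 1.2,
    sex_probs = c(M = 0.42, F = 0.56, UNK = 0.02),
    occp_probs = c(MD = 0.35, PH = 0.03, OT = 0.15, RN = 0.05, HP = 0.05,
                   CN = 0.33, LW = 0.01, UNK = 0.03),
    outcome_probs = c(DE = 0.005, LT = 0.010, DS = 0.004, HO = 0.120,
                      CA = 0.003, RI = 0.003, OT = 0.150),
    indication_pts = list(infliximab = "Crohn's disease",
                          etanercept = "Juvenile idiopathic arthritis",
                          adalimumab = "Juvenile idiopathic arthritis",
                          golimumab = "Ulcerative colitis",
                          certolizumab = "Crohn's disease"),
    seed = 20240101L) {
  cfg <- list(n_cases = n_cases, quarters = quarters,
              vocabulary = data.table::as.data.table(vocabulary),
              planted = as.data.frame(planted),
              duplicate_fraction = duplicate_fraction,
              deleted_fraction = deleted_fraction,
              missing_age_fraction = missing_age_fraction,
              adult_fraction = adult_fraction,
              stratum_weights = stratum_weights / sum(stratum_weights),
              offlabel_only_fraction = offlabel_only_fraction,
              indication_only_fraction = indication_only_fraction,
              product_issue_only_fraction = product_issue_only_fraction,
              timeline_missing_fraction = timeline_missing_fraction,
              indication_reac_prob = indication_reac_prob,
              onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
              sex_probs = sex_probs, occp_probs = occp_probs,
              outcome_probs = outcome_probs,
              indication_pts = indication_pts, seed = as.integer(seed))
  stopifnot(all(cfg$vocabulary$baseline_prob >= 0),
            all(cfg$vocabulary$baseline_prob < 1),
            all(cfg$planted$theta > 0),
            "Product issues" %in% cfg$vocabulary$soc,
            cfg$offlabel_only_fraction + cfg$indication_only_fraction +
              cfg$product_issue_only_fraction < 1)
  structure(cfg, class = "synthetic_config")
}

# per-(agent, pt) event probability for a "normal" report, with planted
# odds multipliers applied
event_prob_matrix <- function(config) {
  v <- config$vocabulary
  agents <- names(config$n_cases)
  p <- matrix(rep(v$baseline_prob, each = length(agents)),
              nrow = length(agents),
              dimnames = list(agents, v$pt))
  pl <- config$planted
  if (nrow(pl)) {
    for (i in seq_len(nrow(pl))) {
      p0 <- p[pl$agent[i], pl$pt[i]]
      odds <- pl$theta[i] * p0 / (1 - p0)
      p[pl$agent[i], pl$pt[i]] <- odds / (1 + odds)
    }
  }
  p
}

#' Expected reporting odds ratios of planted associations
#'
#' Closed-form ground truth for the generator: per-report event
#' probabilities are independent Bernoulli, so among curated reports the
#' probability that PT q appears on a target-drug report is
#' \code{p_t * pi_n / (pi_n + lambda)}, where \code{p_t} is the baseline
#' probability with the planted odds multiplier applied, \code{pi_n} the
#' probability of a normal report and \code{lambda} the off-label-only
#' fraction (off-label-only reports survive curation but can carry no
#' other PT; the indication-only and product-issues-only types are
#' excluded during curation and drop out of the universe). The expected
#' ROR is the odds ratio of these effective probabilities against the
#' pooled comparator agents.
#'
#' @param config a [synthetic_config()].
#' @return data.table \code{(agent, pt, theta, p_target, p_comparator,
#'   expected_ror)}.
#' @export
planted_truth <- function(config) {
  p <- event_prob_matrix(config)
  pi_n <- 1 - config$offlabel_only_fraction -
    config$indication_only_fraction - config$product_issue_only_fraction
  shrink <- pi_n / (pi_n + config$offlabel_only_fraction)
  agents <- rownames(p)
  n <- config$n_cases[agents]
  pl <- config$planted
  rows <- lapply(seq_len(nrow(pl)), function(i) {
    ag <- pl$agent[i]; q <- pl$pt[i]
    p_t <- p[ag, q] * shrink
    others <- setdiff(agents, ag)
    # comparator probability: report-count-weighted mix of the other agents
    p_c <- sum(p[others, q] * n[others]) / sum(n[others]) * shrink
    data.table::data.table(
      agent = ag, pt = q, theta = pl$theta[i],
      p_target = p_t, p_comparator = p_c,
      expected_ror = (p_t / (1 - p_t)) / (p_c / (1 - p_c)))
  })
  data.table::rbindlist(rows)
}

# random calendar day inside each quarter, returned as yyyymmdd string
random_day_in_quarter <- function(quarter_id) {
  out <- character(length(quarter_id))
  for (q in unique(quarter_id)) {
    b <- quarter_bounds(q)
    i <- which(quarter_id == q)
    days <- as.integer(b$last - b$first)
    out[i] <- format(b$first + sample.int(days + 1L, length(i),
                                          replace = TRUE) - 1L, "%Y%m%d")
  }
  out
}

#' Generate synthetic FAERS quarterly bundles
#'
#' Draws the full report set defined by a [synthetic_config()] and
#' assembles it into per-quarter \code{faers_quarter} bundles in the exact
#' layout [read_quarter()] parses (use [write_faers()] to put them on
#' disk). Ground truth — the per-case truth table and the planted
#' expected RORs — travels in the \code{"truth"} attribute.
#'
#' @param config a [synthetic_config()].
#' @param seed optional seed overriding \code{config$seed}.
#' @return list of \code{faers_quarter} bundles (attribute \code{"truth"}:
#'   list with \code{cases}, the case-level generating table, and
#'   \code{planted}, the [planted_truth()] table).
#' @export
generate_faers <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(as.integer(seed))
  agents <- names(config$n_cases)
  n <- sum(config$n_cases)
  agent <- rep(agents, times = config$n_cases)
  caseid <- as.character(10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  # report type
  type_probs <- c(normal = 1 - config$offlabel_only_fraction -
                    config$indication_only_fraction -
                    config$product_issue_only_fraction,
                  offlabel_only = config$offlabel_only_fraction,
                  indication_only = config$indication_only_fraction,
                  product_issue_only = config$product_issue_only_fraction)
  rtype <- sample(names(type_probs), n, replace = TRUE, prob = type_probs)

  # ages: adult share, else stratum mixture; mixed units; missingness
  is_adult <- stats::runif(n) < config$adult_fraction
  stratum <- sample(c("0-3", "4-11", "12-17"), n, replace = TRUE,
                    prob = config$stratum_weights)
  lo <- c(`0-3` = 0, `4-11` = 4, `12-17` = 12)[stratum]
  hi <- c(`0-3` = 4, `4-11` = 12, `12-17` = 18)[stratum]
  age_years <- ifelse(is_adult, stats::runif(n, 18, 80),
                      stats::runif(n, lo, hi))
  unit <- sample(c("YR", "MON", "WK", "DY"), n, replace = TRUE,
                 prob = c(0.70, 0.15, 0.05, 0.10))
  age_value <- round(age_years * c(YR = 1, MON = 12, WK = 365.25 / 7,
                                   DY = 365.25)[unit], 2)
  age_missing <- stats::runif(n) < config$missing_age_fraction
  age_str <- ifelse(age_missing, "", as.character(age_value))
  unit_str <- ifelse(age_missing, "", unit)

  sex <- sample(names(config$sex_probs), n, replace = TRUE,
                prob = config$sex_probs)
  sex[sex == "UNK"] <- ""
  occp <- sample(names(config$occp_probs), n, replace = TRUE,
                 prob = config$occp_probs)
  occp[occp == "UNK"] <- ""

  quarter <- sample(config$quarters, n, replace = TRUE)
  fda_dt <- random_day_in_quarter(quarter)

  # event timeline: event precedes receipt by a short reporting lag;
  # therapy start precedes the event by a lognormal onset delay
  lag <- sample.int(60L, n, replace = TRUE)
  onset <- pmax(0L, as.integer(round(stats::rlnorm(n, config$onset_meanlog,
                                                   config$onset_sdlog))))
  event_date <- as.Date(fda_dt, "%Y%m%d") - lag
  start_date <- event_date - onset
  timeline_missing <- stats::runif(n) < config$timeline_missing_fraction
  event_str <- ifelse(timeline_missing, "", format(event_date, "%Y%m%d"))
  start_str <- format(start_date, "%Y%m%d")

  # reactions: independent per-PT Bernoulli with planted odds shifts for
  # normal reports; special types carry their single fixed PT. A fallback
  # PT keeps every normal report analysable after indication/product-issue
  # filtering without disturbing any other PT's sampling law.
  pmat <- event_prob_matrix(config)
  v <- config$vocabulary
  prob_rows <- pmat[agent, , drop = FALSE]
  draw <- matrix(stats::runif(n * nrow(v)), n) < prob_rows
  indic <- unlist(config$indication_pts[agent], use.names = FALSE)
  pi_pts <- v$pt[v$soc == "Product issues"]
  vocab_pts <- v$pt
  indic_add <- stats::runif(n) < config$indication_reac_prob
  normal <- rtype == "normal"
  draw[!normal, ] <- FALSE
  # fallback: indication PTs have zero independent probability, so the
  # drawn set equals the post-indication-filter set; add the fallback PT
  # when it is empty or entirely Product issues
  n_drawn <- rowSums(draw)
  n_pi <- rowSums(draw[, vocab_pts %in% pi_pts, drop = FALSE])
  need_fallback <- normal & (n_drawn == 0L | n_drawn == n_pi)
  hit <- which(draw, arr.ind = TRUE)
  pio <- which(rtype == "product_issue_only")
  long_pts <- data.table::data.table(
    report = c(hit[, 1L],
               which(normal & indic_add),
               which(need_fallback),
               which(rtype == "offlabel_only"),
               which(rtype == "indication_only"),
               pio),
    pt = c(vocab_pts[hit[, 2L]],
           indic[normal & indic_add],
           rep("Drug ineffective", sum(need_fallback)),
           rep("Off-label use", sum(rtype == "offlabel_only")),
           indic[rtype == "indication_only"],
           sample(pi_pts, length(pio), replace = TRUE)))
  long_pts <- unique(long_pts)
  data.table::setorder(long_pts, report)
  pt_sets <- split(long_pts$pt, factor(long_pts$report, levels = seq_len(n)))
  names(pt_sets) <- NULL

  # outcomes
  oc_codes <- names(config$outcome_probs)
  oc_draw <- matrix(stats::runif(n * length(oc_codes)), n) <
    matrix(rep(config$outcome_probs, each = n), n)
  oc_hit <- which(oc_draw, arr.ind = TRUE)
  oc_long <- data.table::data.table(report = oc_hit[, 1L],
                                    code = oc_codes[oc_hit[, 2L]])
  data.table::setorder(oc_long, report)
  outcomes <- split(oc_long$code, factor(oc_long$report,
                                         levels = seq_len(n)))
  names(outcomes) <- NULL

  # drug names: synonym spelling variants, occasional dose suffix and
  # concomitant distractors
  dict <- default_drug_dictionary()
  drugname <- character(n)
  for (ag in agents) {
    idx <- which(agent == ag)
    drugname[idx] <- sample(dict[[ag]]$synonyms, length(idx), replace = TRUE)
  }
  dose_suffix <- stats::runif(n) < 0.3
  drugname[dose_suffix] <- paste(drugname[dose_suffix], "100MG")
  has_conco <- stats::runif(n) < 0.3
  conco_name <- sample(c("ASPIRIN", "METHOTREXATE", "PREDNISONE"), n,
                       replace = TRUE)

  # duplicates and deletions
  dup <- stats::runif(n) < config$duplicate_fraction
  deleted <- stats::runif(n) < config$deleted_fraction
  dup_fda <- format(as.Date(fda_dt, "%Y%m%d") +
                      sample.int(20L, n, replace = TRUE), "%Y%m%d")

  base_case <- data.table::data.table(
    caseid = caseid, agent = agent, rtype = rtype, quarter = quarter,
    fda_dt = fda_dt, event_dt = event_str, start_dt = start_str,
    age = age_str, age_cod = unit_str, age_years_true = age_years,
    is_adult = is_adult, sex = sex, occp_cod = occp,
    drugname = drugname, has_conco = has_conco, conco_name = conco_name,
    duplicated = dup, deleted = deleted, dup_fda_dt = dup_fda)
  base_case[, pts := pt_sets]
  base_case[, outcomes_true := outcomes]

  # emit one row set per report version
  versions <- data.table::data.table(
    caseid = c(caseid, caseid[dup]),
    version = c(rep(1L, n), rep(2L, sum(dup))),
    row = c(seq_len(n), which(dup)))
  versions[, primaryid := paste0(caseid, version)]
  versions[, fda := ifelse(version == 1L, fda_dt[row], dup_fda[row])]

  demo <- versions[, data.table::data.table(
    primaryid = primaryid, caseid = caseid, fda_dt = fda,
    event_dt = event_str[row], age = age_str[row], age_cod = unit_str[row],
    sex = sex[row], occp_cod = occp[row], reporter_country = "US")]

  drug_rows <- versions[, {
    pid <- rep(primaryid, ifelse(has_conco[row], 2L, 1L))
    cid <- rep(caseid, ifelse(has_conco[row], 2L, 1L))
    rr <- rep(row, ifelse(has_conco[row], 2L, 1L))
    seqs <- unlist(lapply(has_conco[row], function(h) if (h) 1:2 else 1L))
    data.table::data.table(
      primaryid = pid, caseid = cid, drug_seq = as.character(seqs),
      role_cod = ifelse(seqs == 1L, "PS",
                        sample(c("SS", "C"), length(seqs), replace = TRUE)),
      drugname = ifelse(seqs == 1L, drugname[rr], conco_name[rr]),
      prod_ai = "")
  }]

  reac <- versions[, {
    k <- lengths(pt_sets[row])
    data.table::data.table(primaryid = rep(primaryid, k),
                           caseid = rep(caseid, k),
                           pt = unlist(pt_sets[row], use.names = FALSE))
  }]

  outc <- versions[, {
    k <- lengths(outcomes[row])
    data.table::data.table(primaryid = rep(primaryid, k),
                           caseid = rep(caseid, k),
                           outc_cod = unlist(outcomes[row],
                                             use.names = FALSE))
  }]

  ther <- versions[, data.table::data.table(
    primaryid = primaryid, caseid = caseid, dsg_drug_seq = "1",
    start_dt = start_str[row], end_dt = "")]

  indi <- versions[, data.table::data.table(
    primaryid = primaryid, caseid = caseid, indi_drug_seq = "1",
    indi_pt = indic[row])]

  rpsr <- versions[, data.table::data.table(
    primaryid = primaryid, caseid = caseid,
    rpsr_cod = sample(c("FGN", "SDY", "HP", "CSM"), .N, replace = TRUE))]

  # split into quarter bundles by receipt date of each version
  vq <- quarter_of(as.integer(substr(demo$fda_dt, 1, 4)),
                   as.integer(substr(demo$fda_dt, 5, 6)))
  qlevels <- sort(unique(vq))
  id_q <- stats::setNames(vq, demo$primaryid)
  split_tab <- function(tab) {
    split(tab, factor(id_q[tab$primaryid], levels = qlevels))
  }
  parts <- lapply(list(demo = demo, drug = drug_rows, reac = reac,
                       outc = outc, ther = ther, indi = indi, rpsr = rpsr),
                  split_tab)
  bundles <- lapply(seq_along(qlevels), function(k) {
    q <- qlevels[k]
    structure(list(
      quarter_id = q,
      tables = lapply(parts, `[[`, k),
      deleted_caseids = sort(caseid[deleted & quarter == q]),
      log = list(quarter_id = q)), class = "faers_quarter")
  })
  data.table::setattr(bundles, "truth",
                      list(cases = base_case[], planted = planted_truth(config),
                           config = config))
  bundles
}

#' Write synthetic bundles to disk
#'
#' @param bundles output of [generate_faers()].
#' @param path output directory.
#' @return invisibly, the files written.
#' @export
write_faers <- function(bundles, path) {
  files <- unlist(lapply(bundles, write_quarter, path = path))
  invisible(files)
}
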