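# Shared fixtures: a tiny hand-built FAERS quarter with counts known by
# construction, and a small synthetic configuration for fast smoke tests.

fixture_tables <- function() {
  list(
    demo = data.table::data.table(
      primaryid = c("1001", "2001", "3001"),
      caseid = c("100", "200", "300"),
      fda_dt = c("20100401", "20100515", "20100620"),
      event_dt = c("20100301", "", "201005"),
      age = c("6", "17", ""),
      age_cod = c("MON", "YR", ""),
      sex = c("F", "M", ""),
      occp_cod = c("MD", "CN", "OT"),
      reporter_country = c("US", "US", "FR")),
    drug = data.table::data.table(
      primaryid = c("1001", "1001", "2001", "3001"),
      caseid = c("100", "100", "200", "300"),
      drug_seq = c("1", "2", "1", "1"),
      role_cod = c("PS", "C", "PS", "PS"),
      drugname = c("REMICADE", "ASPIRIN", "HUMIRA", "ENBREL 50MG"),
      prod_ai = c("", "", "", "")),
    reac = data.table::data.table(
      primaryid = c("1001", "1001", "2001", "2001", "3001"),
      caseid = c("100", "100", "200", "200", "300"),
      pt = c("Pyrexia", "Crohn's disease", "Headache", "Pyrexia",
             "Injection site pain")),
    outc = data.table::data.table(
      primaryid = c("1001", "2001"),
      caseid = c("100", "200"),
      outc_cod = c("HO", "OT")),
    ther = data.table::data.table(
      primaryid = c("1001", "2001"),
      caseid = c("100", "200"),
      dsg_drug_seq = c("1", "1"),
      start_dt = c("20100201", "20100101"),
      end_dt = c("", "")),
    indi = data.table::data.table(
      primaryid = "1001", caseid = "100", indi_drug_seq = "1",
      indi_pt = "Crohn's disease"),
    rpsr = data.table::data.table(
      primaryid = "1001", caseid = "100", rpsr_cod = "HP"))
}

write_fixture_quarter <- function(dir, quarter_id = "2010Q2",
                                  tables = fixture_tables(),
                                  deleted = character(0)) {
  bundle <- structure(list(quarter_id = quarter_id, tables = tables,
                           deleted_caseids = deleted, log = list()),
                      class = "faers_quarter")
  write_quarter(bundle, dir)
  bundle
}

fixture_pt_soc <- function() {
  v <- synthetic_vocabulary()
  stats::setNames(v$soc, v$pt)
}

# small, fast generator configuration for smoke tests (not the study-scale
# defaults used by the acceptance suite)
small_config <- function(...) {
  synthetic_config(
    n_cases = c(infliximab = 250, etanercept = 250, adalimumab = 250,
                golimumab = 250, certolizumab = 250),
    quarters = quarter_seq("2010Q1", "2016Q4"),
    ...)
}

# minimal cases table for direct unit tests of the analysis layer
toy_cases <- function() {
  data.table::data.table(
    primaryid = as.character(1:8),
    caseid = as.character(1:8),
    agent = c("infliximab", "infliximab", "infliximab", "etanercept",
              "etanercept", "etanercept", "etanercept", "etanercept"),
    quarter = c("2010Q1", "2012Q3", "2015Q1", "2010Q2", "2014Q1",
                "2015Q2", "2016Q1", "2013Q4"),
    age_years = c(1, 5, 13, 2, 6, 15, 16, 17),
    stratum = assign_stratum(c(1, 5, 13, 2, 6, 15, 16, 17)),
    sex = c("F", "F", "M", "M", "F", "UNK", "F", "M"),
    reporter_class = rep(c("Physician", "Consumer"), 4),
    pts = list("Pyrexia", c("Pyrexia", "Headache"), "Uveitis",
               "Headache", "Pyrexia", "Injection site pain",
               c("Injection site pain", "Pyrexia"), "Headache"),
    socs = list("General disorders and administration site conditions",
                c("General disorders and administration site conditions",
                  "Nervous system disorders"),
                "Eye disorders", "Nervous system disorders",
                "General disorders and administration site conditions",
                "General disorders and administration site conditions",
                "General disorders and administration site conditions",
                "Nervous system disorders"),
    outcomes = list("HO", c("HO", "LT"), NULL, "OT", NULL, "DE",
                    NULL, NULL),
    therapy_start = as.Date(c("2010-01-01", "2012-06-01", NA, "2010-03-01",
                              "2014-01-10", NA, "2015-12-01", "2013-10-01")),
    event_date = as.Date(c("2010-01-11", "2012-07-01", "2015-02-01",
                           "2010-02-01", NA, "2015-05-01", "2016-01-20",
                           "2014-12-31")))
}
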