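# Small in-code fixtures shared across module tests.

extdata <- function(name) {
  system.file("extdata", name, package = "faersignal", mustWork = TRUE)
}

# A hand-built mini bundle: three cases, one with a follow-up version.
mini_bundle <- function() {
  list(
    demo = tibble::tibble(
      primaryid = c("1001", "1002", "2001", "3001"),
      caseid = c("100", "100", "200", "300"),
      fda_dt = c("20200101", "20210101", "20200615", "20210301"),
      event_dt = c("20191201", "20191201", "2020", ""),
      sex = c("F", "F", "M", ""),
      age = c("62", "62", "744", "8"),
      age_cod = c("YR", "YR", "MON", "DEC"),
      wt = c("70", "71", "154", ""),
      wt_cod = c("KG", "KG", "LBS", ""),
      occp_cod = c("MD", "MD", "CN", "PH"),
      reporter_country = c("US", "US", "JP", "US")
    ),
    drug = tibble::tibble(
      caseid = c("100", "100", "200", "300"),
      drug_seq = c("1", "2", "1", "1"),
      role_cod = c("PS", "C", "PS", "SS"),
      drugname = c("TRACLEER", "SILDENAFIL", "  Opsumit ", "TRACLEER"),
      route = c("", "Oral", "Transplacental", "Oral")
    ),
    reac = tibble::tibble(
      caseid = c("100", "100", "100", "200", "200", "300"),
      pt = c("Dyspnoea", "Pain in jaw", "Dyspnoea", "Pneumonia", "Oedema", "Dyspnoea")
    ),
    outc = tibble::tibble(
      caseid = c("100", "100", "200"),
      outc_cod = c("HO", "DE", "OT")
    ),
    ther = tibble::tibble(
      caseid = c("100", "200"),
      dsg_drug_seq = c("1", "1"),
      start_dt = c("20191101", "202001")
    )
  )
}

mini_dictionary <- function() {
  tibble::tibble(
    pt = c("Dyspnoea", "Pain in jaw", "Pneumonia", "Oedema"),
    soc = c("Respiratory, thoracic and mediastinal disorders",
            "Musculoskeletal and connective tissue disorders",
            "Infections and infestations",
            "General disorders and administration site conditions")
  )
}

# Push a raw character table through the parser (write + re-read).
read_back <- function(tbl, dialect = "faers_dollar") {
  p <- tempfile(fileext = ".txt")
  on.exit(unlink(p))
  write_faers_table(tbl, p, dialect)
  read_faers_table(p, dialect)
}

# Parse every table of a raw simulated bundle.
parse_bundle <- function(bundle) {
  lapply(bundle, read_back)
}

# Coded cohort straight from a simulated bundle (the standard test path).
coded_from_sim <- function(sim, cfg) {
  bundle <- sim$bundle
  bundle$demo <- deduplicate_cases(bundle$demo)
  reports <- assemble_case_reports(bundle)
  build_cohort(reports, lexicon = sim_lexicon(cfg),
               dictionary = sim_pt_dictionary(cfg),
               targets = cfg$target_drugs)
}
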