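# Synthetic FAERS-shaped report generator with planted signals and full
# ground truth, so every pipeline stage is testable without any download.

#' Configuration for the synthetic report generator
#'
#' Defaults emulate the structure of a spontaneous-report cohort for the
#' three oral endothelin receptor antagonists: the target drugs hold small
#' primary-suspect shares of the database (3.1/4.3/2.6%, echoing their
#' relative report volumes), target reports are predominantly female (74%),
#' event terms follow a geometric rate ladder from common (15% of cases) to
#' rare (0.2%), onset delays are log-normal with a median around 180 days,
#' and about half of the reports lack usable onset/start dates. Planted
#' signals multiply the per-term Bernoulli reporting rate for cases whose
#' primary suspect is the given drug.
#'
#' @param n_cases Number of cases before follow-up versions.
#' @param seed Integer seed; fixes the generated bundle bit-for-bit.
#' @param target_drugs Target INNs.
#' @param target_drug_probs Probability that a case's primary suspect is each
#'   target (named after `target_drugs`).
#' @param background_drug_count Number of background drugs sharing the rest.
#' @param pt_dictionary_size Number of event PTs (`PT01`, `PT02`, ...).
#' @param soc_count Number of SOCs the PTs are assigned to round-robin.
#' @param baseline_rates Per-PT event probability per case; default is a
#'   geometric ladder from 0.15 down to 0.002.
#' @param planted_signals Tibble (`drug`, `pt`, `lambda`) of rate
#'   multipliers; `lambda > 0`, and `lambda * rate` must stay below 1.
#' @param sex_female_prob_target,sex_female_prob_background,sex_unknown_prob
#'   Sex mixture.
#' @param age_mean,age_sd,age_missing_prob Age model (years).
#' @param weight_mean,weight_sd,weight_missing_prob Weight model (kg).
#' @param outcome_probs Named per-code outcome probabilities (independent).
#' @param reporter_probs,country_probs Categorical mixtures.
#' @param tto_meanlog,tto_sdlog Log-normal onset-delay parameters (days).
#' @param tto_missing_start_prob,tto_imprecise_start_prob,tto_missing_event_prob
#'   Fractions of reports with a missing, month-precise, or missing onset
#'   date component.
#' @param tto_negative_prob Fraction with event recorded before start.
#' @param duplicate_prob Fraction of cases that receive a follow-up demo row
#'   (same `caseid`, later `fda_dt`, new `primaryid`).
#' @param concomitant_max Maximum number of extra non-PS drug records.
#' @param misspelling_prob Fraction of target drug-name strings corrupted so
#'   they miss the lexicon (for normalization testing).
#' @param brand_name_prob Probability a target drug is written as a brand
#'   name rather than the uppercased INN.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 20000,
                       seed = 1,
                       target_drugs = ERA_TARGETS,
                       target_drug_probs = c(bosentan = 0.031,
                                             ambrisentan = 0.043,
                                             macitentan = 0.026),
                       background_drug_count = 25,
                       pt_dictionary_size = 50,
                       soc_count = 8,
                       baseline_rates = NULL,
                       planted_signals = NULL,
                       sex_female_prob_target = 0.74,
                       sex_female_prob_background = 0.55,
                       sex_unknown_prob = 0.05,
                       age_mean = 60, age_sd = 16, age_missing_prob = 0.25,
                       weight_mean = 75, weight_sd = 15, weight_missing_prob = 0.4,
                       outcome_probs = c(HO = 0.35, DE = 0.12, OT = 0.25,
                                         LT = 0.02, DS = 0.01, RI = 0.005,
                                         CA = 0.001),
                       reporter_probs = c(MD = 0.30, PH = 0.18, OT = 0.20,
                                          CN = 0.25, RN = 0.01, UNK = 0.06),
                       country_probs = c(US = 0.70, JP = 0.05, DE = 0.05,
                                         FR = 0.04, GB = 0.04, CA = 0.03,
                                         OTHER = 0.09),
                       tto_meanlog = log(180), tto_sdlog = 1.4,
                       tto_missing_start_prob = 0.30,
                       tto_imprecise_start_prob = 0.10,
                       tto_missing_event_prob = 0.10,
                       tto_negative_prob = 0.02,
                       duplicate_prob = 0.10,
                       concomitant_max = 3,
                       misspelling_prob = 0,
                       brand_name_prob = 0.5) {
  if (is.null(baseline_rates)) {
    k <- pt_dictionary_size
    baseline_rates <- 0.15 * (0.002 / 0.15)^((seq_len(k) - 1) / max(k - 1, 1))
  }
  stopifnot(length(baseline_rates) == pt_dictionary_size,
            all(baseline_rates > 0), all(baseline_rates < 1))
  if (is.null(planted_signals)) {
    planted_signals <- tibble(drug = character(), pt = character(),
                              lambda = numeric())
  }
  planted_signals <- as_tibble(planted_signals)
  stopifnot(all(c("drug", "pt", "lambda") %in% names(planted_signals)) ||
              nrow(planted_signals) == 0)

  cfg <- as.list(environment())
  cfg$k <- NULL

  probs <- c(target_drug_probs, sex_female_prob_target,
             sex_female_prob_background, sex_unknown_prob, age_missing_prob,
             weight_missing_prob, outcome_probs, reporter_probs, country_probs,
             tto_missing_start_prob, tto_imprecise_start_prob,
             tto_missing_event_prob, tto_negative_prob, duplicate_prob,
             misspelling_prob, brand_name_prob)
  stopifnot(all(probs >= 0 & probs <= 1), sum(target_drug_probs) < 1)

  pts <- sprintf("PT%02d", seq_len(pt_dictionary_size))
  if (nrow(planted_signals) > 0) {
    stopifnot(all(planted_signals$lambda > 0),
              all(planted_signals$drug %in% target_drugs),
              all(planted_signals$pt %in% pts))
    idx <- match(planted_signals$pt, pts)
    if (any(planted_signals$lambda * baseline_rates[idx] >= 1)) {
      stop("infeasible config: lambda * baseline rate >= 1 for a planted pair",
           call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

#' PT dictionary and drug lexicon implied by a simulation config
#'
#' @param config A [sim_config()].
#' @return `sim_pt_dictionary()`: tibble (`pt`, `soc`) assigning each
#'   synthetic PT a SOC round-robin. `sim_lexicon()`: tibble (`raw_name`,
#'   `inn`) covering the target brand names/INNs and background drugs.
#' @export
sim_pt_dictionary <- function(config) {
  k <- config$pt_dictionary_size
  tibble(pt = sprintf("PT%02d", seq_len(k)),
         soc = sprintf("SOC%d", ((seq_len(k) - 1) %% config$soc_count) + 1))
}

#' @rdname sim_pt_dictionary
#' @export
sim_lexicon <- function(config) {
  bg <- sprintf("bgdrug%02d", seq_len(config$background_drug_count))
  bind_rows(
    default_era_lexicon(),
    tibble(raw_name = toupper(config$target_drugs),
           inn = tolower(config$target_drugs)),
    tibble(raw_name = toupper(bg), inn = bg)
  ) %>% distinct(.data$raw_name, .keep_all = TRUE)
}

sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs / sum(probs))
}

#' Simulate a FAERS-shaped report bundle with known ground truth
#'
#' Generates the seven quarterly tables (`demo`, `drug`, `reac`, `outc`,
#' `ther`, `indi`, `rpsr`) as raw character tibbles in FAERS column
#' conventions, plus a truth object sufficient to compute every expected
#' count. Events are independent per-PT Bernoulli draws with rate
#' `baseline * lambda` for planted (primary-suspect drug, PT) pairs.
#' Follow-up versions are emitted as extra demo rows sharing the `caseid`
#' with a later `fda_dt` (and altered weight), so deduplication correctness
#' is observable. The same seed reproduces the bundle bit-for-bit.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given the bundle is also written
#'   there with [write_faers_bundle()] plus a `truth.json`.
#' @param dialect Dialect used when writing.
#' @return A list with elements `bundle` (named list of raw tibbles) and
#'   `truth` (list: `cases` tibble with per-case PS drug, sex, age, true
#'   onset delay and flags; `planted`; `n_event_pairs`; counts of planted
#'   misspellings and follow-ups).
#' @export
simulate_faers_bundle <- function(config, dir = NULL,
                                  dialect = c("faers_dollar", "csv")) {
  stopifnot(inherits(config, "sim_config"))
  dialect <- match.arg(dialect)
  n <- config$n_cases

  empty_bundle <- function() {
    list(
      demo = tibble(primaryid = character(), caseid = character(),
                    fda_dt = character(), event_dt = character(),
                    sex = character(), age = character(), age_cod = character(),
                    wt = character(), wt_cod = character(), occp_cod = character(),
                    reporter_country = character()),
      drug = tibble(caseid = character(), drug_seq = character(),
                    role_cod = character(), drugname = character(),
                    route = character()),
      reac = tibble(caseid = character(), pt = character()),
      outc = tibble(caseid = character(), outc_cod = character()),
      ther = tibble(caseid = character(), dsg_drug_seq = character(),
                    start_dt = character()),
      indi = tibble(caseid = character(), indi_pt = character()),
      rpsr = tibble(caseid = character(), rpsr_cod = character())
    )
  }
  if (n == 0) {
    out <- list(bundle = empty_bundle(),
                truth = list(cases = tibble(), planted = config$planted_signals,
                             n_event_pairs = 0L, n_misspelled = 0L,
                             n_followups = 0L))
    if (!is.null(dir)) write_sim_output(out, dir, dialect)
    return(out)
  }

  with_rng(config$seed, {
    caseid <- as.character(10000000L + seq_len(n))
    primaryid <- paste0(caseid, "1")

    # primary-suspect drug
    bg_drugs <- sprintf("bgdrug%02d", seq_len(config$background_drug_count))
    p_tgt <- config$target_drug_probs
    p_bg <- rep((1 - sum(p_tgt)) / length(bg_drugs), length(bg_drugs))
    ps_drug <- sample(c(config$target_drugs, bg_drugs), n, replace = TRUE,
                      prob = c(p_tgt, p_bg))
    is_target <- ps_drug %in% config$target_drugs

    # demographics
    p_female <- ifelse(is_target, config$sex_female_prob_target,
                       config$sex_female_prob_background)
    sex <- ifelse(runif(n) < config$sex_unknown_prob, "UNK",
                  ifelse(runif(n) < p_female, "F", "M"))
    age_years <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 1), 100)
    age_missing <- runif(n) < config$age_missing_prob
    age_cod <- sample(c("YR", "MON", "DEC"), n, replace = TRUE,
                      prob = c(0.95, 0.03, 0.02))
    age_val <- round(ifelse(age_cod == "MON", age_years * 12,
                     ifelse(age_cod == "DEC", age_years / 10, age_years)), 1)
    age_chr <- ifelse(age_missing, "", as.character(age_val))
    age_cod_chr <- ifelse(age_missing, "", age_cod)

    wt <- round(pmax(rnorm(n, config$weight_mean, config$weight_sd), 30), 1)
    wt_missing <- runif(n) < config$weight_missing_prob
    wt_chr <- ifelse(wt_missing, "", as.character(wt))
    wt_cod_chr <- ifelse(wt_missing, "", "KG")

    occp <- sample_cat(n, config$reporter_probs)
    occp[occp == "UNK"] <- ""
    country <- sample_cat(n, config$country_probs)

    # dates
    d0 <- as.Date("2004-01-01"); d1 <- as.Date("2025-06-30")
    fda_dt <- d0 + floor(runif(n) * as.numeric(d1 - d0 + 1))
    start_dt <- fda_dt - floor(runif(n, 30, 1000))
    tto_true <- round(rlnorm(n, config$tto_meanlog, config$tto_sdlog))
    negative <- runif(n) < config$tto_negative_prob
    event_dt <- start_dt + ifelse(negative, -sample(1:30, n, replace = TRUE),
                                  tto_true)
    start_missing <- runif(n) < config$tto_missing_start_prob
    start_imprecise <- !start_missing &
      runif(n) < config$tto_imprecise_start_prob / (1 - config$tto_missing_start_prob)
    event_missing <- runif(n) < config$tto_missing_event_prob
    start_chr <- ifelse(start_missing, "",
                 ifelse(start_imprecise, format(start_dt, "%Y%m"),
                        format(start_dt, "%Y%m%d")))
    event_chr <- ifelse(event_missing, "", format(event_dt, "%Y%m%d"))
    tto_usable <- !start_missing & !start_imprecise & !event_missing & !negative

    # events: independent Bernoulli per PT, planted pairs multiplied
    k <- config$pt_dictionary_size
    pts <- sprintf("PT%02d", seq_len(k))
    rate <- matrix(rep(config$baseline_rates, each = n), nrow = n)
    pl <- config$planted_signals
    if (nrow(pl) > 0) {
      for (i in seq_len(nrow(pl))) {
        j <- match(pl$pt[i], pts)
        sel <- ps_drug == pl$drug[i]
        rate[sel, j] <- pmin(rate[sel, j] * pl$lambda[i], 1 - 1e-12)
      }
    }
    hit <- matrix(runif(n * k), nrow = n) < rate
    ev_case <- rep(caseid, times = k)[as.vector(hit)]
    ev_pt <- rep(pts, each = n)[as.vector(hit)]
    n_event_pairs <- length(ev_case)
    reac <- tibble(caseid = ev_case, pt = ev_pt)
    # list ~1% of event rows twice to exercise per-case set semantics
    if (nrow(reac) > 0) {
      dup_idx <- which(runif(nrow(reac)) < 0.01)
      if (length(dup_idx)) reac <- bind_rows(reac, reac[dup_idx, ])
      reac <- reac[order(reac$caseid, reac$pt), ]
    }

    # outcomes
    oc_list <- lapply(names(config$outcome_probs), function(code) {
      sel <- runif(n) < config$outcome_probs[[code]]
      tibble(caseid = caseid[sel], outc_cod = code)
    })
    outc <- arrange(bind_rows(oc_list), .data$caseid, .data$outc_cod)

    # drug records: PS row (row 1) plus concomitants
    lex <- default_era_lexicon()
    brand_of <- split(lex$raw_name, lex$inn)
    ps_name <- toupper(ps_drug)
    use_brand <- is_target & runif(n) < config$brand_name_prob
    for (dg in config$target_drugs) {
      sel <- which(use_brand & ps_drug == dg)
      brands <- setdiff(brand_of[[dg]], toupper(dg))
      if (length(sel) && length(brands)) {
        ps_name[sel] <- sample(brands, length(sel), replace = TRUE)
      }
    }
    misspelled <- is_target & runif(n) < config$misspelling_prob
    ps_name[misspelled] <- paste0(ps_name[misspelled], "XQ")
    route <- sample(c("Oral", "", "ORAL", "Intravenous"), n, replace = TRUE,
                    prob = c(0.45, 0.35, 0.15, 0.05))

    n_con <- sample(0:config$concomitant_max, n, replace = TRUE)
    con_case <- rep(caseid, n_con)
    con_seq <- unlist(lapply(n_con, function(m) if (m > 0) 1 + seq_len(m) else NULL))
    con_name <- toupper(sample(bg_drugs, length(con_case), replace = TRUE))
    con_role <- sample(c("C", "SS", "I"), length(con_case), replace = TRUE,
                       prob = c(0.7, 0.2, 0.1))
    drug <- bind_rows(
      tibble(caseid = caseid, drug_seq = "1", role_cod = "PS",
             drugname = ps_name, route = route),
      tibble(caseid = con_case, drug_seq = as.character(con_seq),
             role_cod = con_role, drugname = con_name, route = "")
    ) %>% arrange(.data$caseid, as.integer(.data$drug_seq))

    ther <- tibble(caseid = caseid, dsg_drug_seq = "1", start_dt = start_chr)
    ther <- ther[ther$start_dt != "", ]

    # follow-up versions: extra demo rows, later receipt, altered weight
    has_fu <- runif(n) < config$duplicate_prob
    fu_idx <- which(has_fu)
    fu_fda <- fda_dt[fu_idx] + sample(30:400, length(fu_idx), replace = TRUE)
    demo_first <- tibble(
      primaryid = primaryid, caseid = caseid,
      fda_dt = format(fda_dt, "%Y%m%d"), event_dt = event_chr,
      sex = ifelse(sex == "UNK", "", sex),
      age = age_chr, age_cod = age_cod_chr, wt = wt_chr, wt_cod = wt_cod_chr,
      occp_cod = occp, reporter_country = country
    )
    demo_fu <- demo_first[fu_idx, ]
    demo_fu$primaryid <- paste0(caseid[fu_idx], "2")
    demo_fu$fda_dt <- format(fu_fda, "%Y%m%d")
    demo_fu$wt <- ifelse(demo_fu$wt == "", "",
                         as.character(round(as.numeric(demo_fu$wt) + 1, 1)))
    demo <- arrange(bind_rows(demo_first, demo_fu),
                    .data$caseid, .data$primaryid)

    indi <- tibble(caseid = caseid[is_target], indi_pt = "Pulmonary arterial hypertension")
    rpsr <- tibble(caseid = caseid, rpsr_cod = "FGN")

    truth_cases <- tibble(
      caseid = caseid, ps_drug = ps_drug, is_target = is_target,
      sex = sex, age_years = ifelse(age_missing, NA_real_, age_years),
      tto_days = ifelse(tto_usable, tto_true, NA_real_),
      tto_usable = tto_usable,
      has_followup = has_fu, misspelled = misspelled,
      n_events = rowSums(hit)
    )

    out <- list(
      bundle = list(demo = demo, drug = drug, reac = reac, outc = outc,
                    ther = ther, indi = indi, rpsr = rpsr),
      truth = list(cases = truth_cases, planted = config$planted_signals,
                   n_event_pairs = n_event_pairs,
                   n_misspelled = sum(misspelled),
                   n_followups = sum(has_fu))
    )
    if (!is.null(dir)) write_sim_output(out, dir, dialect)
    out
  })
}

write_sim_output <- function(sim, dir, dialect) {
  write_faers_bundle(sim$bundle, dir, dialect)
  jsonlite::write_json(
    list(planted = sim$truth$planted,
         n_event_pairs = sim$truth$n_event_pairs,
         n_misspelled = sim$truth$n_misspelled,
         n_followups = sim$truth$n_followups),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Expected contingency cells for planted pairs
#'
#' Closed-form expectations of the 2x2 cells under a configuration, for use
#' as the recovery-test oracle. The scan drops event-free reports, so the
#' "without the event" cells are scaled by the probability that a case has
#' at least one other event.
#'
#' @param config A [sim_config()] with planted signals.
#' @return A tibble with one row per planted pair: `drug`, `pt`, `lambda`,
#'   expected `ea`, `eb`, `ec`, `ed`, and the implied `ror_expected`.
#' @export
expected_contingency <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pl <- config$planted_signals
  if (nrow(pl) == 0) return(tibble(drug = character(), pt = character(),
                                   lambda = numeric(), ea = numeric(),
                                   eb = numeric(), ec = numeric(),
                                   ed = numeric(), ror_expected = numeric()))
  pts <- sprintf("PT%02d", seq_len(config$pt_dictionary_size))
  base <- config$baseline_rates
  n <- config$n_cases
  n_bg <- n * (1 - sum(config$target_drug_probs))

  rows <- lapply(seq_len(nrow(pl)), function(i) {
    dg <- pl$drug[i]; j <- match(pl$pt[i], pts); lam <- pl$lambda[i]
    n_d <- n * config$target_drug_probs[[dg]]
    # per-PT rates for cases whose PS drug is dg (all its planted pairs apply)
    r_d <- base
    own <- pl[pl$drug == dg, ]
    r_d[match(own$pt, pts)] <- pmin(r_d[match(own$pt, pts)] * own$lambda, 1)
    p <- r_d[j]
    ea <- n_d * p
    ec <- n_d * (1 - p) * (1 - prod(1 - r_d[-j]))
    eb <- n_bg * base[j]
    ed <- n_bg * (1 - base[j]) * (1 - prod(1 - base[-j]))
    tibble(drug = dg, pt = pl$pt[i], lambda = lam,
           ea = ea, eb = eb, ec = ec, ed = ed,
           ror_expected = (ea * ed) / (eb * ec))
  })
  bind_rows(rows)
}
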