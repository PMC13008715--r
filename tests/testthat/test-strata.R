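# Demographic aggregations and the sex-stratified volcano.

test_that("published count fixture reproduces the printed aggregates", {
  s <- as_demographic_summary(extdata("era_report_counts.csv"))
  expect_equal(unname(sex_ratio(s)["bosentan"]), 2.77)
  expect_equal(unname(sex_ratio(s, pooled = TRUE)), 2.91)
  expect_equal(serious_outcome_total(s, "bosentan"), 15394)
  sh <- drug_share(s)
  expect_equal(sh$share[sh$drug == "ambrisentan"], 42.69)
  ab <- age_band_share(s, "18-65")
  expect_equal(ab$share[ab$drug == "bosentan"], 23.40)
})

test_that("drug shares sum to 100 within rounding and handle the single-drug case", {
  sh <- drug_share(c(bosentan = 35112, ambrisentan = 48411, macitentan = 29877))
  expect_lt(abs(sum(sh$share) - 100), 0.011)
  expect_equal(drug_share(c(x = 42))$share, 100)
  expect_error(drug_share(c(x = 0)), "zero")
})

test_that("sex ratio handles equality and zero males", {
  s <- as_demographic_summary(tibble::tibble(
    drug = c("d", "d", "d", "e", "e", "e"),
    variable = c("total", "sex", "sex", "total", "sex", "sex"),
    category = c("reports", "F", "M", "reports", "F", "M"),
    n = c(20, 10, 10, 5, 5, 0)
  ))
  expect_warning(r <- sex_ratio(s))
  expect_equal(unname(r["d"]), 1.00)
  expect_true(is.na(r["e"]))
})

test_that("synthetic cohort demographics match generator truth", {
  cfg <- sim_config(n_cases = 2500, seed = 41)
  sim <- simulate_faers_bundle(cfg)
  coded <- coded_from_sim(sim, cfg)
  s <- summarize_demographics(coded)
  truth <- sim$truth$cases

  # coded drops event-free cases; mirror that in the truth
  in_scan <- truth$caseid %in% coded$caseid[!is.na(coded$target_drug)]
  tt <- truth[truth$is_target & in_scan, ]

  totals <- table(tt$ps_drug)
  for (dg in names(totals)) {
    expect_equal(s$totals$n[s$totals$drug == dg], unname(totals[dg]))
  }
  sx <- table(tt$ps_drug, tt$sex)
  cs <- s$counts[s$counts$variable == "sex", ]
  for (dg in rownames(sx)) {
    expect_equal(cs$n[cs$drug == dg & cs$category == "F"], unname(sx[dg, "F"]))
    expect_equal(cs$n[cs$drug == dg & cs$category == "M"], unname(sx[dg, "M"]))
  }
  # per-variable counts sum to the drug total (outcomes excepted)
  for (v in c("sex", "age_band", "route", "year")) {
    per <- tapply(s$counts$n[s$counts$variable == v],
                  s$counts$drug[s$counts$variable == v], sum)
    expect_equal(as.vector(per[s$totals$drug]), s$totals$n, info = v)
  }
})

test_that("a case is counted under every outcome code it carries", {
  coded <- tibble::tibble(
    caseid = c("1", "2"), target_drug = "bosentan",
    sex = c("F", "M"), age_years = c(50, 70), weight_kg = c(60, 80),
    reporter = "MD", country = "US", route_final = "oral", year = 2020L,
    outcomes = list(c("HO", "DE"), character())
  )
  s <- summarize_demographics(coded)
  oc <- s$counts[s$counts$variable == "outcome", ]
  expect_equal(sort(oc$category), c("DE", "HO"))
  expect_equal(oc$n, c(1, 1))
  expect_equal(s$totals$n, 2)
})

test_that("volcano flags a planted female-enriched PT and respects strictness", {
  cfg <- sim_config(n_cases = 20000, seed = 51)
  sim <- simulate_faers_bundle(cfg)
  coded <- coded_from_sim(sim, cfg)

  # plant: among ambrisentan reports, make PT05 strongly female-skewed
  # (true reporting OR ~ 3) by reassigning sex for carriers
  amb <- which(!is.na(coded$target_drug) & coded$target_drug == "ambrisentan")
  has05 <- vapply(amb, function(r) "PT05" %in% coded$events[[r]], logical(1))
  carriers <- amb[has05]
  coded$sex[carriers] <- withr::with_seed(52, {
    sample(c("F", "M"), length(carriers), TRUE, prob = c(0.9, 0.1))
  })
  v <- sex_stratified_volcano(coded, "ambrisentan")
  expect_s3_class(v, "faers_volcano")
  row <- v[v$pt == "PT05", ]
  expect_equal(row$flagged_direction, "female")
  expect_gt(row$fc, 1.2)

})

test_that("fc exactly at the 1.2 boundary is not flagged even when p < 0.05", {
  # counts chosen so fc = (1200*10000)/(1000*10000) = 1.2 exactly, p << 0.05
  n_fx <- 1200; n_mx <- 1000; n_fo <- 10000; n_mo <- 10000
  coded <- tibble::tibble(
    caseid = as.character(seq_len(n_fx + n_mx + n_fo + n_mo)),
    target_drug = "bosentan",
    sex = rep(c("F", "M", "F", "M"), c(n_fx, n_mx, n_fo, n_mo)),
    events = c(rep(list("X"), n_fx), rep(list("X"), n_mx),
               rep(list("OTHER"), n_fo), rep(list("OTHER"), n_mo))
  )
  v <- sex_stratified_volcano(coded, "bosentan")
  row <- v[v$pt == "X", ]
  expect_equal(row$fc, 1.2, tolerance = 1e-12)
  expect_lt(row$p_value, 0.05)
  expect_equal(row$flagged_direction, "none")
})

test_that("volcano skips zero-cell PTs and is symmetric under sex swap", {
  coded <- tibble::tibble(
    caseid = as.character(1:8), target_drug = "bosentan",
    sex = c("F", "F", "F", "F", "M", "M", "M", "M"),
    events = list(c("PTA", "PTB"), "PTA", "PTB", "PTC",
                  "PTB", "PTB", "PTC", "PTC")
  )
  v <- sex_stratified_volcano(coded, "bosentan")
  # PTA reported only by females -> skipped
  expect_false("PTA" %in% v$pt)
  expect_equal(attr(v, "skipped_zero_cell"), 1L)

  swapped <- coded
  swapped$sex <- c(F = "M", M = "F")[coded$sex]
  v2 <- sex_stratified_volcano(swapped, "bosentan")
  common <- intersect(v$pt, v2$pt)
  m1 <- v[match(common, v$pt), ]
  m2 <- v2[match(common, v2$pt), ]
  expect_equal(m1$fc, 1 / m2$fc, tolerance = 1e-12)
  expect_equal(m1$p_value, m2$p_value, tolerance = 1e-12)
})
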