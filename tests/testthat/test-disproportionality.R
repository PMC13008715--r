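# The four statistics, thresholds, consensus, and the scan.

test_that("independence tables give null statistics", {
  t <- data.frame(a = 10, b = 10, c = 10, d = 10)
  expect_equal(compute_ror(t)$ror, 1)
  expect_equal(compute_prr(t)$prr, 1)
  expect_equal(compute_chi2(t), 0)
  expect_equal(compute_bcpnn(t)$ic, 0)
  expect_equal(compute_ebgm(t)$ebgm, 1)
})

test_that("worked 2x2 example matches hand evaluation", {
  t <- data.frame(a = 20, b = 10, c = 10, d = 20)
  r <- signal_stats(t)
  expect_equal(r$ror, 4)                         # ad/bc = 400/100
  expect_equal(r$prr, 2)                         # 20*30/(10*30)
  expect_equal(r$chi2, 60 * (300 - 30)^2 / 810000)  # = 5.4
  expect_equal(r$ebgm, 20 * 60 / (30 * 30))      # = 4/3
  se <- sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)
  expect_equal(r$ror_low, exp(log(4) - 1.96 * se))
  expect_equal(r$ror_high, exp(log(4) + 1.96 * se))
  # posterior moments vs the independent straight-line oracle
  o <- oracle_stats(20, 10, 10, 20)
  expect_equal(r$e_ic, unname(o["e_ic"]))
  expect_equal(r$v_ic, unname(o["v_ic"]))
  expect_equal(r$ic025, unname(o["ic025"]))
})

test_that("all statistics match the straight-line oracle to 12 significant digits", {
  tabs <- random_tables(1000, max_cell = 100, seed = 101)
  got <- signal_stats(tabs)
  cols <- c("ror", "ror_low", "ror_high", "prr", "prr_low", "prr_high",
            "chi2", "ic", "e_ic", "v_ic", "ic025", "ebgm", "ebgm05", "ebgm95")
  want <- t(mapply(function(a, b, c, d) oracle_stats(a, b, c, d),
                   tabs$a, tabs$b, tabs$c, tabs$d))
  for (cl in cols) {
    expect_lt(max(rel_err(got[[cl]], want[, cl])), 1e-12)
  }
})

test_that("Yates chi-square equals the standard routine on random tables", {
  tabs <- random_tables(200, max_cell = 60, seed = 7)
  got <- compute_chi2(tabs)
  ref <- vapply(seq_len(nrow(tabs)), function(i) {
    m <- matrix(c(tabs$a[i], tabs$c[i], tabs$b[i], tabs$d[i]), 2)
    suppressWarnings(unname(stats::chisq.test(m, correct = TRUE)$statistic))
  }, numeric(1))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("null calibration: ad = bc forces unit ratios, zero IC and zero chi2", {
  tabs <- data.frame(a = c(5, 8, 30), b = c(10, 4, 15),
                     c = c(2, 16, 10), d = c(4, 8, 5))
  stopifnot(all(tabs$a * tabs$d == tabs$b * tabs$c))
  r <- signal_stats(tabs)
  expect_equal(r$ror, rep(1, 3))
  expect_equal(r$prr, rep(1, 3))
  expect_equal(r$ebgm, rep(1, 3))
  expect_equal(r$ic, rep(0, 3))
  expect_equal(r$chi2, rep(0, 3))
})

test_that("ebgm equals 2^ic on every table (printed-formula identity)", {
  tabs <- random_tables(500, seed = 13)
  r <- signal_stats(tabs)
  expect_equal(r$ebgm, 2^r$ic, tolerance = 1e-12)
  # and the CI width identity for the closed-form EBGM
  width <- log(r$ebgm95 / r$ebgm05)
  expect_equal(width, 2 * 1.96 * sqrt(1 / tabs$a + 1 / tabs$b + 1 / tabs$c + 1 / tabs$d),
               tolerance = 1e-12)
})

test_that("all four point estimates strictly increase in a (b, c, d fixed)", {
  # regime with a below the comparator margins, where the observed/expected
  # ratio is monotone in a alongside ROR and PRR
  a_seq <- 1:40
  tabs <- data.frame(a = a_seq, b = 60, c = 70, d = 800)
  r <- signal_stats(tabs)
  for (cl in c("ror", "prr", "ic", "ebgm")) {
    expect_true(all(diff(r[[cl]]) > 0), info = cl)
  }
})

test_that("posterior IC shrinks toward zero and converges to IC at scale", {
  base <- c(a = 12, b = 40, c = 30, d = 300)
  for (mult in c(1, 10, 100, 1000)) {
    t <- as.data.frame(as.list(base * mult))
    r <- compute_bcpnn(t)
    expect_lte(abs(r$e_ic), abs(r$ic) + 1e-9)
  }
  gap <- vapply(c(1, 10, 100, 1000), function(mult) {
    r <- compute_bcpnn(as.data.frame(as.list(base * mult)))
    abs(r$e_ic - r$ic)
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[4], 1e-3)
})

test_that("zero cells report missing by default and +0.5 correction when asked", {
  t <- data.frame(a = 0, b = 10, c = 5, d = 20)
  expect_true(is.na(compute_ror(t)$ror))
  r <- compute_ror(t, zero_cell = "haldane")
  expect_equal(r$ror, (0.5 * 20.5) / (10.5 * 5.5))
  # a = 0: observed ic is -Inf but the posterior stays defined
  bc <- compute_bcpnn(t)
  expect_equal(bc$ic, -Inf)
  expect_true(is.finite(bc$e_ic) && is.finite(bc$v_ic))
})

test_that("consensus requires at least two positive algorithms (all 16 combos)", {
  combos <- expand.grid(ror = c(FALSE, TRUE), prr = c(FALSE, TRUE),
                        ic = c(FALSE, TRUE), ebgm = c(FALSE, TRUE))
  th <- signal_thresholds("methods_text")
  for (i in seq_len(nrow(combos))) {
    co <- combos[i, ]
    res <- tibble::tibble(
      a = 10,
      ror = 2, ror_low = if (co$ror) 1.5 else 0.5,
      prr = 2, prr_low = if (co$prr) 1.5 else 0.5,
      ic025 = if (co$ic) 0.5 else -0.5,
      ebgm05 = if (co$ebgm) 0.5 else -0.5
    )
    out <- evaluate_signal(res, th)
    expect_equal(out$n_algorithms_positive, sum(unlist(co)))
    expect_equal(out$consensus, sum(unlist(co)) >= 2)
  }
})

test_that("the two presets differ exactly by the point-estimate floors", {
  # ROR low > 1 but ROR < 3; PRR low > 1 but PRR < 2; EBGM05 in (0, 2]
  res <- tibble::tibble(a = 50, ror = 2.5, ror_low = 1.3,
                        prr = 1.8, prr_low = 1.2, ic025 = 0.2, ebgm05 = 1.5)
  m <- evaluate_signal(res, signal_thresholds("methods_text"))
  t2 <- evaluate_signal(res, signal_thresholds("table2"))
  expect_equal(unlist(m[c("flag_ror", "flag_prr", "flag_ic", "flag_ebgm")]),
               c(flag_ror = TRUE, flag_prr = TRUE, flag_ic = TRUE, flag_ebgm = TRUE))
  expect_equal(unlist(t2[c("flag_ror", "flag_prr", "flag_ic", "flag_ebgm")]),
               c(flag_ror = FALSE, flag_prr = FALSE, flag_ic = TRUE, flag_ebgm = FALSE))
  expect_true(m$consensus); expect_false(t2$consensus)
})

test_that("missing statistics never count as positive", {
  res <- tibble::tibble(a = 3, ror = NA_real_, ror_low = NA_real_,
                        prr = NA_real_, prr_low = NA_real_,
                        ic025 = 0.4, ebgm05 = 0.3)
  out <- evaluate_signal(res, signal_thresholds("methods_text"))
  expect_false(out$flag_ror); expect_false(out$flag_prr)
  expect_true(out$flag_ic); expect_true(out$flag_ebgm)
  expect_true(out$consensus)
})

test_that("build_contingency counts cases once per term at both levels", {
  b <- mini_bundle()
  b$demo <- deduplicate_cases(read_back(b$demo))
  reports <- assemble_case_reports(b)
  coded <- build_cohort(reports, dictionary = mini_dictionary())
  # cases: 100 bosentan {Dyspnoea, Pain in jaw}, 200 macitentan {Pneumonia, Oedema},
  # 300 background {Dyspnoea}
  t <- build_contingency(coded, "bosentan", "Dyspnoea", "PT")
  expect_equal(unlist(t[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 0, d = 0))
  expect_error(build_contingency(coded, "ambrisentan", "Dyspnoea"), "empty cohort")
})

test_that("a case with two PTs in one SOC contributes once at SOC level", {
  b <- mini_bundle()
  b$reac <- rbind(b$reac, tibble::tibble(caseid = "100", pt = "Pneumonia"))
  b$demo <- deduplicate_cases(read_back(b$demo))
  reports <- assemble_case_reports(b)
  dict <- mini_dictionary()
  dict$soc[dict$pt == "Pneumonia"] <- dict$soc[dict$pt == "Dyspnoea"]
  coded <- build_cohort(reports, dictionary = dict)
  t <- build_contingency(coded, "bosentan",
                         "Respiratory, thoracic and mediastinal disorders", "SOC")
  expect_equal(t$a, 1)
})

test_that("scan cells match a nested-loop counting oracle on a simulated bundle", {
  cfg <- sim_config(n_cases = 3000, seed = 17,
                    planted_signals = tibble::tibble(drug = "ambrisentan",
                                                     pt = "PT40", lambda = 6))
  sim <- simulate_faers_bundle(cfg)
  coded <- coded_from_sim(sim, cfg)
  scan <- run_signal_scan(coded, level = "PT")

  # brute force counting, straight over the coded rows
  is_bg <- is.na(coded$target_drug)
  n_bg <- sum(is_bg)
  for (i in sample(seq_len(nrow(scan)), 25)) {
    dg <- scan$drug[i]; term <- scan$term[i]
    tgt_rows <- which(!is.na(coded$target_drug) & coded$target_drug == dg)
    a <- sum(vapply(tgt_rows, function(r) term %in% coded$events[[r]], logical(1)))
    b <- sum(vapply(which(is_bg), function(r) term %in% coded$events[[r]], logical(1)))
    expect_equal(scan$a[i], a)
    expect_equal(scan$b[i], b)
    expect_equal(scan$c[i], length(tgt_rows) - a)
    expect_equal(scan$d[i], n_bg - b)
  }
  # build_contingency agrees with the scan row
  j <- which(scan$drug == "ambrisentan" & scan$term == "PT40")
  t <- build_contingency(coded, "ambrisentan", "PT40", "PT")
  expect_equal(unlist(t[c("a", "b", "c", "d")]),
               unlist(scan[j, c("a", "b", "c", "d")]))
})

test_that("scan ordering is count-descending with lexicographic tie-break", {
  cfg <- sim_config(n_cases = 1200, seed = 23)
  sim <- simulate_faers_bundle(cfg)
  coded <- coded_from_sim(sim, cfg)
  scan <- run_signal_scan(coded)
  per_drug <- split(seq_len(nrow(scan)), scan$drug)
  for (idx in per_drug) {
    a <- scan$a[idx]; term <- scan$term[idx]
    expect_true(all(diff(a) <= 0))
    ties <- which(diff(a) == 0)
    expect_true(all(term[ties] < term[ties + 1]))
  }
  # determinism
  scan2 <- run_signal_scan(coded)
  expect_equal(tidy(scan), tidy(scan2))
})

test_that("tidy and glance expose the scan as plain tibbles", {
  cfg <- sim_config(n_cases = 600, seed = 2)
  sim <- simulate_faers_bundle(cfg)
  coded <- coded_from_sim(sim, cfg)
  scan <- run_signal_scan(coded)
  td <- tidy(scan)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "faers_scan"))
  gl <- glance(scan)
  expect_equal(gl$n_pairs, nrow(scan))
  expect_equal(gl$preset, "methods_text")
  p <- autoplot(scan)
  expect_s3_class(p, "ggplot")
})
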