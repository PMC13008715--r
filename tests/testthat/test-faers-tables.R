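# Parsing, deduplication, and case-report assembly.

test_that("dollar-delimited tables parse with typed dates and partial-date flags", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "DEMO.txt")
  writeLines(c(
    "primaryid$caseid$fda_dt$event_dt$sex",
    "11$1$20200115$20191201$F",
    "21$2$202003$2015$M",
    "31$3$20200230$$F"          # invalid day -> parse warning
  ), p)
  tbl <- read_faers_table(p, dialect = "faers_dollar")
  expect_equal(nrow(tbl), 3)
  expect_s3_class(tbl$fda_dt, "Date")
  expect_equal(tbl$fda_dt[1], as.Date("2020-01-15"))
  expect_equal(tbl$fda_dt_precision, c("day", "month", NA))
  expect_equal(tbl$event_dt_precision[2], "year")
  expect_equal(tbl$event_dt[2], as.Date("2015-01-01"))
  expect_true(is.na(tbl$fda_dt[3]))
  expect_equal(attr(tbl, "parse_warnings"), 1L)
})

test_that("a missing caseid column is a hard error naming the file", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "DRUG.txt")
  writeLines(c("primaryid$drugname", "1$X"), p)
  expect_error(read_faers_table(p), "caseid")
  expect_error(read_faers_table(p), basename(p))
})

test_that("write/read round trip preserves field values in both dialects", {
  dir <- withr::local_tempdir()
  for (dialect in c("faers_dollar", "csv")) {
    p <- file.path(dir, paste0("DEMO.", dialect))
    writeLines(gsub("\\$", if (dialect == "csv") "," else "$", c(
      "primaryid$caseid$fda_dt$event_dt$sex$age",
      "11$1$20200115$202012$F$63",
      "21$2$2021$$M$"
    )), p)
    t1 <- read_faers_table(p, dialect)
    p2 <- file.path(dir, paste0("DEMO2.", dialect))
    write_faers_table(t1, p2, dialect)
    t2 <- read_faers_table(p2, dialect)
    expect_equal(as.data.frame(t1), as.data.frame(t2), ignore_attr = TRUE)
  }
})

test_that("deduplication keeps the most recent receipt and breaks ties by primaryid", {
  demo <- tibble::tibble(
    primaryid = c("1001", "1002", "2001", "3002", "3001"),
    caseid = c("100", "100", "200", "300", "300"),
    fda_dt = as.Date(c("2020-01-01", "2021-01-01", "2020-06-15",
                       "2021-03-01", "2021-03-01"))
  )
  out <- deduplicate_cases(demo)
  expect_equal(nrow(out), 3)
  expect_equal(out$fda_dt[out$caseid == "100"], as.Date("2021-01-01"))
  # tie on fda_dt -> larger primaryid wins
  expect_equal(out$primaryid[out$caseid == "300"], "3002")
  # single-caseid rows pass through unchanged
  expect_equal(out[out$caseid == "200", ], demo[3, ])
})

test_that("deduplication matches a brute-force group-by-max oracle and is idempotent", {
  cfg <- sim_config(n_cases = 1000, seed = 11, duplicate_prob = 0.2)
  sim <- simulate_faers_bundle(cfg)
  demo <- sim$bundle$demo
  expect_gt(nrow(demo), 1000)

  out <- deduplicate_cases(demo)
  expect_equal(nrow(out), length(unique(demo$caseid)))
  expect_setequal(out$caseid, unique(demo$caseid))

  # brute force: per caseid keep max (fda_dt, primaryid)
  oracle <- do.call(rbind, lapply(split(as.data.frame(demo), demo$caseid), function(g) {
    g <- g[order(g$fda_dt, as.numeric(g$primaryid)), ]
    g[nrow(g), ]
  }))
  oracle <- oracle[order(oracle$caseid), ]
  got <- as.data.frame(out)[order(out$caseid), ]
  rownames(oracle) <- rownames(got) <- NULL
  expect_equal(got, oracle)

  expect_equal(deduplicate_cases(out), out)
})

test_that("empty demo input deduplicates to empty output", {
  demo <- tibble::tibble(primaryid = character(), caseid = character(),
                         fda_dt = as.Date(character()))
  expect_equal(nrow(deduplicate_cases(demo)), 0)
})

test_that("assembled case reports aggregate child rows with set semantics", {
  b <- mini_bundle()
  b$demo <- deduplicate_cases(read_back(b$demo))
  reports <- assemble_case_reports(b)
  expect_equal(nrow(reports), 3)

  r100 <- reports[reports$caseid == "100", ]
  expect_equal(nrow(r100$drugs[[1]]), 2)
  # Dyspnoea listed twice counts once
  expect_setequal(r100$events[[1]], c("Dyspnoea", "Pain in jaw"))
  expect_setequal(r100$outcomes[[1]], c("HO", "DE"))
  # follow-up was dropped by dedup: fda_dt is the later version
  expect_equal(r100$fda_dt, as.Date("2021-01-01"))

  # age unit conversion: 744 months ~ 62 y, 8 decades = 80 y
  expect_equal(reports$age_years[reports$caseid == "200"], 62, tolerance = 0.01)
  expect_equal(reports$age_years[reports$caseid == "300"], 80)
  # weight: 154 lbs -> ~69.85 kg
  expect_equal(reports$weight_kg[reports$caseid == "200"], 69.85, tolerance = 0.01)
})

test_that("orphan child rows are dropped and tallied", {
  b <- mini_bundle()
  b$demo <- deduplicate_cases(read_back(b$demo))
  b$reac <- rbind(b$reac, tibble::tibble(caseid = "999", pt = "Nausea"))
  reports <- assemble_case_reports(b)
  expect_equal(attr(reports, "orphan_rows"), 1L)
  expect_false("999" %in% reports$caseid)
})

test_that("per-case event counts sum to distinct (caseid, pt) pairs", {
  cfg <- sim_config(n_cases = 500, seed = 3)
  sim <- simulate_faers_bundle(cfg)
  bundle <- sim$bundle
  bundle$demo <- deduplicate_cases(bundle$demo)
  reports <- assemble_case_reports(bundle)
  n_pairs <- nrow(unique(as.data.frame(bundle$reac)[c("caseid", "pt")]))
  expect_equal(sum(lengths(reports$events)), n_pairs)
  expect_equal(sim$truth$n_event_pairs, n_pairs)
})
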