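# End-to-end pipeline: ingest -> dedup -> cohort -> scan -> tto -> strata ->
# novelty, with config echo and a hashed run manifest.

#' Run configuration for the end-to-end pipeline
#'
#' @param bundle_dir Directory with the seven report tables (or `bundle`, a
#'   named list of tibbles, may be passed directly to [run_pipeline()]).
#' @param dialect Table dialect, `"faers_dollar"` or `"csv"`.
#' @param lexicon Drug lexicon tibble or CSV path (default the built-in
#'   lexicon for the three target drugs).
#' @param dictionary PT->SOC dictionary tibble or CSV path (optional; SOC
#'   outputs are skipped without it).
#' @param labels Label list tibble or CSV path (optional; novelty output is
#'   skipped without it).
#' @param targets Target INNs.
#' @param preset Threshold preset (see [signal_thresholds()]).
#' @param min_case_count Minimum report count for flags.
#' @param levels Scan levels, subset of `c("PT", "SOC")`.
#' @param out_dir Output directory for the TSVs and manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(bundle_dir = NULL, dialect = "faers_dollar",
                       lexicon = NULL, dictionary = NULL, labels = NULL,
                       targets = ERA_TARGETS,
                       preset = "methods_text", min_case_count = 1,
                       levels = c("PT", "SOC"), out_dir = NULL) {
  structure(list(bundle_dir = bundle_dir, dialect = dialect, lexicon = lexicon,
                 dictionary = dictionary, labels = labels, targets = targets,
                 preset = preset, min_case_count = min_case_count,
                 levels = levels, out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

write_tsv_out <- function(x, path) {
  df <- as_tibble(x)
  df[] <- lapply(df, function(col) if (is.list(col)) vapply(col, toString, "") else col)
  readr::write_tsv(df, path)
  path
}

#' Run the full signal-detection pipeline
#'
#' Ingests a report bundle, deduplicates cases, builds the coded cohort,
#' scans each requested level for disproportionality signals, and computes
#' the time-to-onset, demographic, sex-volcano and label-novelty outputs.
#' All stages are deterministic given identical inputs and configuration:
#' rerunning writes byte-identical statistics tables. A `manifest.json`
#' records the configuration, stage row counts, warning tallies, package
#' version and an MD5 hash of every output file.
#'
#' @param config A [run_config()] (or a YAML path for [read_run_config()]).
#' @param bundle Optional pre-read bundle (named list of tibbles), which
#'   takes precedence over `config$bundle_dir`.
#' @return Invisibly, a list with the in-memory results (`coded`, `scans`,
#'   `tto`, `demographics`, `volcano`, `novelty`, `manifest`).
#' @export
run_pipeline <- function(config, bundle = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(bundle)) {
    stopifnot(!is.null(config$bundle_dir))
    bundle <- stage("ingest", read_faers_bundle(config$bundle_dir, config$dialect))
  }
  tallies <- list(demo_rows_raw = nrow(bundle$demo))

  bundle$demo <- stage("dedup", deduplicate_cases(bundle$demo))
  tallies$cases_after_dedup <- nrow(bundle$demo)

  reports <- stage("assemble", assemble_case_reports(bundle))
  tallies$orphan_rows <- attr(reports, "orphan_rows")

  lexicon <- config$lexicon %||% default_era_lexicon()
  coded <- stage("cohort", build_cohort(reports, lexicon = lexicon,
                                        dictionary = config$dictionary,
                                        targets = config$targets))
  for (nm in c("unmatched_drug_names", "multi_target_cases", "unmapped_pts",
               "event_free_cases")) {
    tallies[[nm]] <- attr(coded, nm)
  }
  tallies$target_reports <- sum(!is.na(coded$target_drug))
  tallies$background_reports <- sum(is.na(coded$target_drug))

  th <- signal_thresholds(config$preset, min_case_count = config$min_case_count)
  levels <- intersect(config$levels, c("PT", "SOC"))
  if (is.null(config$dictionary)) levels <- setdiff(levels, "SOC")
  scans <- stage("scan", lapply(setNames(levels, levels), function(lv) {
    run_signal_scan(coded, level = lv, thresholds = th)
  }))

  tto <- stage("tto", summarize_tto(compute_tto(coded)))
  demog <- stage("strata", summarize_demographics(coded))
  volcano <- stage("volcano", {
    drugs <- intersect(tolower(config$targets), unique(coded$target_drug))
    ok <- lapply(drugs, function(dg) {
      tryCatch(sex_stratified_volcano(coded, dg), error = function(e) NULL)
    })
    bind_rows(ok[!vapply(ok, is.null, logical(1))])
  })
  novelty <- if (!is.null(config$labels) && "PT" %in% names(scans)) {
    stage("novelty", assess_novelty(scans$PT, config$labels))
  } else NULL

  outputs <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    o <- function(name, x) {
      p <- file.path(config$out_dir, name)
      write_tsv_out(x, p)
      outputs <<- c(outputs, p)
    }
    for (lv in names(scans)) o(paste0("scan_", lv, ".tsv"), tidy(scans[[lv]]))
    o("tto_summary.tsv", tto$stats)
    o("tto_bins.tsv", tto$bins)
    o("demographics.tsv", demog$counts)
    if (nrow(volcano)) o("volcano.tsv", as_tibble(volcano))
    if (!is.null(novelty)) o("novelty.tsv", novelty)
  }

  manifest <- list(
    config = config[setdiff(names(config), c("lexicon", "dictionary", "labels"))],
    package_version = as.character(utils::packageVersion("faersignal")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    tallies = tallies,
    outputs = if (length(outputs)) {
      as.list(setNames(unname(tools::md5sum(outputs)), basename(outputs)))
    } else list()
  )
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(coded = coded, scans = scans, tto = tto,
                 demographics = demog, volcano = volcano, novelty = novelty,
                 manifest = manifest))
}
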