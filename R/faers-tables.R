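# Reading FAERS-style quarterly tables, case deduplication, and assembly of
# joined case reports.

# Harmonize the column-name variants seen across FAERS vintages and fixtures.
COLUMN_ALIASES <- c(
  case_id = "caseid", case = "caseid", case_num = "caseid",
  isr = "primaryid",
  gndr_cod = "sex",
  drugname = "drug_name", drug = "drug_name",
  role_cod = "role",
  route_cod = "route",
  pt_term = "pt",
  outc_cod = "outcome",
  dsg_drug_seq = "drug_seq",
  rept_country = "country", reporter_country = "country",
  occp_cod = "reporter"
)

DATE_COLUMNS <- c("fda_dt", "event_dt", "start_dt", "end_dt", "rept_dt",
                  "init_fda_dt", "mfr_dt")

#' Read one FAERS-style table
#'
#' Reads a single quarterly table (DEMO, DRUG, REAC, OUTC, THER, INDI, RPSR)
#' in either the `'$'`-delimited FAERS ASCII dialect or plain CSV. Column
#' names are lower-cased and harmonized through a built-in alias map; date
#' columns are parsed to `Date` with a companion `*_precision` column
#' (`"day"`/`"month"`/`"year"`) so partial dates stay usable. All other
#' columns are kept as character, unknown columns included.
#'
#' @param path Path to the file.
#' @param dialect `"faers_dollar"` for `'$'`-delimited ASCII, `"csv"` for
#'   comma-separated fixtures.
#' @return A tibble. The number of date values that failed to parse is
#'   attached as `attr(, "parse_warnings")`.
#' @details A missing `caseid` column is a hard error naming the file;
#'   unparseable dates are set missing and counted in the parse-warning tally.
#' @export
read_faers_table <- function(path, dialect = c("faers_dollar", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  delim <- if (dialect == "faers_dollar") "$" else ","
  tbl <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
  tbl <- as_tibble(tbl)
  names(tbl) <- tolower(names(tbl))
  hits <- names(tbl) %in% names(COLUMN_ALIASES)
  names(tbl)[hits] <- unname(COLUMN_ALIASES[names(tbl)[hits]])

  if (!"caseid" %in% names(tbl)) {
    stop("file '", path, "' is missing mandatory column 'caseid'", call. = FALSE)
  }

  n_bad_dates <- 0L
  for (dc in intersect(DATE_COLUMNS, names(tbl))) {
    raw <- tbl[[dc]]
    parsed <- parse_faers_date(raw)
    nonblank <- !is.na(raw) & trimws(raw) != ""
    n_bad_dates <- n_bad_dates + sum(nonblank & is.na(parsed$date))
    tbl[[dc]] <- parsed$date
    tbl[[paste0(dc, "_precision")]] <- parsed$precision
  }
  attr(tbl, "parse_warnings") <- n_bad_dates
  tbl
}

#' Write one FAERS-style table
#'
#' Inverse of [read_faers_table()]: date columns are re-serialized at their
#' recorded precision and the companion `*_precision` columns dropped, so a
#' parse/write/parse round trip preserves all field values.
#'
#' @param tbl A tibble as returned by [read_faers_table()].
#' @param path Output path.
#' @inheritParams read_faers_table
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(tbl, path, dialect = c("faers_dollar", "csv")) {
  dialect <- match.arg(dialect)
  out <- as_tibble(tbl)
  for (dc in intersect(DATE_COLUMNS, names(out))) {
    pc <- paste0(dc, "_precision")
    prec <- if (pc %in% names(out)) out[[pc]] else rep("day", nrow(out))
    if (inherits(out[[dc]], "Date")) {
      out[[dc]] <- format_faers_date(out[[dc]], prec)
    }
    out[[pc]] <- NULL
  }
  out[] <- lapply(out, function(x) ifelse(is.na(x), "", as.character(x)))
  delim <- if (dialect == "faers_dollar") "$" else ","
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Deduplicate cases by the most-recent-receipt rule
#'
#' Spontaneous reports arrive in versions: follow-ups share the `caseid` of
#' the initial report. For each `caseid` only the row with the most recent
#' `fda_dt` (FDA receipt date) is retained; rows with a unique `caseid` pass
#' through unchanged. Ties on `fda_dt` are broken deterministically by the
#' largest `primaryid`.
#'
#' @param demo Demographics table with `caseid`, `fda_dt` and `primaryid`
#'   columns (as from [read_faers_table()]).
#' @return A tibble with exactly one row per `caseid`, ordered by `caseid`.
#' @export
deduplicate_cases <- function(demo) {
  stopifnot(is.data.frame(demo))
  need <- c("caseid", "fda_dt", "primaryid")
  miss <- setdiff(need, names(demo))
  if (length(miss)) {
    stop("deduplicate_cases: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(demo) == 0) return(as_tibble(demo))

  d <- as_tibble(demo)
  fda <- d$fda_dt
  if (!inherits(fda, "Date")) fda <- parse_faers_date(fda)$date
  fda_key <- as.numeric(fda)
  fda_key[is.na(fda_key)] <- -Inf
  pid_num <- suppressWarnings(as.numeric(d$primaryid))
  pid_key <- if (all(!is.na(pid_num))) pid_num else xtfrm(as.character(d$primaryid))

  ord <- order(d$caseid, fda_key, pid_key)
  d <- d[ord, , drop = FALSE]
  keep <- !duplicated(d$caseid, fromLast = TRUE)
  d[keep, , drop = FALSE]
}

#' Assemble joined case reports
#'
#' Joins the deduplicated demographics table with the drug, reaction,
#' outcome and therapy tables into one row per case. Drug and therapy rows
#' become list-columns of tibbles; events (reaction PTs) and outcome codes
#' are per-case sets, so a PT listed twice in one case counts once. Ages are
#' normalized to years from the FAERS unit codes (`YR`, `MON`, `WK`, `DY`,
#' `HR`, `DEC`), weights to kilograms.
#'
#' @param bundle A named list of tibbles with elements `demo` (already
#'   deduplicated), `drug`, `reac`, and optionally `outc`, `ther`, `indi`,
#'   `rpsr` (the last two are passed through untouched).
#' @return A tibble of case reports with one row per `caseid` and columns
#'   `caseid`, `primaryid`, `fda_dt`, `event_dt` (+ precisions), `sex`,
#'   `age_years`, `weight_kg`, `reporter`, `country`, `year`, and
#'   list-columns `drugs`, `events`, `outcomes`, `therapy`. The number of
#'   orphan rows (child-table rows whose `caseid` is absent from `demo`)
#'   is attached as `attr(, "orphan_rows")`.
#' @export
assemble_case_reports <- function(bundle) {
  stopifnot(is.list(bundle), !is.null(bundle$demo))
  demo <- as_tibble(bundle$demo)
  demo_hits <- names(demo) %in% names(COLUMN_ALIASES)
  names(demo)[demo_hits] <- unname(COLUMN_ALIASES[names(demo)[demo_hits]])
  for (dc in intersect(c("fda_dt", "event_dt"), names(demo))) {
    if (!inherits(demo[[dc]], "Date")) {
      parsed <- parse_faers_date(demo[[dc]])
      demo[[dc]] <- parsed$date
      demo[[paste0(dc, "_precision")]] <- parsed$precision
    }
  }
  if (anyDuplicated(demo$caseid)) {
    stop("assemble_case_reports: demo has duplicated caseid values; ",
         "run deduplicate_cases() first", call. = FALSE)
  }
  ids <- demo$caseid
  orphans <- 0L

  grab <- function(tbl) {
    if (is.null(tbl) || nrow(tbl) == 0) return(NULL)
    tbl <- as_tibble(tbl)
    hits <- names(tbl) %in% names(COLUMN_ALIASES)
    names(tbl)[hits] <- unname(COLUMN_ALIASES[names(tbl)[hits]])
    bad <- !(tbl$caseid %in% ids)
    orphans <<- orphans + sum(bad)
    tbl[!bad, , drop = FALSE]
  }

  fac <- factor(ids, levels = ids)
  split_by_case <- function(tbl) {
    if (is.null(tbl)) return(rep(list(NULL), length(ids)))
    unname(split(tbl, factor(tbl$caseid, levels = ids)))
  }

  drug <- grab(bundle$drug)
  if (!is.null(drug)) {
    if (!"drug_seq" %in% names(drug)) drug$drug_seq <- "1"
    if (!"route" %in% names(drug)) drug$route <- NA_character_
    if (!"role" %in% names(drug)) drug$role <- NA_character_
    drug <- select(drug, all_of(c("caseid", "drug_name", "role", "route", "drug_seq")))
  }
  reac <- grab(bundle$reac)
  outc <- grab(bundle$outc)
  ther <- grab(bundle$ther)
  if (!is.null(ther)) {
    if (!"drug_seq" %in% names(ther)) ther$drug_seq <- NA_character_
    if (!"start_dt" %in% names(ther)) {
      ther$start_dt <- as.Date(NA)
      ther$start_dt_precision <- NA_character_
    }
    if (!inherits(ther$start_dt, "Date")) {
      parsed <- parse_faers_date(ther$start_dt)
      ther$start_dt <- parsed$date
      ther$start_dt_precision <- parsed$precision
    }
    if (!"start_dt_precision" %in% names(ther)) ther$start_dt_precision <- "day"
    ther <- select(ther, all_of(c("caseid", "drug_seq", "start_dt", "start_dt_precision")))
  }

  events_by_case <- if (is.null(reac)) {
    rep(list(character()), length(ids))
  } else {
    lapply(split(reac$pt, factor(reac$caseid, levels = ids)), unique)
  }
  outcomes_by_case <- if (is.null(outc)) {
    rep(list(character()), length(ids))
  } else {
    lapply(split(outc$outcome, factor(outc$caseid, levels = ids)), unique)
  }

  col_or_na <- function(nm) if (nm %in% names(demo)) demo[[nm]] else rep(NA_character_, nrow(demo))

  year <- if ("fda_dt" %in% names(demo) && inherits(demo$fda_dt, "Date")) {
    as.integer(format(demo$fda_dt, "%Y"))
  } else rep(NA_integer_, nrow(demo))

  reports <- tibble(
    caseid = demo$caseid,
    primaryid = col_or_na("primaryid"),
    fda_dt = if (inherits(demo$fda_dt, "Date")) demo$fda_dt else parse_faers_date(col_or_na("fda_dt"))$date,
    fda_dt_precision = col_or_na("fda_dt_precision"),
    event_dt = if ("event_dt" %in% names(demo) && inherits(demo$event_dt, "Date")) demo$event_dt else as.Date(rep(NA, nrow(demo))),
    event_dt_precision = col_or_na("event_dt_precision"),
    sex = toupper(trimws(col_or_na("sex"))),
    age_years = age_to_years(col_or_na("age"), col_or_na("age_cod")),
    weight_kg = weight_to_kg(col_or_na("wt"), col_or_na("wt_cod")),
    reporter = col_or_na("reporter"),
    country = col_or_na("country"),
    year = year,
    drugs = split_by_case(drug),
    events = unname(events_by_case),
    outcomes = unname(outcomes_by_case),
    therapy = split_by_case(ther)
  )
  reports$sex[is.na(reports$sex) | !(reports$sex %in% c("F", "M"))] <- "Unknown"
  attr(reports, "orphan_rows") <- orphans
  reports
}

#' Read a whole FAERS-style bundle directory
#'
#' Looks for files named after the seven FAERS tables (`DEMO*`, `DRUG*`,
#' `REAC*`, `OUTC*`, `THER*`, `INDI*`, `RPSR*`, case-insensitive) and reads
#' each with [read_faers_table()].
#'
#' @param dir Directory containing the table files.
#' @inheritParams read_faers_table
#' @return A named list of tibbles (missing tables are omitted).
#' @export
read_faers_bundle <- function(dir, dialect = c("faers_dollar", "csv")) {
  dialect <- match.arg(dialect)
  files <- list.files(dir, full.names = TRUE)
  out <- list()
  for (tab in c("demo", "drug", "reac", "outc", "ther", "indi", "rpsr")) {
    hit <- files[grepl(paste0("^", tab), tolower(basename(files)))]
    if (length(hit)) out[[tab]] <- read_faers_table(hit[[1]], dialect = dialect)
  }
  if (is.null(out$demo)) stop("no DEMO table found in ", dir, call. = FALSE)
  out
}

#' Write a whole bundle to a directory
#'
#' @param bundle Named list of tibbles (`demo`, `drug`, ...).
#' @param dir Output directory (created if needed).
#' @inheritParams read_faers_table
#' @return `dir`, invisibly.
#' @export
write_faers_bundle <- function(bundle, dir, dialect = c("faers_dollar", "csv")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "faers_dollar") ".txt" else ".csv"
  for (nm in names(bundle)) {
    write_faers_table(bundle[[nm]], file.path(dir, paste0(toupper(nm), ext)),
                      dialect = dialect)
  }
  invisible(dir)
}
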