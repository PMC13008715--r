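# Cohort construction: drug-name normalization to INNs, primary-suspect
# restriction, route imputation, and PT -> SOC coding.

ERA_TARGETS <- c("bosentan", "ambrisentan", "macitentan")

#' Default drug-name lexicon for the three endothelin receptor antagonists
#'
#' Maps brand names and the uppercased INNs of bosentan, ambrisentan and
#' macitentan to their International Nonproprietary Names. Users analysing
#' other drugs supply their own two-column lexicon (`raw_name`, `inn`).
#'
#' @return A tibble with columns `raw_name` (uppercase) and `inn` (lowercase).
#' @export
default_era_lexicon <- function() {
  tibble(
    raw_name = c("TRACLEER", "STAYVEER", "BOSENTAN",
                 "LETAIRIS", "VOLIBRIS", "AMBRISENTAN",
                 "OPSUMIT", "MACITENTAN"),
    inn = c("bosentan", "bosentan", "bosentan",
            "ambrisentan", "ambrisentan", "ambrisentan",
            "macitentan", "macitentan")
  )
}

#' Read a drug lexicon / PT dictionary / label list from CSV
#'
#' `read_drug_lexicon()` expects columns `raw_name,inn`;
#' `read_pt_dictionary()` expects `pt,soc`; `read_label_list()` expects
#' `drug,pt` (one row per PT listed on that drug's product label).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_drug_lexicon <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  stopifnot(all(c("raw_name", "inn") %in% names(x)))
  mutate(x, raw_name = toupper(trimws(.data$raw_name)), inn = tolower(trimws(.data$inn)))
}

#' @rdname read_drug_lexicon
#' @export
read_pt_dictionary <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  stopifnot(all(c("pt", "soc") %in% names(x)))
  x
}

#' @rdname read_drug_lexicon
#' @export
read_label_list <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  stopifnot(all(c("drug", "pt") %in% names(x)))
  mutate(x, drug = tolower(trimws(.data$drug)))
}

#' Normalize drug names to INNs
#'
#' Applies a lexicon mapping raw (brand/synonym) names to International
#' Nonproprietary Names. Matching is case-insensitive after trimming and
#' collapsing internal whitespace; unmatched names pass through unchanged and
#' are tallied.
#'
#' @param reports Case-report tibble from [assemble_case_reports()].
#' @param lexicon Tibble with columns `raw_name`, `inn` (see
#'   [default_era_lexicon()]), or a path to such a CSV.
#' @return `reports` with normalized names inside the `drugs` list-column;
#'   `attr(, "unmatched_drug_names")` counts drug rows whose name had no
#'   lexicon entry.
#' @export
normalize_drug_names <- function(reports, lexicon = default_era_lexicon()) {
  if (is.character(lexicon)) lexicon <- read_drug_lexicon(lexicon)
  stopifnot(nrow(lexicon) > 0)
  key <- toupper(stringr::str_squish(lexicon$raw_name))
  map <- setNames(tolower(lexicon$inn), key)

  unmatched <- 0L
  reports$drugs <- lapply(reports$drugs, function(d) {
    if (is.null(d) || nrow(d) == 0) return(d)
    k <- toupper(stringr::str_squish(d$drug_name))
    hit <- k %in% names(map)
    unmatched <<- unmatched + sum(!hit)
    d$drug_name[hit] <- unname(map[k[hit]])
    d
  })
  attr(reports, "unmatched_drug_names") <- unmatched
  reports
}

#' Restrict to primary-suspect reports of the target drugs
#'
#' A report is retained iff at least one target drug carries role code `PS`
#' (Primary Suspect). A case in which two distinct target INNs are both PS is
#' emitted once per target (so each drug's scan counts it once) and tallied.
#'
#' @param reports Case-report tibble with INN-normalized drug names.
#' @param targets Character vector of target INNs.
#' @return A coded-report tibble: the retained case rows plus a `target_drug`
#'   column, with `attr(, "multi_target_cases")` counting cases PS for more
#'   than one target.
#' @export
select_primary_suspect <- function(reports, targets = ERA_TARGETS) {
  targets <- tolower(targets)
  ps <- lapply(reports$drugs, function(d) {
    if (is.null(d) || nrow(d) == 0) return(character())
    unique(d$drug_name[!is.na(d$role) & toupper(d$role) == "PS" &
                         tolower(d$drug_name) %in% targets])
  })
  n_hits <- lengths(ps)
  keep <- which(n_hits >= 1)
  idx <- rep(keep, n_hits[keep])
  out <- reports[idx, , drop = FALSE]
  out$target_drug <- tolower(unlist(ps[keep], use.names = FALSE))
  attr(out, "multi_target_cases") <- sum(n_hits > 1)
  out
}

# Background comparator: cases whose PS drug set contains none of the targets
# ("all other drugs in the database except the target drugs").
select_background <- function(reports, targets = ERA_TARGETS) {
  targets <- tolower(targets)
  is_bg <- vapply(reports$drugs, function(d) {
    if (is.null(d) || nrow(d) == 0) return(TRUE)
    !any(!is.na(d$role) & toupper(d$role) == "PS" & tolower(d$drug_name) %in% targets)
  }, logical(1))
  out <- reports[is_bg, , drop = FALSE]
  out$target_drug <- NA_character_
  out
}

#' Impute administration route for the target drug
#'
#' The target drugs are oral medicines, so a missing or blank route on the
#' target drug's record is imputed as `"oral"`; reported routes are kept
#' verbatim after lower-casing.
#'
#' @param coded Coded-report tibble from [select_primary_suspect()].
#' @return `coded` with a `route_final` column.
#' @export
impute_route <- function(coded) {
  route <- mapply(function(d, tgt) {
    if (is.na(tgt) || is.null(d) || nrow(d) == 0) return(NA_character_)
    r <- d$route[tolower(d$drug_name) == tgt & !is.na(d$role) & toupper(d$role) == "PS"]
    r <- r[!is.na(r) & trimws(r) != ""]
    if (length(r) == 0) "oral" else tolower(trimws(r[[1]]))
  }, coded$drugs, coded$target_drug, USE.NAMES = FALSE)
  coded$route_final <- route
  coded
}

#' Map event PTs to System Organ Classes
#'
#' Attaches each Preferred Term's primary SOC from a user-supplied dictionary
#' (`pt`, `soc`). Matching is exact (case-sensitive) after Unicode NFC
#' normalization; dictionary keys are the authoritative spellings. PTs absent
#' from the dictionary are carried with SOC `"UNMAPPED"` and tallied.
#'
#' @param events Either a character vector of PTs, or a coded-report tibble
#'   with an `events` list-column (in which case a parallel `event_soc`
#'   list-column is added).
#' @param dictionary Tibble with columns `pt`, `soc`, or a CSV path.
#' @return For a character vector: a tibble `(pt, soc)`. For a report tibble:
#'   the tibble with an `event_soc` list-column;
#'   `attr(, "unmapped_pts")` counts unmapped event terms.
#' @export
map_pt_to_soc <- function(events, dictionary) {
  if (is.character(dictionary)) dictionary <- read_pt_dictionary(dictionary)
  keys <- enc2utf8(dictionary$pt)
  map <- setNames(dictionary$soc, keys)

  lookup <- function(pts) {
    if (length(pts) == 0) return(character())
    k <- enc2utf8(as.character(pts))
    soc <- unname(map[k])
    soc[is.na(soc)] <- "UNMAPPED"
    soc
  }

  if (is.character(events) || (is.atomic(events) && !is.data.frame(events))) {
    soc <- lookup(events)
    return(tibble(pt = as.character(events), soc = soc))
  }

  stopifnot(is.data.frame(events), "events" %in% names(events))
  socs <- lapply(events$events, lookup)
  events$event_soc <- socs
  attr(events, "unmapped_pts") <- sum(vapply(socs, function(s) sum(s == "UNMAPPED"), 0L))
  events
}

#' Build the full coded cohort (targets plus background comparator)
#'
#' Convenience wrapper: normalizes drug names, splits the deduplicated case
#' reports into target primary-suspect rows and background-comparator rows,
#' imputes routes for the targets and codes events to SOCs. The result is the
#' input expected by [run_signal_scan()] and [build_contingency()].
#'
#' @inheritParams normalize_drug_names
#' @inheritParams select_primary_suspect
#' @param dictionary PT->SOC dictionary tibble or CSV path.
#' @param drop_event_free Drop coded reports with no events from the scan set
#'   (default `TRUE`); the number dropped is tallied.
#' @return A coded-report tibble spanning target (`target_drug` set) and
#'   background (`target_drug` `NA`) reports, with attributes
#'   `unmatched_drug_names`, `multi_target_cases`, `unmapped_pts`, and
#'   `event_free_cases`.
#' @export
build_cohort <- function(reports, lexicon = default_era_lexicon(),
                         dictionary = NULL, targets = ERA_TARGETS,
                         drop_event_free = TRUE) {
  reports <- normalize_drug_names(reports, lexicon)
  tallies <- list(unmatched_drug_names = attr(reports, "unmatched_drug_names"))
  tgt <- select_primary_suspect(reports, targets)
  tallies$multi_target_cases <- attr(tgt, "multi_target_cases")
  tgt <- impute_route(tgt)
  bg <- select_background(reports, targets)
  bg$route_final <- NA_character_
  coded <- bind_rows(tgt, bg)

  if (!is.null(dictionary)) {
    coded <- map_pt_to_soc(coded, dictionary)
    tallies$unmapped_pts <- attr(coded, "unmapped_pts")
  }

  event_free <- lengths(coded$events) == 0
  tallies$event_free_cases <- sum(event_free)
  if (drop_event_free) coded <- coded[!event_free, , drop = FALSE]

  for (nm in names(tallies)) attr(coded, nm) <- tallies[[nm]]
  attr(coded, "targets") <- tolower(targets)
  coded
}
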