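#' @importFrom rlang %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join anti_join bind_rows distinct n rename all_of across count %>%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median quantile rnorm runif rlnorm rbinom pchisq setNames
NULL

# Round half away from zero at `digits` decimals (printed tables use commercial
# rounding, which base round() does not).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` with a private RNG stream seeded by `seed`; the caller's
# .Random.seed is untouched.
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Parse FAERS-style dates with partial-date precision
#'
#' FAERS date fields are `YYYYMMDD` integers, but partial dates (`YYYY`,
#' `YYYYMM`) occur. Partial dates are anchored at the start of their period and
#' flagged with a coarser precision so that downstream consumers (notably
#' time-to-onset, which requires day precision) can filter on it.
#'
#' @param x Character vector of raw date strings.
#' @return A list with `date` (a `Date` vector, period start for partial dates)
#'   and `precision` (`"day"`, `"month"`, `"year"`, or `NA` when unparseable).
#' @examples
#' parse_faers_date(c("20200115", "202001", "2020", "bad"))
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA")] <- NA_character_
  nch <- nchar(x)
  digits_only <- !is.na(x) & grepl("^[0-9]+$", x)

  date <- as.Date(rep(NA, length(x)))
  precision <- rep(NA_character_, length(x))

  is_day <- digits_only & nch == 8
  is_month <- digits_only & nch == 6
  is_year <- digits_only & nch == 4

  date[is_day] <- as.Date(x[is_day], format = "%Y%m%d")
  date[is_month] <- as.Date(paste0(x[is_month], "01"), format = "%Y%m%d")
  date[is_year] <- as.Date(paste0(x[is_year], "0101"), format = "%Y%m%d")

  precision[is_day & !is.na(date)] <- "day"
  precision[is_month & !is.na(date)] <- "month"
  precision[is_year & !is.na(date)] <- "year"
  # dates that looked complete but failed (e.g. month 13) stay NA precision
  list(date = date, precision = precision)
}

# Inverse of parse_faers_date: format back at the recorded precision.
format_faers_date <- function(date, precision) {
  out <- rep(NA_character_, length(date))
  ok <- !is.na(date) & !is.na(precision)
  fmt <- c(day = "%Y%m%d", month = "%Y%m", year = "%Y")
  for (p in names(fmt)) {
    sel <- ok & precision == p
    out[sel] <- format(date[sel], fmt[[p]])
  }
  out
}

# FAERS age-unit codes -> years. Implausible ages (>120 y) become missing.
age_to_years <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(as.character(age_cod)))
  cod[is.na(cod) | cod == ""] <- "YR"
  div <- c(YR = 1, MON = 12, WK = 52.18, DY = 365.25, HR = 8766)
  yrs <- ifelse(cod == "DEC", age * 10,
         ifelse(cod %in% names(div), age / div[cod], NA_real_))
  yrs[!is.na(yrs) & (yrs < 0 | yrs > 120)] <- NA_real_
  yrs
}

# Weight -> kg; LBS converted, unknown unit codes treated as kg.
weight_to_kg <- function(wt, wt_cod) {
  wt <- suppressWarnings(as.numeric(wt))
  cod <- toupper(trimws(as.character(wt_cod)))
  ifelse(!is.na(cod) & cod == "LBS", wt * 0.453592, wt)
}
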