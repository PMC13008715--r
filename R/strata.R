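# Demographic summaries (per-drug category counts, ratios, shares, serious
# outcomes) and the sex-stratified reporting volcano analysis.

AGE_BANDS <- c("<18", "18-65", ">=65", "Unknown")
SERIOUS_OUTCOME_CODES <- c("DE", "LT", "DS", "RI")

age_band <- function(age_years) {
  out <- rep("Unknown", length(age_years))
  out[!is.na(age_years) & age_years < 18] <- "<18"
  out[!is.na(age_years) & age_years >= 18 & age_years < 65] <- "18-65"
  out[!is.na(age_years) & age_years >= 65] <- ">=65"
  out
}

#' Summarize report demographics per target drug
#'
#' Category counts and percentages (of the drug's report total, rounded
#' half-up to 2 decimals) for sex, age band (`<18`, `18-65`, `>=65` on age in
#' years), reporter occupation, outcome code, country, imputed route and
#' receipt year, plus median (IQR) age and weight. A case contributes to
#' every outcome code it carries, so outcome counts can exceed the case
#' count; every other variable partitions the drug's reports (with an
#' `Unknown` category).
#'
#' @param coded Coded-report tibble from [build_cohort()].
#' @param drugs Optional character vector restricting the summary to these
#'   target INNs (default: all target drugs present).
#' @return An object of class `demographic_summary`: a list with tibbles
#'   `totals` (`drug`, `n`), `counts` (`drug`, `variable`, `category`, `n`,
#'   `pct`) and `medians` (`drug`, `variable`, `median`, `q1`, `q3`).
#' @export
summarize_demographics <- function(coded, drugs = NULL) {
  tgt <- coded[!is.na(coded$target_drug), , drop = FALSE]
  if (!is.null(drugs)) tgt <- tgt[tgt$target_drug %in% tolower(drugs), , drop = FALSE]
  stopifnot(nrow(tgt) > 0)

  tgt$age_band <- age_band(tgt$age_years)
  base <- tibble(
    drug = tgt$target_drug,
    sex = ifelse(tgt$sex %in% c("F", "M"), tgt$sex, "Unknown"),
    age_band = tgt$age_band,
    reporter = ifelse(is.na(tgt$reporter) | tgt$reporter == "", "Unknown", tgt$reporter),
    country = ifelse(is.na(tgt$country) | tgt$country == "", "Unknown", tgt$country),
    route = ifelse(is.na(tgt$route_final), "Unknown", tgt$route_final),
    year = ifelse(is.na(tgt$year), "Unknown", as.character(tgt$year))
  )
  totals <- count(base, .data$drug, name = "n")

  count_var <- function(var) {
    base %>%
      count(.data$drug, category = .data[[var]], name = "n") %>%
      mutate(variable = var)
  }
  counts <- bind_rows(lapply(c("sex", "age_band", "reporter", "country",
                               "route", "year"), count_var))

  # outcomes: one contribution per code a case carries
  k <- lengths(tgt$outcomes)
  outc <- tibble(drug = rep(tgt$target_drug, k),
                 category = unlist(tgt$outcomes, use.names = FALSE)) %>%
    count(.data$drug, .data$category, name = "n") %>%
    mutate(variable = "outcome")
  counts <- bind_rows(counts, outc) %>%
    left_join(rename(totals, total = "n"), by = "drug") %>%
    mutate(pct = round_half_up(100 * .data$n / .data$total, 2)) %>%
    select(all_of(c("drug", "variable", "category", "n", "pct"))) %>%
    arrange(.data$drug, .data$variable, dplyr::desc(.data$n))

  med_var <- function(x, var) {
    tibble(drug = tgt$target_drug, value = x) %>%
      filter(!is.na(.data$value)) %>%
      group_by(.data$drug) %>%
      summarise(median = quantile(.data$value, 0.5, type = 7),
                q1 = quantile(.data$value, 0.25, type = 7),
                q3 = quantile(.data$value, 0.75, type = 7),
                .groups = "drop") %>%
      mutate(variable = var)
  }
  medians <- bind_rows(med_var(tgt$age_years, "age_years"),
                       med_var(tgt$weight_kg, "weight_kg")) %>%
    select(all_of(c("drug", "variable", "median", "q1", "q3")))

  structure(list(totals = totals, counts = counts, medians = medians),
            class = "demographic_summary")
}

#' Build a demographic summary from pre-aggregated counts
#'
#' Constructs the same object as [summarize_demographics()] from a long
#' count table (`drug`, `variable`, `category`, `n`), e.g. counts transcribed
#' from a published report table. Report totals are taken from rows with
#' `variable == "total"`.
#'
#' @param counts Long tibble (or CSV path) with columns `drug`, `variable`,
#'   `category`, `n`.
#' @return A `demographic_summary`.
#' @export
as_demographic_summary <- function(counts) {
  if (is.character(counts)) {
    counts <- readr::read_csv(counts, col_types = "cccd", progress = FALSE)
  }
  stopifnot(all(c("drug", "variable", "category", "n") %in% names(counts)))
  counts <- mutate(counts, drug = tolower(.data$drug), n = as.numeric(.data$n))
  totals <- counts %>%
    filter(.data$variable == "total") %>%
    select(all_of(c("drug", "n")))
  stopifnot(nrow(totals) > 0)
  rest <- counts %>%
    filter(.data$variable != "total") %>%
    left_join(rename(totals, total = "n"), by = "drug") %>%
    mutate(pct = round_half_up(100 * .data$n / .data$total, 2)) %>%
    select(all_of(c("drug", "variable", "category", "n", "pct")))
  structure(list(totals = totals, counts = rest,
                 medians = tibble(drug = character(), variable = character(),
                                  median = numeric(), q1 = numeric(), q3 = numeric())),
            class = "demographic_summary")
}

#' @export
print.demographic_summary <- function(x, ...) {
  cat("Demographic summary:", paste(x$totals$drug, collapse = ", "), "\n")
  print(x$totals)
  invisible(x)
}

#' @method tidy demographic_summary
#' @export
tidy.demographic_summary <- function(x, ...) x$counts

#' @method glance demographic_summary
#' @export
glance.demographic_summary <- function(x, ...) x$totals

get_counts <- function(summary, variable, drug = NULL) {
  stopifnot(inherits(summary, "demographic_summary"))
  out <- filter(summary$counts, .data$variable == !!variable)
  if (!is.null(drug)) out <- filter(out, .data$drug == tolower(!!drug))
  out
}

#' Serious-outcome total
#'
#' Sum of the death (`DE`), life-threatening (`LT`), disability (`DS`) and
#' required-intervention-to-prevent-permanent-damage (`RI`) outcome counts;
#' hospitalization, other-serious and congenital-anomaly counts are not
#' included in this total.
#'
#' @param summary A `demographic_summary`.
#' @param drug Optional single INN; default returns one value per drug.
#' @return Named numeric vector (or scalar when `drug` is given).
#' @export
serious_outcome_total <- function(summary, drug = NULL) {
  oc <- get_counts(summary, "outcome", drug)
  oc <- filter(oc, toupper(.data$category) %in% SERIOUS_OUTCOME_CODES)
  out <- oc %>% group_by(.data$drug) %>% summarise(n = sum(.data$n), .groups = "drop")
  res <- setNames(out$n, out$drug)
  if (!is.null(drug)) unname(res[tolower(drug)]) else res
}

#' Male-to-female reporting ratio
#'
#' The `x` of the ratio `1:x`, i.e. female count / male count, rounded
#' half-up to 2 decimals; Unknown-sex reports are excluded. With
#' `pooled = TRUE` the ratio is computed on the summed counts of all drugs
#' in the summary.
#'
#' @param summary A `demographic_summary`.
#' @param drug Optional single INN.
#' @param pooled Pool all drugs before taking the ratio.
#' @return Named numeric vector (or scalar). A drug with zero male reports
#'   yields `NA` with a warning.
#' @export
sex_ratio <- function(summary, drug = NULL, pooled = FALSE) {
  sx <- get_counts(summary, "sex", drug)
  tab <- sx %>%
    mutate(category = toupper(.data$category)) %>%
    filter(.data$category %in% c("F", "M", "FEMALE", "MALE")) %>%
    mutate(category = substr(.data$category, 1, 1))
  if (pooled) tab$drug <- "pooled"
  wide <- tab %>%
    group_by(.data$drug, .data$category) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n", values_fill = 0)
  for (cl in c("F", "M")) if (!cl %in% names(wide)) wide[[cl]] <- 0
  if (any(wide$M == 0)) warning("zero male reports; ratio undefined")
  res <- setNames(ifelse(wide$M > 0, round_half_up(wide$F / wide$M, 2), NA_real_),
                  wide$drug)
  if (!is.null(drug) && !pooled) unname(res[tolower(drug)]) else res
}

#' Per-drug share of pooled reports
#'
#' Each drug's report total as a percentage of the pooled total across all
#' drugs supplied, rounded half-up to 2 decimals.
#'
#' @param report_totals Named numeric vector of per-drug report counts, or a
#'   tibble with columns `drug`, `n`, or a `demographic_summary`.
#' @return A tibble with columns `drug`, `n`, `share`.
#' @export
drug_share <- function(report_totals) {
  if (inherits(report_totals, "demographic_summary")) report_totals <- report_totals$totals
  if (is.numeric(report_totals) && !is.null(names(report_totals))) {
    report_totals <- tibble(drug = names(report_totals), n = unname(report_totals))
  }
  stopifnot(is.data.frame(report_totals), all(c("drug", "n") %in% names(report_totals)))
  pooled <- sum(report_totals$n)
  if (pooled <= 0) stop("drug_share: pooled report total is zero", call. = FALSE)
  mutate(as_tibble(report_totals), share = round_half_up(100 * .data$n / pooled, 2))
}

#' Per-drug share of a pooled age band
#'
#' For one age band, each drug's count as a percentage of the band's pooled
#' count across drugs (e.g. "who contributes the 18-65-year-old reports"),
#' rounded half-up to 2 decimals.
#'
#' @param band_counts A `demographic_summary`, or a tibble with columns
#'   `drug`, `category`, `n` holding age-band counts.
#' @param band Band label: `"<18"`, `"18-65"` or `">=65"`.
#' @return A tibble with columns `drug`, `n`, `share`.
#' @export
age_band_share <- function(band_counts, band = "18-65") {
  if (inherits(band_counts, "demographic_summary")) {
    band_counts <- get_counts(band_counts, "age_band")
  }
  stopifnot(all(c("drug", "category", "n") %in% names(band_counts)))
  sel <- filter(as_tibble(band_counts), .data$category == !!band)
  pooled <- sum(sel$n)
  if (pooled <= 0) stop("age_band_share: pooled band count is zero", call. = FALSE)
  sel %>%
    mutate(share = round_half_up(100 * .data$n / pooled, 2)) %>%
    select(all_of(c("drug", "n", "share")))
}

#' Sex-stratified reporting volcano analysis
#'
#' For one target drug, compares female against male reporting of each PT
#' within the drug's own reports: the 2x2 table is (female vs male) x
#' (this PT vs any other event), the fold change is its odds ratio
#' (female-to-male reporting odds ratio), and the p-value comes from the
#' Yates-corrected chi-square. A PT is flagged female- or male-predominant
#' when `fc > 1.2` or `fc < 1/1.2` (strict) and `p < 0.05`. PTs with any
#' zero cell are skipped and tallied.
#'
#' @param coded Coded-report tibble from [build_cohort()].
#' @param drug Target INN.
#' @return A tibble of class `faers_volcano` with columns `drug`, `pt`,
#'   `n_female`, `n_male`, `fc`, `log2_fc`, `p_value`, `flagged_direction`
#'   (`"female"`, `"male"` or `"none"`); `attr(, "skipped_zero_cell")` counts
#'   skipped PTs.
#' @export
sex_stratified_volcano <- function(coded, drug) {
  drug <- tolower(drug)
  tgt <- coded[!is.na(coded$target_drug) & coded$target_drug == drug, , drop = FALSE]
  tgt <- tgt[tgt$sex %in% c("F", "M"), , drop = FALSE]
  stopifnot(nrow(tgt) > 0)
  n_f <- sum(tgt$sex == "F"); n_m <- sum(tgt$sex == "M")
  if (n_f == 0 || n_m == 0) stop("volcano needs reports of both sexes", call. = FALSE)

  k <- lengths(lapply(tgt$events, unique))
  long <- tibble(sex = rep(tgt$sex, k),
                 pt = unlist(lapply(tgt$events, unique), use.names = FALSE))
  tab <- long %>%
    count(.data$pt, .data$sex, name = "n") %>%
    tidyr::pivot_wider(names_from = "sex", values_from = "n", values_fill = 0) %>%
    rename(n_female = "F", n_male = "M")

  tab <- mutate(tab,
                f_other = n_f - .data$n_female,
                m_other = n_m - .data$n_male)
  zero <- tab$n_female == 0 | tab$n_male == 0 | tab$f_other == 0 | tab$m_other == 0
  skipped <- sum(zero)
  tab <- tab[!zero, , drop = FALSE]

  cells <- tibble(a = tab$n_female, b = tab$n_male, c = tab$f_other, d = tab$m_other)
  fc <- (cells$a * cells$d) / (cells$b * cells$c)
  chi2 <- compute_chi2(cells, correct = TRUE)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  dir <- ifelse((fc > 1.2 | fc < 1 / 1.2) & p < 0.05,
                ifelse(fc > 1, "female", "male"), "none")

  out <- tibble(drug = drug, pt = tab$pt,
                n_female = tab$n_female, n_male = tab$n_male,
                fc = fc, log2_fc = log2(fc), p_value = p,
                flagged_direction = dir) %>%
    arrange(.data$p_value, .data$pt)
  structure(out, class = c("faers_volcano", class(out)),
            skipped_zero_cell = skipped)
}

#' Plot a sex-stratified volcano
#'
#' log2 female-to-male reporting odds ratio against -log10 p, with the
#' conventional fold-change and significance guides.
#'
#' @param object A `faers_volcano` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot faers_volcano
#' @export
autoplot.faers_volcano <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc, y = -log10(.data$p_value),
                                   colour = .data$flagged_direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-log2(1.2), log2(1.2)), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(female = "#c2185b", male = "#1565c0",
                                            none = "grey60")) +
    ggplot2::labs(x = "log2 female-to-male reporting OR", y = "-log10 p",
                  colour = "predominance") +
    ggplot2::theme_minimal()
}
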