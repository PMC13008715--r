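# Time-to-onset (TTO): days from therapy start to adverse-event onset,
# binned as in the reporting tables, with median/IQR summaries.

TTO_EDGES <- c(0, 31, 61, 91, 121, 151, 181, 361, Inf)
TTO_LABELS <- c("0\u201331", "31\u201361", "61\u201391", "91\u2013121",
                "121\u2013150", "151\u2013181", "181\u2013361", ">=361")
TTO_UNKNOWN <- "Unknown"

#' Bin a known time-to-onset in days
#'
#' Half-open bins with edges 0, 31, 61, 91, 121, 151, 181, 361, Inf; the
#' printed labels are kept even where they overlap at the boundaries
#' (e.g. day 150 falls in `[121, 151)` and is labelled `"121-150"`; day 361
#' falls in `[361, Inf)`, labelled `">=361"`).
#'
#' @param tto_days Non-negative integer vector of known onset delays.
#' @return Character vector of bin labels.
#' @export
bin_tto <- function(tto_days) {
  stopifnot(all(is.na(tto_days) | tto_days >= 0))
  idx <- findInterval(tto_days, TTO_EDGES, rightmost.closed = FALSE)
  out <- TTO_LABELS[idx]
  out[is.na(tto_days)] <- TTO_UNKNOWN
  out
}

#' Compute time-to-onset per coded report
#'
#' TTO is the difference in days between the case's event onset date and the
#' earliest day-precise therapy start date for the target drug. If either
#' date is missing or imprecise (month- or year-level), or the difference is
#' negative (event recorded before therapy start), the record is `Unknown`.
#'
#' @param coded Coded-report tibble from [build_cohort()] (rows with a
#'   `target_drug`; background rows are ignored).
#' @return A tibble with one row per target report: `caseid`, `drug`,
#'   `tto_days` (`NA` when unknown) and `bin_label`.
#' @export
compute_tto <- function(coded) {
  tgt <- coded[!is.na(coded$target_drug), , drop = FALSE]

  start <- mapply(function(drugs, ther, dg) {
    if (is.null(ther) || nrow(ther) == 0) return(NA_real_)
    seqs <- NULL
    if (!is.null(drugs) && nrow(drugs) > 0 && "drug_seq" %in% names(drugs)) {
      seqs <- drugs$drug_seq[tolower(drugs$drug_name) == dg &
                               !is.na(drugs$role) & toupper(drugs$role) == "PS"]
    }
    rows <- ther
    if (length(seqs) && !all(is.na(ther$drug_seq))) {
      rows <- ther[ther$drug_seq %in% seqs, , drop = FALSE]
    }
    ok <- !is.na(rows$start_dt) & !is.na(rows$start_dt_precision) &
      rows$start_dt_precision == "day"
    if (!any(ok)) return(NA_real_)
    min(as.numeric(rows$start_dt[ok]))
  }, tgt$drugs, tgt$therapy, tgt$target_drug, USE.NAMES = FALSE)

  event_ok <- !is.na(tgt$event_dt) & !is.na(tgt$event_dt_precision) &
    tgt$event_dt_precision == "day"
  tto <- as.numeric(tgt$event_dt) - start
  tto[!event_ok | is.na(start)] <- NA_real_
  tto[!is.na(tto) & tto < 0] <- NA_real_

  tibble(caseid = tgt$caseid, drug = tgt$target_drug,
         tto_days = tto, bin_label = bin_tto(tto))
}

#' Summarize time-to-onset records
#'
#' Median and quartiles (linear interpolation, `stats::quantile` type 7) over
#' the known onset delays, per-bin counts and percentages (of all records,
#' Unknown included), and the fraction of known delays of at least 361 days.
#'
#' @param records Tibble from [compute_tto()]; if a `drug` column is present
#'   the summary is per drug.
#' @return An object of class `tto_summary`: a list with tibbles `stats`
#'   (`drug`, `n_known`, `n_unknown`, `median`, `q1`, `q3`, `frac_ge_361`)
#'   and `bins` (`drug`, `bin_label`, `n`, `pct`).
#' @export
summarize_tto <- function(records) {
  stopifnot(nrow(records) >= 1)
  if (!"drug" %in% names(records)) records$drug <- "all"

  one <- function(x) {
    known <- x$tto_days[!is.na(x$tto_days)]
    qs <- if (length(known)) unname(quantile(known, c(0.25, 0.5, 0.75), type = 7))
          else rep(NA_real_, 3)
    tibble(n_known = length(known), n_unknown = sum(is.na(x$tto_days)),
           median = qs[2], q1 = qs[1], q3 = qs[3],
           frac_ge_361 = if (length(known)) mean(known >= 361) else NA_real_)
  }
  stats <- records %>%
    group_by(.data$drug) %>%
    dplyr::group_modify(~one(.x)) %>%
    ungroup()

  all_bins <- c(TTO_LABELS, TTO_UNKNOWN)
  bins <- records %>%
    mutate(bin_label = factor(.data$bin_label, levels = all_bins)) %>%
    count(.data$drug, .data$bin_label, .drop = FALSE, name = "n") %>%
    group_by(.data$drug) %>%
    mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 2)) %>%
    ungroup() %>%
    mutate(bin_label = as.character(.data$bin_label))

  structure(list(stats = stats, bins = bins), class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat("Time-to-onset summary\n")
  print(x$stats)
  invisible(x)
}

#' @method tidy tto_summary
#' @export
tidy.tto_summary <- function(x, ...) x$bins

#' @method glance tto_summary
#' @export
glance.tto_summary <- function(x, ...) x$stats

#' Plot the time-to-onset bin distribution
#'
#' @param object A `tto_summary`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-bin percentages, faceted by drug.
#' @method autoplot tto_summary
#' @export
autoplot.tto_summary <- function(object, ...) {
  df <- object$bins
  df$bin_label <- factor(df$bin_label, levels = c(TTO_LABELS, TTO_UNKNOWN))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_label, y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~drug) +
    ggplot2::labs(x = "time to onset (days)", y = "% of reports") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
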