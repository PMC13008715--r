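# Label-novelty assessment: consensus-positive terms absent from every
# supplied product-label PT list are candidate new signals.

#' Assess label novelty of scan-positive terms
#'
#' A PT's verdict is `"Y"` (novel) iff it is absent from every supplied
#' product-label PT list AND at least two of the four algorithms flagged it
#' for at least one drug; otherwise `"N"`. Label lists are pre-flattened by
#' the user across all label sections (boxed warnings through post-marketing
#' experience); a term mentioned only as an indication counts as already
#' occurred, so the user keeps such terms in the label list and they yield
#' `"N"`.
#'
#' @param signal_results A PT-level [run_signal_scan()] result (or any tibble
#'   with `term`, `drug`, `a`, `n_algorithms_positive` columns).
#' @param labels Label list: tibble with columns `drug`, `pt` (one row per
#'   PT present on that drug's label), or a CSV path for [read_label_list()].
#' @return A tibble with one row per scanned PT: `pt`, `total_reports`,
#'   one `label_<drug>` presence column (`"Y"`/`"N"`) per drug in `labels`,
#'   `consensus_any`, and `novel` (`"Y"`/`"N"`), ordered by total reports.
#' @export
assess_novelty <- function(signal_results, labels) {
  if (is.character(labels)) labels <- read_label_list(labels)
  stopifnot(all(c("drug", "pt") %in% names(labels)))
  res <- as_tibble(signal_results)
  stopifnot(all(c("term", "a", "n_algorithms_positive") %in% names(res)))

  label_drugs <- sort(unique(labels$drug))
  per_pt <- res %>%
    group_by(pt = .data$term) %>%
    summarise(total_reports = sum(.data$a),
              consensus_any = any(.data$n_algorithms_positive >= 2L),
              .groups = "drop")

  on_label <- lapply(label_drugs, function(dg) {
    per_pt$pt %in% labels$pt[labels$drug == dg]
  })
  names(on_label) <- paste0("label_", label_drugs)
  for (nm in names(on_label)) per_pt[[nm]] <- ifelse(on_label[[nm]], "Y", "N")

  any_label <- Reduce(`|`, on_label, rep(FALSE, nrow(per_pt)))
  per_pt$novel <- ifelse(!any_label & per_pt$consensus_any, "Y", "N")
  arrange(per_pt, dplyr::desc(.data$total_reports), .data$pt)
}
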