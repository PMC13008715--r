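# The four disproportionality statistics on 2x2 contingency tables, threshold
# presets, and the scan over all drug-event pairs.
#
# Notation for one drug-event pair, counting deduplicated case reports:
#   a = target-drug reports with the event      b = comparator reports with it
#   c = target-drug reports without the event   d = comparator reports without
# The comparator is the full database minus the target drugs.

#' Prior constants for the BCPNN information component
#'
#' The information component's posterior moments use a Dirichlet-style prior
#' with constants alpha, beta (margins), alpha1, beta1, gamma11 (joint), and
#' a derived gamma chosen so the prior is consistent with the margins:
#' `gamma = gamma11 * (n+alpha)(n+beta) / ((a+b+alpha1)(a+c+beta1))`.
#' The defaults (2, 2, 1, 1, 1) are the customary choice.
#'
#' @param alpha,beta,alpha1,beta1,gamma11 Positive reals.
#' @return A named list of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(alpha = 2, beta = 2, alpha1 = 1, beta1 = 1, gamma11 = 1) {
  stopifnot(alpha > 0, beta > 0, alpha1 > 0, beta1 > 0, gamma11 > 0)
  structure(list(alpha = alpha, beta = beta, alpha1 = alpha1,
                 beta1 = beta1, gamma11 = gamma11),
            class = "bcpnn_priors")
}

#' Signal-threshold presets
#'
#' Two named presets are shipped because screening rules are stated in two
#' common forms in the pharmacovigilance literature:
#' * `"methods_text"` (default): ROR 95% CI lower bound > 1; PRR 95% CI lower
#'   bound > 1; IC025 > 0; EBGM05 > 0 — no point-estimate floors.
#' * `"table2"`: ROR >= 3 with CI lower bound > 1; PRR >= 2 with CI lower
#'   bound > 1; IC025 > 0; EBGM05 > 2.
#'
#' A positive consensus signal requires at least two of the four algorithms
#' to flag the pair.
#'
#' @param preset `"methods_text"` or `"table2"`.
#' @param min_case_count Minimum report count `a` for any flag (default 1;
#'   3 is a customary stricter choice).
#' @param ... Named overrides of individual rule parameters
#'   (`ror_point_min`, `ror_ci_low_min`, `prr_point_min`, `prr_ci_low_min`,
#'   `ic025_min`, `ebgm05_min`).
#' @return A list of class `signal_thresholds`.
#' @export
signal_thresholds <- function(preset = c("methods_text", "table2"),
                              min_case_count = 1, ...) {
  preset <- match.arg(preset)
  th <- switch(preset,
    methods_text = list(ror_point_min = -Inf, ror_ci_low_min = 1,
                        prr_point_min = -Inf, prr_ci_low_min = 1,
                        ic025_min = 0, ebgm05_min = 0),
    table2 = list(ror_point_min = 3, ror_ci_low_min = 1,
                  prr_point_min = 2, prr_ci_low_min = 1,
                  ic025_min = 0, ebgm05_min = 2)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(th))
  if (length(bad)) stop("unknown threshold parameter(s): ", paste(bad, collapse = ", "))
  th[names(dots)] <- dots
  th$preset <- preset
  th$min_case_count <- min_case_count
  structure(th, class = "signal_thresholds")
}

check_cells <- function(t) {
  stopifnot(is.data.frame(t), all(c("a", "b", "c", "d") %in% names(t)))
  for (cl in c("a", "b", "c", "d")) t[[cl]] <- as.double(t[[cl]])  # avoid int overflow
  with(t, stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0)))
  t
}

#' Reporting odds ratio with 95% CI
#'
#' `ROR = ad / bc`, with Wald interval
#' `exp(log ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param t Data frame with numeric columns `a`, `b`, `c`, `d` (one row per
#'   2x2 table; all statistics are vectorized over rows).
#' @param zero_cell `"missing"` (default) reports the statistic as `NA` when
#'   any cell is zero; `"haldane"` applies the Haldane-Anscombe +0.5
#'   continuity correction to all four cells instead.
#' @return A tibble with columns `ror`, `ror_low`, `ror_high`.
#' @export
compute_ror <- function(t, zero_cell = c("missing", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  t <- check_cells(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (zero_cell == "haldane") {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero; c <- c + 0.5 * zero; d <- d + 0.5 * zero
    zero <- rep(FALSE, length(a))
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  low <- exp(log(ror) - 1.96 * se)
  high <- exp(log(ror) + 1.96 * se)
  ror[zero] <- NA_real_; low[zero] <- NA_real_; high[zero] <- NA_real_
  tibble(ror = ror, ror_low = low, ror_high = high)
}

#' Proportional reporting ratio with 95% CI
#'
#' `PRR = a(c+d) / (c(a+b))`, with
#' `SE(log PRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`.
#'
#' @inheritParams compute_ror
#' @return A tibble with columns `prr`, `prr_low`, `prr_high`.
#' @export
compute_prr <- function(t, zero_cell = c("missing", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  t <- check_cells(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  bad <- a == 0 | c == 0 | (a + b) == 0 | (c + d) == 0
  if (zero_cell == "haldane") {
    zero <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * zero; b <- b + 0.5 * zero; c <- c + 0.5 * zero; d <- d + 0.5 * zero
    bad <- rep(FALSE, length(a))
  }
  prr <- (a * (c + d)) / (c * (a + b))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  low <- exp(log(prr) - 1.96 * se)
  high <- exp(log(prr) + 1.96 * se)
  prr[bad] <- NA_real_; low[bad] <- NA_real_; high[bad] <- NA_real_
  tibble(prr = prr, prr_low = low, prr_high = high)
}

#' Chi-square statistic for the 2x2 table
#'
#' Yates-corrected Pearson statistic (the customary choice in spontaneous-
#' report disproportionality work):
#' `n (|ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, clamped at 0 when
#' `|ad - bc| <= n/2`. Plain (uncorrected) Pearson is available via
#' `correct = FALSE`.
#'
#' @inheritParams compute_ror
#' @param correct Apply the Yates continuity correction (default `TRUE`).
#' @return Numeric vector of chi-square values (`NA` where a margin is zero).
#' @export
compute_chi2 <- function(t, correct = TRUE) {
  t <- check_cells(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  dev <- abs(a * d - b * c)
  if (correct) dev <- pmax(dev - n / 2, 0)
  chi2 <- n * dev^2 / denom
  chi2[denom == 0] <- NA_real_
  chi2
}

#' BCPNN information component with posterior uncertainty
#'
#' The information component is the log2 observed/expected reporting ratio
#' `IC = log2( a n / ((a+b)(a+c)) )`. Its Bayesian posterior moments under
#' the Dirichlet-style prior of [bcpnn_priors()] are
#' `E(IC) = log2[ (a+g11)(n+alpha)(n+beta) / ((n+gamma)(a+b+alpha1)(a+c+beta1)) ]`
#' and
#' `V(IC) = (1/ln^2 2) * [ (n-a+gamma-g11)/((a+g11)(1+n+gamma))`
#' ` + (n-(a+b)+alpha-alpha1)/((a+b+alpha1)(1+n+alpha))`
#' ` + (n-(a+c)+beta-beta1)/((a+c+beta1)(1+n+beta)) ]`,
#' and the reported lower bound is `IC025 = E(IC) - 2 sqrt(V(IC))` (the
#' two-standard-deviation form, emitted under the conventional IC025 name).
#'
#' @inheritParams compute_ror
#' @param priors A [bcpnn_priors()] object.
#' @return A tibble with columns `ic`, `e_ic`, `v_ic`, `ic025`. With `a = 0`
#'   the observed `ic` is `-Inf` while the posterior moments remain defined.
#' @export
compute_bcpnn <- function(t, priors = bcpnn_priors()) {
  t <- check_cells(t)
  stopifnot(inherits(priors, "bcpnn_priors"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  al <- priors$alpha; be <- priors$beta
  al1 <- priors$alpha1; be1 <- priors$beta1; g11 <- priors$gamma11

  ic <- log2(a * n / ((a + b) * (a + c)))
  gam <- g11 * (n + al) * (n + be) / ((a + b + al1) * (a + c + be1))
  e_ic <- log2((a + g11) * (n + al) * (n + be) /
                 ((n + gam) * (a + b + al1) * (a + c + be1)))
  v_ic <- (1 / log(2)^2) * (
    (n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
    (n - (a + b) + al - al1) / ((a + b + al1) * (1 + n + al)) +
    (n - (a + c) + be - be1) / ((a + c + be1) * (1 + n + be))
  )
  bad <- n == 0
  ic[bad] <- NA_real_; e_ic[bad] <- NA_real_; v_ic[bad] <- NA_real_
  tibble(ic = ic, e_ic = e_ic, v_ic = v_ic, ic025 = e_ic - 2 * sqrt(v_ic))
}

#' Closed-form empirical Bayes geometric mean with 95% CI
#'
#' The simplified closed-form EBGM
#' `EBGM = a n / ((a+c)(a+b))` (the observed/expected reporting ratio, so
#' that `EBGM = 2^IC` exactly), with Wald interval
#' `exp(log EBGM +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. This is the ratio
#' form, not the DuMouchel gamma-mixture fit.
#'
#' @inheritParams compute_ror
#' @return A tibble with columns `ebgm`, `ebgm05`, `ebgm95` (CI `NA` where a
#'   cell is zero unless `zero_cell = "haldane"`).
#' @export
compute_ebgm <- function(t, zero_cell = c("missing", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  t <- check_cells(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  ebgm <- a * n / ((a + c) * (a + b))
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  aa <- a; bb <- b; cc <- c; dd <- d
  if (zero_cell == "haldane") {
    aa <- a + 0.5 * zero; bb <- b + 0.5 * zero; cc <- c + 0.5 * zero; dd <- d + 0.5 * zero
    ebgm <- aa * (aa + bb + cc + dd) / ((aa + cc) * (aa + bb))
    zero <- rep(FALSE, length(a))
  }
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  low <- exp(log(ebgm) - 1.96 * se)
  high <- exp(log(ebgm) + 1.96 * se)
  bad0 <- (a + b) == 0 | (a + c) == 0
  ebgm[bad0] <- NA_real_
  low[zero | bad0] <- NA_real_; high[zero | bad0] <- NA_real_
  tibble(ebgm = ebgm, ebgm05 = low, ebgm95 = high)
}

#' All four statistics for a set of 2x2 tables
#'
#' @inheritParams compute_ror
#' @inheritParams compute_bcpnn
#' @inheritParams compute_chi2
#' @return The input with columns `ror`, `ror_low`, `ror_high`, `prr`,
#'   `prr_low`, `prr_high`, `chi2`, `ic`, `e_ic`, `v_ic`, `ic025`, `ebgm`,
#'   `ebgm05`, `ebgm95` appended.
#' @export
signal_stats <- function(t, priors = bcpnn_priors(),
                         zero_cell = c("missing", "haldane"), correct = TRUE) {
  zero_cell <- match.arg(zero_cell)
  dplyr::bind_cols(
    as_tibble(t),
    compute_ror(t, zero_cell),
    compute_prr(t, zero_cell),
    tibble(chi2 = compute_chi2(t, correct)),
    compute_bcpnn(t, priors),
    compute_ebgm(t, zero_cell)
  )
}

#' Build one 2x2 contingency table
#'
#' Counts deduplicated case reports for a (drug, term) pair against the
#' full-database comparator: `a`/`c` come from reports whose primary suspect
#' is `drug`; `b`/`d` from reports whose primary suspect is none of the
#' target drugs (reports PS for another target are excluded from the
#' comparator). The counting unit is the case: at PT level a case with a PT
#' listed twice counts once, and at SOC level a case contributes once per
#' SOC however many of its PTs fall in it.
#'
#' @param coded_reports Coded-report tibble from [build_cohort()], spanning
#'   target and background reports.
#' @param drug Target INN.
#' @param event PT (or SOC) string.
#' @param level `"PT"` or `"SOC"`.
#' @return One-row tibble with columns `drug`, `level`, `event`, `a`, `b`,
#'   `c`, `d`, `n`.
#' @export
build_contingency <- function(coded_reports, drug, event, level = c("PT", "SOC")) {
  level <- match.arg(level)
  drug <- tolower(drug)
  tgt <- coded_reports[!is.na(coded_reports$target_drug) &
                         coded_reports$target_drug == drug, , drop = FALSE]
  if (nrow(tgt) == 0) stop("empty cohort: no reports with primary suspect '",
                           drug, "'", call. = FALSE)
  bg <- coded_reports[is.na(coded_reports$target_drug), , drop = FALSE]

  terms_of <- function(row_events, row_socs) {
    if (level == "PT") unique(row_events) else unique(row_socs)
  }
  has_term <- function(x) {
    ev <- x$events
    sc <- if ("event_soc" %in% names(x)) x$event_soc else vector("list", nrow(x))
    vapply(seq_len(nrow(x)),
           function(i) event %in% terms_of(ev[[i]], sc[[i]]), logical(1))
  }
  a <- sum(has_term(tgt)); c_ <- nrow(tgt) - a
  b <- sum(has_term(bg)); d <- nrow(bg) - b
  tibble(drug = drug, level = level, event = event,
         a = a, b = b, c = c_, d = d, n = a + b + c_ + d)
}

# Long (case, term) pairs at the requested level, one row per distinct pair.
events_long <- function(coded, level = c("PT", "SOC")) {
  level <- match.arg(level)
  src <- if (level == "PT") coded$events else coded$event_soc
  if (level == "SOC" && is.null(src)) {
    stop("SOC-level counting needs event_soc; supply a PT dictionary to build_cohort()",
         call. = FALSE)
  }
  src <- lapply(src, unique)
  k <- lengths(src)
  tibble(
    row = rep(seq_len(nrow(coded)), k),
    target_drug = rep(coded$target_drug, k),
    term = unlist(src, use.names = FALSE)
  )
}

#' Evaluate per-algorithm flags and the two-of-four consensus
#'
#' Applies the active threshold preset to computed statistics. A missing
#' statistic never counts as positive. The consensus flag is set when at
#' least two of the four algorithms are positive.
#'
#' @param results Tibble with the statistic columns from [signal_stats()]
#'   (and `a` for the minimum-case-count gate).
#' @param thresholds A [signal_thresholds()] object.
#' @return `results` with logical columns `flag_ror`, `flag_prr`, `flag_ic`,
#'   `flag_ebgm`, integer `n_algorithms_positive`, and logical `consensus`.
#' @export
evaluate_signal <- function(results, thresholds = signal_thresholds()) {
  stopifnot(inherits(thresholds, "signal_thresholds"))
  pos <- function(x, op, cut) !is.na(x) & op(x, cut)
  gate <- !is.na(results$a) & results$a >= thresholds$min_case_count
  results$flag_ror <- gate &
    pos(results$ror, `>=`, thresholds$ror_point_min) &
    pos(results$ror_low, `>`, thresholds$ror_ci_low_min)
  results$flag_prr <- gate &
    pos(results$prr, `>=`, thresholds$prr_point_min) &
    pos(results$prr_low, `>`, thresholds$prr_ci_low_min)
  results$flag_ic <- gate & pos(results$ic025, `>`, thresholds$ic025_min)
  results$flag_ebgm <- gate & pos(results$ebgm05, `>`, thresholds$ebgm05_min)
  results$n_algorithms_positive <- results$flag_ror + results$flag_prr +
    results$flag_ic + results$flag_ebgm
  results$consensus <- results$n_algorithms_positive >= 2L
  results
}

#' Scan all drug-event pairs for disproportionality signals
#'
#' For every target drug and every term with at least one target report,
#' builds the 2x2 table against the full-database comparator, computes the
#' four statistics, and applies the threshold preset. Results are ordered by
#' report count (descending) with lexicographic term order as the
#' deterministic tie-break.
#'
#' @inheritParams build_contingency
#' @param level `"PT"` or `"SOC"`.
#' @param thresholds A [signal_thresholds()] object.
#' @param priors A [bcpnn_priors()] object.
#' @param zero_cell Zero-cell handling passed to the statistics.
#' @return A tibble of class `faers_scan`: one row per (drug, term) with the
#'   counts, statistics, flags and consensus. Scan metadata (level, preset,
#'   cohort sizes) is attached as attributes and surfaced by
#'   [glance.faers_scan()].
#' @export
run_signal_scan <- function(coded_reports, level = c("PT", "SOC"),
                            thresholds = signal_thresholds(),
                            priors = bcpnn_priors(),
                            zero_cell = c("missing", "haldane")) {
  level <- match.arg(level)
  zero_cell <- match.arg(zero_cell)
  targets <- attr(coded_reports, "targets") %||%
    sort(unique(coded_reports$target_drug[!is.na(coded_reports$target_drug)]))

  long <- events_long(coded_reports, level)
  is_tgt <- !is.na(long$target_drug)
  bg_rows <- which(is.na(coded_reports$target_drug))
  n_bg <- length(bg_rows)
  bg_counts <- count(long[!is_tgt, ], .data$term, name = "b")

  pieces <- lapply(targets, function(dg) {
    sel <- is_tgt & long$target_drug == dg
    n_tgt <- sum(!is.na(coded_reports$target_drug) & coded_reports$target_drug == dg)
    if (n_tgt == 0) return(NULL)
    ac <- count(long[sel, ], .data$term, name = "a")
    tab <- left_join(ac, bg_counts, by = "term")
    tab$b[is.na(tab$b)] <- 0L
    mutate(tab, drug = dg, level = level,
           c = n_tgt - .data$a, d = n_bg - .data$b,
           n = .data$a + .data$b + .data$c + .data$d)
  })
  tab <- bind_rows(pieces)
  if (nrow(tab) == 0) {
    stop("empty cohort: no target reports in scan", call. = FALSE)
  }
  tab <- select(tab, all_of(c("drug", "level", "term", "a", "b", "c", "d", "n")))
  res <- signal_stats(tab, priors = priors, zero_cell = zero_cell)
  res <- evaluate_signal(res, thresholds)
  res <- arrange(res, .data$drug, dplyr::desc(.data$a), .data$term)
  structure(res,
            class = c("faers_scan", class(res)),
            thresholds = thresholds, priors = priors, level = level,
            n_background = n_bg)
}

#' @method tidy faers_scan
#' @export
tidy.faers_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "faers_scan")
  for (at in c("thresholds", "priors", "level", "n_background")) {
    attr(out, at) <- NULL
  }
  as_tibble(out)
}

#' @method glance faers_scan
#' @export
glance.faers_scan <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(
    level = attr(x, "level"),
    preset = th$preset,
    n_pairs = nrow(x),
    n_consensus = sum(x$consensus, na.rm = TRUE),
    n_background = attr(x, "n_background")
  )
}

#' Plot a signal scan
#'
#' Observed information component against report count, highlighting
#' consensus-positive pairs, faceted by drug.
#'
#' @param object A `faers_scan` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot faers_scan
#' @export
autoplot.faers_scan <- function(object, ...) {
  df <- tidy.faers_scan(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ic, y = .data$a,
                                   colour = .data$consensus)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~drug) +
    ggplot2::labs(x = "information component (log2 O/E)",
                  y = "case reports", colour = ">=2 algorithms") +
    ggplot2::theme_minimal()
}
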