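#' Reporting odds ratio with log-Wald 95% confidence interval
#'
#' The disproportionality statistic of the pipeline. For a 2x2 drug-event
#' contingency table with cells `a` (exposed, event), `b` (exposed, no
#' event), `c` (non-exposed, event), `d` (non-exposed, no event):
#' `ROR = (a*d) / (b*c)`, with
#' `95% CI = exp(log(ROR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' When any cell is zero the Haldane-Anscombe continuity correction (0.5
#' added to all four cells) is applied first and flagged in the output; the
#' estimate then stays finite without touching non-degenerate tables.
#'
#' All four arguments are vectorized and recycled to a common length.
#'
#' @param a,b,c,d non-negative integer cell counts; `a + b` (exposed margin)
#'   and `c + d` (non-exposed margin) must be positive.
#' @param conf_z normal quantile for the interval (default 1.96, a two-sided
#'   95% interval).
#' @return tibble with columns `a`, `b`, `c`, `d` (as supplied), `corrected`,
#'   `ror`, `ci_low`, `ci_high`.
#' @export
ror_estimate <- function(a, b, c, d, conf_z = 1.96) {
  k <- vctrs::vec_recycle_common(a = a, b = b, c = c, d = d)
  a <- k$a; b <- k$b; c <- k$c; d <- k$d
  cells <- cbind(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stopf("contingency cells must be non-negative and complete")
  }
  if (any(a + b == 0) || any(c + d == 0)) {
    stopf("undefined stratum: an exposure margin is zero")
  }
  corrected <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  off <- ifelse(corrected, 0.5, 0)
  aa <- a + off; bb <- b + off; cc <- c + off; dd <- d + off
  ror <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  tibble(
    a = a, b = b, c = c, d = d, corrected = corrected, ror = ror,
    ci_low = exp(log(ror) - conf_z * se),
    ci_high = exp(log(ror) + conf_z * se)
  )
}

# map reactions to case-level event terms at a hierarchy level; a case counts
# once per term no matter how many of its PTs map there
case_events_at_level <- function(x, dictionary, level) {
  ev <- distinct(x$reactions, .data$case_id, .data$pt)
  if (level == "PT") {
    ev <- semi_join(ev, dictionary, by = "pt") %>% rename(term = "pt")
  } else {
    col <- if (level == "HLGT") "hlgt" else "soc"
    ev <- ev %>%
      inner_join(dictionary[, c("pt", col)], by = "pt") %>%
      transmute(.data$case_id, term = .data[[col]])
  }
  distinct(ev, .data$case_id, .data$term)
}

#' Build one drug-event contingency table
#'
#' Counts cases, not reactions: a case contributes once to the event side of
#' the table if at least one of its reaction PTs maps to `term` at the
#' requested level, however many do. The comparator stratum is every case not
#' in the exposure stratum, so `a + b + c + d` equals the total case count.
#'
#' @param x a classified `report_set` (see [classify_exposure()]).
#' @param exposure an exposure category present in the data, or `"all_fq"`
#'   for the pooled any-fluoroquinolone stratum.
#' @param term a term existing at `level` in the dictionary.
#' @param level `"PT"`, `"HLGT"` or `"SOC"`.
#' @param dictionary a `term_dictionary`.
#' @return one-row tibble with columns `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(x, exposure, term, level = "PT",
                              dictionary = default_dictionary()) {
  level <- match.arg(level, pv_hierarchy_levels)
  if (!"exposure_category" %in% names(x$cases)) {
    stopf("reports must be classified first; run classify_exposure()")
  }
  known <- switch(level, PT = dictionary$pt, HLGT = dictionary$hlgt,
                  SOC = dictionary$soc)
  if (!term %in% known) stopf("unknown %s term: %s", level, term)
  ev <- case_events_at_level(x, dictionary, level)
  has_event <- x$cases$case_id %in% ev$case_id[ev$term == term]
  in_stratum <- if (identical(exposure, "all_fq")) {
    x$cases$exposure_category != "non_fq"
  } else {
    x$cases$exposure_category == exposure
  }
  tibble(
    a = sum(in_stratum & has_event),
    b = sum(in_stratum & !has_event),
    c = sum(!in_stratum & has_event),
    d = sum(!in_stratum & !has_event)
  )
}

#' Apply the signal rule to screened estimates
#'
#' A drug-event pair is a signal when the ROR exceeds 1, the lower bound of
#' its 95% confidence interval exceeds 1, and at least `min_cases` exposed
#' event cases were reported.
#'
#' @param ror,ci_low,n_cases vectors (recycled).
#' @param min_cases minimum exposed event-case count (default 3).
#' @return logical vector.
#' @export
evaluate_signal <- function(ror, ci_low, n_cases, min_cases = 3) {
  ror > 1 & ci_low > 1 & n_cases >= min_cases
}

#' Screen every exposure/term pair for disproportionate reporting
#'
#' Builds the full set of contingency tables at the requested hierarchy
#' levels for each mutually exclusive exposure category present in the data
#' (plus the pooled `"all_fq"` stratum), estimates RORs with 95% Wald
#' intervals, applies the signal rule, and drops rows with fewer than
#' `min_cases` exposed event cases (the display rule: pairs with under three
#' reports are not shown). No multiplicity adjustment is applied to the
#' screen itself.
#'
#' @param x a classified `report_set`.
#' @param dictionary a `term_dictionary`.
#' @param levels subset of `c("PT", "HLGT", "SOC")`.
#' @param exposures exposure categories to screen; default every category
#'   present except the `"non_fq"` comparator.
#' @param min_cases display threshold on `a` (default 3).
#' @param include_all_fq also emit pooled any-FQ rows (default `TRUE`).
#' @return a `pv_signals` tibble: `exposure`, `level`, `term`, `a`, `b`, `c`,
#'   `d`, `corrected`, `ror`, `ci_low`, `ci_high`, `n_cases`, `is_signal`,
#'   sorted by level then descending ROR.
#' @export
screen_signals <- function(x, dictionary = default_dictionary(),
                           levels = pv_hierarchy_levels, exposures = NULL,
                           min_cases = 3, include_all_fq = TRUE) {
  levels <- match.arg(levels, pv_hierarchy_levels, several.ok = TRUE)
  if (!"exposure_category" %in% names(x$cases)) {
    stopf("reports must be classified first; run classify_exposure()")
  }
  n_total <- n_cases(x)
  strata <- x$cases %>% count(exposure = .data$exposure_category, name = "n_stratum")
  if (is.null(exposures)) {
    exposures <- setdiff(strata$exposure, "non_fq")
  }
  out <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    lev <- levels[[li]]
    ev <- case_events_at_level(x, dictionary, lev)
    ev <- left_join(ev,
                    x$cases[, c("case_id", "exposure_category")],
                    by = "case_id")
    term_totals <- count(ev, .data$term, name = "n_event")
    a_tab <- count(ev, .data$term, exposure = .data$exposure_category, name = "a")
    rows <- a_tab %>% filter(.data$exposure %in% exposures)
    if (include_all_fq) {
      pooled <- ev %>%
        filter(.data$exposure_category != "non_fq") %>%
        count(.data$term, name = "a") %>%
        mutate(exposure = "all_fq")
      rows <- bind_rows(rows, pooled)
    }
    n_fq_total <- sum(strata$n_stratum[strata$exposure != "non_fq"])
    rows <- rows %>%
      left_join(strata, by = "exposure") %>%
      mutate(n_stratum = ifelse(.data$exposure == "all_fq", n_fq_total,
                                .data$n_stratum)) %>%
      left_join(term_totals, by = "term") %>%
      filter(.data$a >= min_cases)
    if (nrow(rows) == 0L) next
    est <- ror_estimate(rows$a, rows$n_stratum - rows$a,
                        rows$n_event - rows$a,
                        n_total - rows$n_stratum - (rows$n_event - rows$a))
    out[[li]] <- bind_cols(
      tibble(exposure = rows$exposure, level = lev, term = rows$term),
      est
    ) %>%
      mutate(n_cases = .data$a,
             is_signal = evaluate_signal(.data$ror, .data$ci_low,
                                         .data$n_cases, min_cases))
  }
  res <- bind_rows(out)
  if (nrow(res)) {
    res <- res %>%
      mutate(level = factor(.data$level, levels = levels)) %>%
      arrange(.data$level, desc(.data$ror)) %>%
      mutate(level = as.character(.data$level))
  }
  structure(res, class = c("pv_signals", class(res)),
            n_total = n_total, min_cases = min_cases)
}

#' @exportS3Method generics::tidy
tidy.pv_signals <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pv_signals")
  attr(out, "n_total") <- NULL
  attr(out, "min_cases") <- NULL
  out
}

#' @exportS3Method generics::glance
glance.pv_signals <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_signals = sum(x$is_signal),
    n_corrected = sum(x$corrected),
    n_total_cases = attr(x, "n_total"),
    min_cases = attr(x, "min_cases")
  )
}

#' Forest plot of screened signals
#'
#' @param object a `pv_signals` result.
#' @param level which hierarchy level to draw (default the first present).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pv_signals <- function(object, level = NULL, ...) {
  level <- level %||% object$level[[1L]]
  df <- tidy(object) %>% filter(.data$level == !!level)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror,
                                   y = stats::reorder(.data$term, .data$ror),
                                   colour = .data$is_signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$exposure)) +
    ggplot2::labs(x = "reporting odds ratio (log scale)", y = NULL,
                  colour = "signal",
                  title = sprintf("Disproportionality screen (%s level)", level)) +
    ggplot2::theme_minimal()
}
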