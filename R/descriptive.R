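# derive a case-level analysis frame with the standard descriptive variables;
# outcome is the severity-precedence representative flag (a case reporting
# both death and hospitalisation tabulates under death)
case_frame <- function(x) {
  df <- x$cases
  df$age_group <- derive_age_group(df$age_years)
  df$severity <- severity_class(df$outcomes)
  df$outcome <- map_chr(df$outcomes, function(o) {
    pv_outcome_flags[min(match(o, pv_outcome_flags))]
  })
  df
}

#' Stratified count table with column percentages
#'
#' The Table-1-style summary: counts of `row_var` levels within each level of
#' `col_var`, with column percentages (2 decimals, half-up). A `total` column
#' is always included. Derivable variables (`age_group`, `severity`,
#' `outcome`) are computed on the fly; `exposure_category` and `therapy`
#' require a classified report set.
#'
#' @param x a `report_set` (or a case-level data frame already containing the
#'   variables).
#' @param row_var,col_var variable names (character). Use
#'   `col_var = "total"` for a one-column summary.
#' @param drop_unspecified drop `"unspecified"` row levels before
#'   percentaging (default `FALSE`: not-specified levels are retained as
#'   their own category, as printed summary tables carry them).
#' @return tibble with columns `row_level`, `col_level`, `n`, `pct`
#'   (column-wise percentage).
#' @export
stratified_counts <- function(x, row_var, col_var = "total",
                              drop_unspecified = FALSE) {
  df <- if (inherits(x, "report_set")) case_frame(x) else as_tibble(x)
  if (!row_var %in% names(df)) stopf("unknown variable: %s", row_var)
  if (col_var != "total" && !col_var %in% names(df)) {
    stopf("unknown variable: %s", col_var)
  }
  df$.row <- as.character(df[[row_var]])
  df$.col <- if (col_var == "total") "total" else as.character(df[[col_var]])
  if (drop_unspecified) df <- df[df$.row != "unspecified", , drop = FALSE]

  tab <- df %>% count(.data$.col, .data$.row, name = "n")
  # complete missing row/column combinations with zero counts
  tab <- tidyr::complete(tab, .col = unique(df$.col), .row = unique(df$.row),
                         fill = list(n = 0L))
  totals <- df %>% count(.data$.col, name = "col_total")
  all_rows <- tab %>%
    group_by(.data$.row) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    mutate(.col = "total")
  if (col_var != "total") {
    tab <- bind_rows(tab, all_rows)
    totals <- bind_rows(totals, tibble(.col = "total", col_total = nrow(df)))
  }
  tab %>%
    left_join(totals, by = ".col") %>%
    mutate(pct = ifelse(.data$col_total > 0,
                        round_half_up(100 * .data$n / .data$col_total, 2), 0)) %>%
    transmute(row_level = .data$.row, col_level = .data$.col,
              .data$n, .data$pct) %>%
    arrange(.data$col_level, .data$row_level)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected (no Yates continuity correction) Pearson test on a count
#' matrix, with an advisory flag recommending the exact test when any
#' expected cell count falls below 5.
#'
#' @param x a numeric count matrix (r x c).
#' @return tibble with `method`, `statistic`, `df`, `p_value`,
#'   `fisher_recommended`.
#' @export
chi_square_test <- function(x) {
  x <- as.matrix(x)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stopf("degenerate table: a margin is zero")
  }
  ct <- suppressWarnings(chisq.test(x, correct = FALSE))
  tibble(
    method = "chi_square",
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value),
    fisher_recommended = any(ct$expected < 5)
  )
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value under the probability-ordering definition: the sum of
#' hypergeometric probabilities of all tables (margins fixed) no more likely
#' than the observed one.
#'
#' @param x a 2x2 count matrix.
#' @return tibble with `method`, `statistic` (`NA`), `df` (`NA`), `p_value`.
#' @export
fisher_exact_test <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == 2L)) stopf("fisher_exact_test expects a 2x2 table")
  ft <- fisher.test(x)
  tibble(method = "fisher_exact", statistic = NA_real_, df = NA_integer_,
         p_value = unname(ft$p.value))
}

#' Characterize fatal cases within an event-defined subset
#'
#' Restricts to a subset of cases (optionally those with at least one
#' reaction in a given SOC), identifies the fatal cases (outcome flag
#' `died`), and summarizes them: fatal count and proportion of the subset, a
#' PT frequency ranking over the fatal cases (ties broken alphabetically),
#' and sex, age-group and exposure distributions. A nested PT sub-filter
#' (e.g. a specific fatal event of interest) reuses the same report shape on
#' the fatal subset.
#'
#' @param x a `report_set`.
#' @param dictionary a `term_dictionary` (needed when `soc` is given).
#' @param soc optional SOC name defining the event subset.
#' @param pt optional PT drilling into the fatal subset.
#' @return object of class `pv_fatal_report`: list with `n_subset`,
#'   `n_fatal`, `fatal_pct`, optionally `n_focus`/`focus_pct` (PT filter),
#'   `pt_ranking`, `sex`, `age_group`, `exposure` distribution tibbles
#'   computed over the focal case set.
#' @export
characterize_fatal <- function(x, dictionary = default_dictionary(),
                               soc = NULL, pt = NULL) {
  df <- case_frame(x)
  if (!is.null(soc)) {
    ev <- case_events_at_level(x, dictionary, "SOC")
    subset_ids <- ev$case_id[ev$term == soc]
    df <- df[df$case_id %in% subset_ids, , drop = FALSE]
  }
  fatal <- df[map_lgl(df$outcomes, ~ "died" %in% .x), , drop = FALSE]
  focus <- fatal
  res <- list(
    n_subset = nrow(df),
    n_fatal = nrow(fatal),
    fatal_pct = if (nrow(df)) round_half_up(100 * nrow(fatal) / nrow(df), 2) else 0
  )
  if (!is.null(pt)) {
    pt_ids <- unique(x$reactions$case_id[x$reactions$pt == pt])
    focus <- fatal[fatal$case_id %in% pt_ids, , drop = FALSE]
    res$n_focus <- nrow(focus)
    res$focus_pct <- if (nrow(fatal))
      round_half_up(100 * nrow(focus) / nrow(fatal), 2) else 0
  }
  focus_reac <- x$reactions[x$reactions$case_id %in% focus$case_id, , drop = FALSE]
  res$pt_ranking <- focus_reac %>%
    distinct(.data$case_id, .data$pt) %>%
    count(.data$pt, name = "n") %>%
    mutate(pct = if (nrow(focus)) round_half_up(100 * .data$n / nrow(focus), 2)
           else 0) %>%
    arrange(desc(.data$n), .data$pt)
  dist_of <- function(v, levels = NULL) {
    tab <- tibble(level = as.character(v)) %>% count(.data$level, name = "n") %>%
      mutate(pct = if (nrow(focus)) round_half_up(100 * .data$n / nrow(focus), 2)
             else 0)
    if (!is.null(levels)) {
      tab <- tab[order(match(tab$level, levels)), , drop = FALSE]
    }
    tab
  }
  res$sex <- dist_of(focus$sex, pv_sex_levels)
  res$age_group <- dist_of(focus$age_group, pv_age_group_levels)
  if ("exposure_category" %in% names(focus)) {
    res$exposure <- dist_of(focus$exposure_category, pv_exposure_levels)
  }
  structure(res, class = "pv_fatal_report")
}

#' @export
print.pv_fatal_report <- function(x, ...) {
  cat(sprintf("<pv_fatal_report> %d fatal of %d cases (%.2f%%)\n",
              x$n_fatal, x$n_subset, x$fatal_pct))
  if (!is.null(x$n_focus)) {
    cat(sprintf("  focal PT subset: %d of %d fatal (%.2f%%)\n",
                x$n_focus, x$n_fatal, x$focus_pct))
  }
  cat("  top PTs:\n")
  print(head(x$pt_ranking, 5))
  invisible(x)
}
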