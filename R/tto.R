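#' Compute time-to-onset samples
#'
#' Time-to-onset (TTO) is the whole-day interval between the start of suspect
#' drug administration and the first occurrence of the adverse event. Per
#' case: the earliest start date among suspect fluoroquinolone mentions, and
#' the earliest event date among reactions mapping (by primary SOC) to the
#' optional `soc` filter. Cases lacking either date are dropped with reason
#' `missing`; negative intervals are dropped with reason `inconsistent`
#' (drops are data, not failures, and are fully accounted for). Day-0
#' same-day onsets are valid samples.
#'
#' Only cases with at least one suspect fluoroquinolone enter the analysis.
#'
#' @param x a classified `report_set`.
#' @param dictionary a `term_dictionary`.
#' @param soc optional SOC filter for the event side (default: any reaction).
#' @param fq_names suspect drug names defining the exposure side.
#' @return object of class `pv_tto`: list with `samples` (tibble `case_id`,
#'   `exposure_category`, `therapy`, `sex`, `age_group`, `tto_days`) and
#'   `dropped` (tibble `case_id`, `reason`).
#' @export
compute_tto <- function(x, dictionary = default_dictionary(), soc = NULL,
                        fq_names = pv_fluoroquinolones) {
  if (!"exposure_category" %in% names(x$cases)) x <- classify_exposure(x)
  df <- case_frame(x)
  fq_cases <- df[df$exposure_category != "non_fq", , drop = FALSE]

  starts <- x$drugs %>%
    filter(.data$role == "suspect", .data$drug %in% fq_names,
           !is.na(.data$start_date)) %>%
    group_by(.data$case_id) %>%
    summarise(start = min(.data$start_date), .groups = "drop")
  reac <- x$reactions
  if (!is.null(soc)) {
    soc_pts <- dictionary$pt[dictionary$soc == soc]
    reac <- reac[reac$pt %in% soc_pts, , drop = FALSE]
  }
  events <- reac %>%
    filter(!is.na(.data$event_date)) %>%
    group_by(.data$case_id) %>%
    summarise(event = min(.data$event_date), .groups = "drop")

  base <- fq_cases %>%
    left_join(starts, by = "case_id") %>%
    left_join(events, by = "case_id")
  if (!is.null(soc)) {
    # cases outside the SOC subset are not part of this analysis at all
    in_soc <- x$reactions %>%
      filter(.data$pt %in% dictionary$pt[dictionary$soc == soc]) %>%
      pull(.data$case_id) %>% unique()
    base <- base[base$case_id %in% in_soc, , drop = FALSE]
  }
  tto <- as.integer(base$event - base$start)
  missing <- is.na(tto)
  negative <- !missing & tto < 0
  keep <- !missing & !negative
  samples <- tibble(
    case_id = base$case_id[keep],
    exposure_category = base$exposure_category[keep],
    therapy = base$therapy[keep],
    sex = base$sex[keep],
    age_group = base$age_group[keep],
    tto_days = tto[keep]
  )
  dropped <- bind_rows(
    tibble(case_id = base$case_id[missing], reason = "missing"),
    tibble(case_id = base$case_id[negative], reason = "inconsistent")
  )
  structure(list(samples = samples, dropped = dropped), class = "pv_tto")
}

#' @export
print.pv_tto <- function(x, ...) {
  cat(sprintf("<pv_tto> %d onset samples, %d dropped (%d missing, %d inconsistent)\n",
              nrow(x$samples), nrow(x$dropped),
              sum(x$dropped$reason == "missing"),
              sum(x$dropped$reason == "inconsistent")))
  invisible(x)
}

#' Empirical cumulative distribution of onset times
#'
#' Right-continuous step function over the observed onset days, with the
#' summary quantities used in cumulative-onset reporting: the median onset
#' and the fraction of cases with onset within 7 days.
#'
#' @param x numeric vector of onset days, or a `pv_tto` object (its samples
#'   are used).
#' @return object of class `pv_ecdf`: list with `points` (tibble `t`, `F`),
#'   `n`, `median`, `frac_within_7`.
#' @export
tto_ecdf <- function(x) {
  if (inherits(x, "pv_tto")) x <- x$samples$tto_days
  if (length(x) == 0L) stopf("no onset samples")
  t <- sort(unique(x))
  f <- cumsum(tabulate(match(sort(x), t))) / length(x)
  structure(list(
    points = tibble(t = t, F = f),
    n = length(x),
    median = unname(median(x)),
    frac_within_7 = mean(x <= 7)
  ), class = "pv_ecdf")
}

#' @export
print.pv_ecdf <- function(x, ...) {
  cat(sprintf("<pv_ecdf> n = %d, median = %g days, %.1f%% within 7 days\n",
              x$n, x$median, 100 * x$frac_within_7))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pv_ecdf <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$t, y = .data$F)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "time to onset (days)", y = "cumulative fraction") +
    ggplot2::theme_minimal()
}

#' Wilcoxon rank-sum test
#'
#' Two-sided two-sample location test on ranks. The exact null distribution
#' is used when both groups have at most 20 observations and the pooled data
#' are tie-free; otherwise the normal approximation with tie correction is
#' used, with continuity correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact method; default
#'   auto per the rule above.
#' @return tibble with `method` (`"wilcoxon"`), `exact`, `statistic` (the
#'   rank-sum statistic W), `df` (`NA`), `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- exact %||% (length(x) <= 20L && length(y) <= 20L && !ties)
  if (use_exact && ties) stopf("exact method is unavailable with ties")
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = !use_exact)
  )
  tibble(method = "wilcoxon", exact = use_exact,
         statistic = unname(wt$statistic), df = NA_integer_,
         p_value = min(1, unname(wt$p.value)))
}

#' Kruskal-Wallis test with BH-adjusted pairwise comparisons
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom, plus all pairwise Wilcoxon rank-sum comparisons adjusted as one
#' Benjamini-Hochberg family. When every observation is identical the test
#' is degenerate by convention: H = 0, p = 1.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values` (at least 2 groups;
#'   the omnibus statistic requires at least 2, conventionally 3+).
#' @return object of class `pv_kw`: list with `omnibus` (tibble `method`,
#'   `statistic`, `df`, `p_value`) and `pairwise` (tibble `group1`,
#'   `group2`, `p_value`, `p_adjusted`).
#' @export
kruskal_wallis_test <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stopf("values and groups lengths differ")
  gl <- sort(unique(groups))
  if (length(gl) < 2L) stopf("need at least two groups")
  if (length(unique(values)) == 1L) {
    omnibus <- tibble(method = "kruskal_wallis", statistic = 0,
                      df = length(gl) - 1L, p_value = 1)
  } else {
    kt <- kruskal.test(values, factor(groups))
    omnibus <- tibble(method = "kruskal_wallis",
                      statistic = unname(kt$statistic),
                      df = unname(kt$parameter), p_value = unname(kt$p.value))
  }
  pairs <- utils::combn(gl, 2L)
  pw <- map(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    p <- if (length(unique(c(values[groups == g1], values[groups == g2]))) == 1L) 1
    else wilcoxon_rank_sum(values[groups == g1], values[groups == g2])$p_value
    tibble(group1 = g1, group2 = g2, p_value = p)
  }) %>% bind_rows()
  pw$p_adjusted <- bh_adjust(pw$p_value)
  structure(list(omnibus = omnibus, pairwise = pw), class = "pv_kw")
}

#' @export
print.pv_kw <- function(x, ...) {
  cat(sprintf("<pv_kw> H = %.4f, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  print(x$pairwise)
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: sort ascending, multiply the i-th
#' by m/i, enforce monotonicity from the largest down, cap at 1, and return
#' in the original order. Adjusted values never fall below the raw ones.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
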