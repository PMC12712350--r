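# rectangular Gower distance between recipient and donor records over mixed
# features: range-scaled absolute difference for numerics, 0/1 mismatch for
# categoricals, averaged over the features available for each recipient
gower_distance <- function(recipients, donors, numeric_cols, cat_cols) {
  nr <- nrow(recipients); nd <- nrow(donors)
  total <- matrix(0, nr, nd)
  denom <- matrix(0, nr, nd)
  for (col in numeric_cols) {
    rv <- recipients[[col]]; dv <- donors[[col]]
    rng <- diff(range(c(rv, dv), na.rm = TRUE))
    if (!is.finite(rng) || rng == 0) rng <- 1
    d <- abs(outer(rv, dv, "-")) / rng
    ok <- !is.na(d)
    total[ok] <- total[ok] + d[ok]
    denom <- denom + ok
  }
  for (col in cat_cols) {
    rv <- as.character(recipients[[col]]); dv <- as.character(donors[[col]])
    avail <- !is.na(rv) & rv != "unspecified"
    d <- outer(rv, dv, "!=") * 1
    total[avail, ] <- total[avail, , drop = FALSE] + d[avail, , drop = FALSE]
    denom[avail, ] <- denom[avail, , drop = FALSE] + 1
  }
  denom[denom == 0] <- 1
  total / denom
}

#' k-nearest-neighbour imputation of missing age and sex
#'
#' Completes missing `age_years` and unspecified `sex` using the k nearest
#' complete donor records under Gower distance over the mixed feature set
#' `{sex, age (each only when present on the recipient), country, reporter,
#' exposure category, severity class}`. Ages are imputed as the donor median,
#' sex as the donor mode with alphabetical tie-break. Observed values are
#' never altered, and ties in donor distance are broken by `case_id` order,
#' making the procedure fully deterministic.
#'
#' @param x a `report_set` (classified, so the exposure feature is
#'   available; if unclassified the feature is dropped).
#' @param k number of donors (default 5); there must be at least `k`
#'   complete records.
#' @param chunk_size recipients are processed in blocks of this size to
#'   bound the distance-matrix memory.
#' @return list with `reports` (imputed `report_set`) and `imputed` (tibble
#'   `case_id`, `field`, `value`).
#' @export
knn_impute <- function(x, k = 5L, chunk_size = 1000L) {
  df <- case_frame(x)
  cat_cols <- intersect(c("sex", "country", "reporter", "exposure_category",
                          "severity"), names(df))
  miss_age <- is.na(df$age_years)
  miss_sex <- df$sex == "unspecified"
  recipients_idx <- which(miss_age | miss_sex)
  donors_idx <- which(!miss_age & !miss_sex)
  if (length(donors_idx) < k) {
    stopf("fewer than k = %d complete donor records (%d available)",
          k, length(donors_idx))
  }
  if (length(recipients_idx) == 0L) {
    return(list(reports = x,
                imputed = tibble(case_id = character(), field = character(),
                                 value = character())))
  }
  # sort donors by case_id so stable ordering breaks distance ties by id
  donors_idx <- donors_idx[order(df$case_id[donors_idx], method = "radix")]
  donors <- df[donors_idx, , drop = FALSE]

  imputed <- list()
  new_age <- df$age_years
  new_sex <- df$sex
  for (block in split(recipients_idx,
                      ceiling(seq_along(recipients_idx) / chunk_size))) {
    rec <- df[block, , drop = FALSE]
    dmat <- gower_distance(rec, donors, "age_years", cat_cols)
    for (i in seq_along(block)) {
      nn <- order(dmat[i, ], method = "radix")[seq_len(k)]
      ri <- block[[i]]
      if (miss_age[ri]) {
        val <- median(donors$age_years[nn])
        new_age[ri] <- val
        imputed[[length(imputed) + 1L]] <-
          tibble(case_id = df$case_id[ri], field = "age_years",
                 value = format(val))
      }
      if (miss_sex[ri]) {
        sx <- donors$sex[nn]
        tab <- sort(table(sx), decreasing = TRUE)
        winners <- names(tab)[tab == max(tab)]
        val <- sort(winners)[[1L]]
        new_sex[ri] <- val
        imputed[[length(imputed) + 1L]] <-
          tibble(case_id = df$case_id[ri], field = "sex", value = val)
      }
    }
  }
  x$cases$age_years <- new_age
  x$cases$sex <- new_sex
  list(reports = x, imputed = bind_rows(imputed))
}

#' Univariate logistic regression odds ratios for one factor
#'
#' Fits `outcome ~ predictor` by maximum likelihood (iteratively reweighted
#' least squares) for a single categorical predictor with a declared
#' reference level, and returns per-level odds ratios `exp(coef)` with Wald
#' 95% confidence intervals `exp(coef +/- 1.96 * SE)` and two-sided Wald
#' p-values. The reference level is emitted as a row with OR fixed at 1 and
#' no interval. Quasi-separated levels (zero or all events) and
#' non-convergence are flagged, never silently returned.
#'
#' @param data a data frame.
#' @param predictor name of the factor column.
#' @param outcome name of a logical/0-1 outcome column.
#' @param reference reference level (default: first sorted level).
#' @return tibble with `predictor`, `level`, `reference`, `n_level`,
#'   `n_events`, `or`, `ci_low`, `ci_high`, `p_value`, `flag`.
#' @export
logistic_univariate <- function(data, predictor, outcome, reference = NULL) {
  y <- as.integer(as.logical(data[[outcome]]))
  v <- as.character(data[[predictor]])
  lev <- sort(unique(v))
  reference <- reference %||% lev[[1L]]
  if (!reference %in% lev) stopf("reference level '%s' not present", reference)
  f <- factor(v, levels = c(reference, setdiff(lev, reference)))
  fit <- glm(y ~ f, family = binomial())
  sm <- summary(fit)$coefficients
  counts <- tibble(level = v, y = y) %>%
    group_by(.data$level) %>%
    summarise(n_level = dplyr::n(), n_events = sum(.data$y), .groups = "drop")
  sep_levels <- counts$level[counts$n_events == 0L |
                               counts$n_events == counts$n_level]
  rows <- map(levels(f), function(lv) {
    nl <- counts$n_level[counts$level == lv]
    ne <- counts$n_events[counts$level == lv]
    if (lv == reference) {
      return(tibble(predictor = predictor, level = lv, reference = reference,
                    n_level = nl, n_events = ne, or = 1, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_, flag = ""))
    }
    cn <- paste0("f", lv)
    est <- sm[cn, "Estimate"]; se <- sm[cn, "Std. Error"]
    flag <- ""
    if (lv %in% sep_levels || reference %in% sep_levels || abs(est) > 15) {
      flag <- "separation"
    }
    if (!fit$converged) flag <- trimws(paste(flag, "non_convergence"))
    tibble(predictor = predictor, level = lv, reference = reference,
           n_level = nl, n_events = ne, or = exp(est),
           ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
           p_value = 2 * stats::pnorm(-abs(est / se)), flag = flag)
  })
  bind_rows(rows)
}

#' Univariate risk-factor screen with one BH family
#'
#' Runs [logistic_univariate()] for each predictor against a case-level
#' binary outcome (at least one reaction PT whose primary SOC equals
#' `outcome_soc`), on the fluoroquinolone-exposed cases, with fixed
#' reference levels: ciprofloxacin (exposure), monotherapy (therapy), male
#' (sex), 0-17 (age group), non_serious (severity). Imputation of missing
#' age/sex runs first unless disabled. All non-reference levels across all
#' predictors form a single Benjamini-Hochberg family.
#'
#' @param x a classified `report_set`.
#' @param dictionary a `term_dictionary`.
#' @param outcome_soc SOC defining the outcome flag (e.g.
#'   `"psychiatric disorders"`).
#' @param predictors character vector of case-level factors to screen.
#' @param impute run [knn_impute()] first (default `TRUE`).
#' @param k donors for imputation.
#' @return a `pv_risk` tibble: the per-level odds-ratio rows plus
#'   `p_adjusted`.
#' @export
risk_factor_screen <- function(x, dictionary = default_dictionary(),
                               outcome_soc = "psychiatric disorders",
                               predictors = c("exposure_category", "therapy",
                                              "sex", "age_group", "severity"),
                               impute = TRUE, k = 5L) {
  if (!"exposure_category" %in% names(x$cases)) {
    stopf("reports must be classified first; run classify_exposure()")
  }
  if (impute) x <- knn_impute(x, k = k)$reports
  df <- case_frame(x)
  df <- df[df$exposure_category != "non_fq", , drop = FALSE]
  ev <- case_events_at_level(x, dictionary, "SOC")
  df$outcome_flag <- df$case_id %in% ev$case_id[ev$term == outcome_soc]

  refs <- c(exposure_category = "ciprofloxacin", therapy = "monotherapy",
            sex = "male", age_group = "0-17", severity = "non_serious")
  rows <- map(predictors, function(p) {
    ref <- if (p %in% names(refs) && refs[[p]] %in% df[[p]]) refs[[p]] else NULL
    logistic_univariate(df, p, "outcome_flag", reference = ref)
  }) %>% bind_rows()
  nonref <- rows$level != rows$reference
  rows$p_adjusted <- NA_real_
  rows$p_adjusted[nonref] <- bh_adjust(rows$p_value[nonref])
  structure(rows, class = c("pv_risk", class(rows)),
            outcome_soc = outcome_soc, n_cases = nrow(df))
}

#' @exportS3Method generics::tidy
tidy.pv_risk <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pv_risk")
  attr(out, "outcome_soc") <- NULL
  attr(out, "n_cases") <- NULL
  out
}

#' @exportS3Method generics::glance
glance.pv_risk <- function(x, ...) {
  nonref <- x$level != x$reference
  tibble(
    outcome_soc = attr(x, "outcome_soc"),
    n_cases = attr(x, "n_cases"),
    n_levels = sum(nonref),
    n_significant = sum(x$p_adjusted[nonref] < 0.05, na.rm = TRUE),
    n_flagged = sum(x$flag[nonref] != "")
  )
}

#' Forest plot of the risk-factor screen
#'
#' @param object a `pv_risk` result.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pv_risk <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(label = paste(.data$predictor, .data$level, sep = ": "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
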