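#' Deduplicate spontaneous reports by exact matching-key equality
#'
#' Two reports are considered duplicates when they agree on the full matching
#' key: age (rounded to whole years; missing matches missing), sex, country,
#' initial receive date, the sorted set of suspect drug names, the sorted
#' indication set, and the sorted reaction PT set. Within each key group only
#' the case with the lexicographically smallest `case_id` is retained. Key
#' construction is order-insensitive in its set-valued components, so the
#' result does not depend on input order.
#'
#' @param x a `report_set`.
#' @return list with `reports` (deduplicated `report_set`) and `removed`
#'   (tibble `removed_id`, `retained_id`).
#' @export
deduplicate <- function(x) {
  ids <- x$cases$case_id
  sus <- x$drugs[x$drugs$role == "suspect", c("case_id", "drug")]
  key <- paste(
    ifelse(is.na(x$cases$age_years), "<NA>",
           as.character(round(x$cases$age_years))),
    x$cases$sex,
    x$cases$country,
    ifelse(is.na(x$cases$receive_date), "<NA>",
           format(x$cases$receive_date, "%Y-%m-%d")),
    collapse_sorted(sus$case_id, sus$drug, ids),
    collapse_sorted(rep(ids, lengths(x$cases$indications)),
                    unlist(x$cases$indications, use.names = FALSE), ids),
    collapse_sorted(x$reactions$case_id, x$reactions$pt, ids),
    sep = "\x1e"
  )
  ord <- order(key, ids, method = "radix")
  first <- !duplicated(key[ord])
  retained_for <- rep(ids[ord][first], times = diff(c(which(first), length(ids) + 1L)))
  removed <- tibble(removed_id = ids[ord][!first],
                    retained_id = retained_for[!first])
  keep <- setdiff(ids, removed$removed_id)
  list(reports = filter_cases(x, keep), removed = removed)
}

#' Exclude cases carrying psychotropic co-medication
#'
#' Removes every case in which any drug mention (any role) carries an ATC code
#' starting with one of the given prefixes. The defaults are the psycholeptic
#' (N05), psychoanaleptic (N06) and addictive-disorder (N07B) classes, the
#' standard confounder filter before screening psychiatric adverse events.
#' Matching is a plain string-prefix test on each comma-separated code, so
#' `N07A` codes are not caught by the `N07B` prefix.
#'
#' @param x a `report_set`.
#' @param atc_prefixes character vector of ATC code prefixes.
#' @return list with `reports` (filtered `report_set`) and `excluded` (tibble
#'   `case_id`, `matched_atc`).
#' @export
exclude_psychotropics <- function(x, atc_prefixes = pv_psychotropic_atc_prefixes) {
  rx <- paste0("(?:^|,)(?:", paste(atc_prefixes, collapse = "|"), ")")
  hit <- stringr::str_detect(x$drugs$atc %||% "", rx)
  hit[is.na(hit)] <- FALSE
  excluded <- x$drugs[hit, c("case_id", "atc")] %>%
    distinct(.data$case_id, .keep_all = TRUE) %>%
    rename(matched_atc = "atc") %>%
    arrange(.data$case_id)
  keep <- setdiff(x$cases$case_id, excluded$case_id)
  list(reports = filter_cases(x, keep), excluded = excluded)
}

#' Classify each case's fluoroquinolone exposure
#'
#' Adds three columns to the cases table:
#' * `exposure_category`: one of the six FQ monotherapies, `"combination"`,
#'   or `"non_fq"` for comparator cases with no suspect FQ. Monotherapy
#'   requires exactly one distinct FQ and no other drug mention of any role.
#' * `combination_subtype`: for combination cases, by precedence
#'   `multiple_fqs` (two or more distinct FQs) > `fq_plus_antibiotics` (any
#'   non-FQ drug with an ATC `J01` prefix) > `fq_plus_other_meds`; `"none"`
#'   otherwise.
#' * `therapy`: `monotherapy` / the combination subtype / `non_fq`, the
#'   factor used by the risk-factor screen.
#'
#' @param x a `report_set`.
#' @param fq_names character vector of fluoroquinolone names (normalized).
#' @param tag_background when `TRUE` (default) cases without a suspect FQ are
#'   tagged `"non_fq"`; when `FALSE` such cases raise an error.
#' @return the `report_set` with classification columns added to `$cases`.
#' @export
classify_exposure <- function(x, fq_names = pv_fluoroquinolones,
                              tag_background = TRUE) {
  ids <- x$cases$case_id
  d <- x$drugs
  is_fq <- d$drug %in% fq_names & d$role == "suspect"
  is_abx <- !(d$drug %in% fq_names) &
    stringr::str_detect(d$atc %||% "", "(?:^|,)J01")
  is_abx[is.na(is_abx)] <- FALSE

  n <- length(ids)
  idx <- match(d$case_id, ids)
  fi <- which(is_fq)
  fq_keep <- fi[!duplicated(paste0(idx[fi], "\r", d$drug[fi]))]
  n_fq_distinct <- tabulate(idx[fq_keep], n)
  single_fq <- rep(NA_character_, n)
  single_fq[idx[fq_keep]] <- d$drug[fq_keep]
  drug_keep <- !duplicated(paste0(idx, "\r", d$drug))
  n_drug_distinct <- tabulate(idx[drug_keep], n)
  any_abx <- logical(n)
  any_abx[idx[is_abx]] <- TRUE

  no_fq <- n_fq_distinct == 0L
  if (any(no_fq) && !tag_background) {
    stopf("case(s) without any suspect fluoroquinolone: %s",
          paste(head(ids[no_fq], 5L), collapse = ", "))
  }
  mono <- n_fq_distinct == 1L & n_drug_distinct == 1L
  category <- ifelse(no_fq, "non_fq", ifelse(mono, single_fq, "combination"))
  subtype <- ifelse(category != "combination", "none",
                    ifelse(n_fq_distinct >= 2L, "multiple_fqs",
                           ifelse(any_abx, "fq_plus_antibiotics",
                                  "fq_plus_other_meds")))
  x$cases$exposure_category <- unname(category)
  x$cases$combination_subtype <- unname(subtype)
  x$cases$therapy <- unname(ifelse(category == "non_fq", "non_fq",
                                   ifelse(subtype == "none", "monotherapy", subtype)))
  x
}

#' Bin ages into the reporting age groups
#'
#' Bins: 0-17, 18-34, 35-64, 65+ (lower bounds inclusive); missing ages map
#' to `"unspecified"`.
#'
#' @param age_years numeric vector (NA allowed).
#' @return character vector of age-group labels.
#' @export
derive_age_group <- function(age_years) {
  if (any(age_years < 0, na.rm = TRUE)) stopf("negative age")
  out <- dplyr::case_when(
    is.na(age_years) ~ "unspecified",
    age_years < 18 ~ "0-17",
    age_years < 35 ~ "18-34",
    age_years < 65 ~ "35-64",
    TRUE ~ "65+"
  )
  out
}

#' Run the full preprocessing flow
#'
#' Deduplication, then psychotropic exclusion, then exposure classification —
#' the fixed stage order of the pipeline. Stage counts are recorded so the
#' attrition ledger (raw, post-dedup, post-exclusion) is always available.
#'
#' @param x a `report_set`.
#' @param atc_prefixes passed to [exclude_psychotropics()].
#' @param fq_names passed to [classify_exposure()].
#' @return object of class `pv_preprocess`: list with `reports` (classified
#'   `report_set`), `counts` (named vector `raw`, `deduplicated`,
#'   `post_exclusion`), `removed_duplicates`, `excluded`.
#' @export
preprocess <- function(x, atc_prefixes = pv_psychotropic_atc_prefixes,
                       fq_names = pv_fluoroquinolones) {
  n_raw <- n_cases(x)
  dd <- deduplicate(x)
  ex <- exclude_psychotropics(dd$reports, atc_prefixes)
  out <- classify_exposure(ex$reports, fq_names)
  structure(list(
    reports = out,
    counts = c(raw = n_raw, deduplicated = n_cases(dd$reports),
               post_exclusion = n_cases(ex$reports)),
    removed_duplicates = dd$removed,
    excluded = ex$excluded
  ), class = "pv_preprocess")
}

#' @export
print.pv_preprocess <- function(x, ...) {
  cat(sprintf(
    "<pv_preprocess> raw %d -> deduplicated %d -> post-exclusion %d cases\n",
    x$counts[["raw"]], x$counts[["deduplicated"]], x$counts[["post_exclusion"]]
  ))
  invisible(x)
}
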