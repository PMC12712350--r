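#' Build a spontaneous-report set from its three component tables
#'
#' A `report_set` is the canonical in-memory form of a batch of spontaneous
#' adverse-event case reports. Because one case carries several drug mentions
#' and several coded reactions, the container is relational: a `cases` tibble
#' (one row per case) and two child tibbles (`drugs`, `reactions`) keyed by
#' `case_id`.
#'
#' @param cases tibble with columns `case_id` (unique character),
#'   `receive_date` (`Date`), `sex` (`male`/`female`/`unspecified`),
#'   `age_years` (numeric in `[0, 120]` or `NA`), `country` (character,
#'   `"unspecified"` allowed), `reporter` (`consumer`/
#'   `healthcare_professional`/`unspecified`), `outcomes` (list column of
#'   non-empty character vectors drawn from the outcome flags), and
#'   `indications` (list column of character vectors, possibly empty).
#' @param drugs tibble with columns `case_id`, `drug` (normalized lowercase
#'   name), `role` (`suspect`/`concomitant`), `atc` (comma-joined ATC codes,
#'   `""` when uncoded) and `start_date` (`Date` or `NA`).
#' @param reactions tibble with columns `case_id`, `pt` (MedDRA-style
#'   preferred term, lowercase) and `event_date` (`Date` or `NA`).
#' @param validate run structural validation (default `TRUE`).
#'
#' @return an object of class `report_set`.
#' @seealso [read_cases()], [write_cases()], [simulate_reports()]
#' @export
report_set <- function(cases, drugs, reactions, validate = TRUE) {
  x <- structure(
    list(
      cases = as_tibble(cases),
      drugs = as_tibble(drugs),
      reactions = as_tibble(reactions)
    ),
    class = "report_set"
  )
  if (validate) validate_report_set(x)
  x
}

#' Validate the structural invariants of a report set
#'
#' Checks column presence, uniqueness of `case_id`, the age range, non-empty
#' outcome sets, that every case carries at least one drug and one reaction,
#' and that child tables reference known cases. Optionally checks that every
#' reaction PT is present in a term dictionary (`strict` coding validation).
#'
#' @param x a `report_set`.
#' @param dictionary optional [term_dictionary] for strict PT validation.
#' @return `x`, invisibly; aborts with an informative message on violation.
#' @export
validate_report_set <- function(x, dictionary = NULL) {
  stopifnot(inherits(x, "report_set"))
  need <- function(df, cols, tab) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stopf("%s table is missing column(s): %s", tab, paste(miss, collapse = ", "))
    }
  }
  need(x$cases, c("case_id", "receive_date", "sex", "age_years", "country",
                  "reporter", "outcomes", "indications"), "cases")
  need(x$drugs, c("case_id", "drug", "role", "atc", "start_date"), "drugs")
  need(x$reactions, c("case_id", "pt", "event_date"), "reactions")

  dup <- unique(x$cases$case_id[duplicated(x$cases$case_id)])
  if (length(dup)) {
    stopf("duplicate case_id value(s): %s",
          paste(head(dup, 5L), collapse = ", "))
  }
  bad_age <- !is.na(x$cases$age_years) &
    (x$cases$age_years < 0 | x$cases$age_years > 120)
  if (any(bad_age)) {
    stopf("age_years outside [0, 120] for case(s): %s",
          paste(head(x$cases$case_id[bad_age], 5L), collapse = ", "))
  }
  if (!all(x$cases$sex %in% pv_sex_levels)) stopf("invalid sex code")
  if (!all(x$cases$reporter %in% pv_reporter_levels)) stopf("invalid reporter code")
  n_out <- lengths(x$cases$outcomes)
  if (any(n_out == 0L)) stopf("every case must carry at least one outcome flag")
  all_out <- unlist(x$cases$outcomes, use.names = FALSE)
  if (!all(all_out %in% pv_outcome_flags)) {
    stopf("unknown outcome flag(s): %s",
          paste(head(setdiff(all_out, pv_outcome_flags), 5L), collapse = ", "))
  }
  ids <- x$cases$case_id
  if (!all(x$drugs$case_id %in% ids)) stopf("drugs table references unknown case_id")
  if (!all(x$reactions$case_id %in% ids)) stopf("reactions table references unknown case_id")
  if (!all(ids %in% x$drugs$case_id)) stopf("every case must carry at least one drug mention")
  if (!all(ids %in% x$reactions$case_id)) stopf("every case must carry at least one reaction")
  if (!all(x$drugs$role %in% c("suspect", "concomitant"))) {
    stopf("drug role must be 'suspect' or 'concomitant'")
  }
  if (!is.null(dictionary)) {
    unknown <- setdiff(unique(x$reactions$pt), dictionary$pt)
    if (length(unknown)) {
      stopf("reaction PT(s) absent from the dictionary: %s",
            paste(head(unknown, 5L), collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf(
    "<report_set> %d cases, %d drug mentions, %d reactions\n",
    nrow(x$cases), nrow(x$drugs), nrow(x$reactions)
  ))
  pr <- attr(x, "problems")
  if (!is.null(pr) && nrow(pr)) {
    cat(sprintf("  (%d malformed input row(s) set aside; see case_problems())\n",
                nrow(pr)))
  }
  print(x$cases, n = 5)
  invisible(x)
}

#' Number of cases in a report set
#' @param x a `report_set`.
#' @export
n_cases <- function(x) nrow(x$cases)

#' Rows rejected during ingestion
#'
#' [read_cases()] does not silently drop malformed rows: they are set aside
#' with a reason, and this accessor returns that ledger.
#'
#' @param x a `report_set` returned by [read_cases()].
#' @return tibble with columns `row`, `case_id`, `issue` (empty when all rows
#'   parsed cleanly).
#' @export
case_problems <- function(x) {
  attr(x, "problems") %||%
    tibble(row = integer(), case_id = character(), issue = character())
}

#' Nest a report set into a one-row-per-case tibble
#'
#' Convenience view for interactive inspection: the drug and reaction child
#' tables are folded into list columns.
#'
#' @param x a `report_set`.
#' @param ... unused.
#' @exportS3Method tibble::as_tibble
as_tibble.report_set <- function(x, ...) {
  x$cases %>%
    left_join(tidyr::nest(x$drugs, drugs = -"case_id"), by = "case_id") %>%
    left_join(tidyr::nest(x$reactions, reactions = -"case_id"), by = "case_id")
}

#' Subset a report set to a set of case identifiers
#'
#' Keeps the drug and reaction child tables in step with the retained cases.
#'
#' @param x a `report_set`.
#' @param case_ids character vector of case identifiers to keep.
#' @return a `report_set` restricted to the given cases.
#' @export
filter_reports <- function(x, case_ids) {
  filter_cases(x, case_ids)
}

# subset a report_set to a set of case ids, keeping child tables in step
filter_cases <- function(x, keep_ids) {
  structure(
    list(
      cases = x$cases[x$cases$case_id %in% keep_ids, , drop = FALSE],
      drugs = x$drugs[x$drugs$case_id %in% keep_ids, , drop = FALSE],
      reactions = x$reactions[x$reactions$case_id %in% keep_ids, , drop = FALSE]
    ),
    class = "report_set"
  )
}

# ---------------------------------------------------------------------------
# CSV dialect (version 1)
#
# One row per case. Sub-fields use "|", lists use ";". Columns:
#   case_id, receive_date (ISO-8601), sex, age_years, country, reporter,
#   outcomes (";"-joined flags), indications (";"-joined),
#   drugs (";"-joined "name|role|atc1,atc2|start_date"),
#   reactions (";"-joined "pt|event_date")
# The first line of a file is the dialect marker comment below.
# ---------------------------------------------------------------------------
pv_dialect_header <- "# pvror-cases-v1"
pv_case_columns <- c("case_id", "receive_date", "sex", "age_years", "country",
                     "reporter", "outcomes", "indications", "drugs", "reactions")

parse_date_iso <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & x != ""
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

#' Read case reports from the documented CSV dialect
#'
#' Parses a cases CSV (see the package vignette for the full column contract:
#' `"|"` separates sub-fields within a mention, `";"` separates list items,
#' dates are ISO-8601). Structural problems with the whole file (a missing
#' mandatory column, duplicated `case_id`) abort; malformed individual rows
#' (age out of range, empty drug or reaction list, ragged sub-fields) are set
#' aside into a problem ledger available via [case_problems()], never silently
#' dropped.
#'
#' Drug names are normalized (lowercase, trimmed, internal whitespace
#' collapsed) and any role other than `suspect` (e.g. FAERS "interacting") is
#' collapsed to `concomitant`.
#'
#' @param path path to a cases CSV.
#' @return a validated `report_set` with a `problems` attribute.
#' @export
read_cases <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readr::read_csv(
    path, comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  )
  miss <- setdiff(pv_case_columns, names(raw))
  if (length(miss)) {
    stopf("cases file is missing mandatory column(s): %s",
          paste(miss, collapse = ", "))
  }
  dup <- unique(raw$case_id[duplicated(raw$case_id)])
  if (length(dup)) {
    stopf("duplicate case_id in input: %s", paste(head(dup, 10L), collapse = ", "))
  }

  problems <- list()
  note <- function(row, id, issue) {
    problems[[length(problems) + 1L]] <<- tibble(row = row, case_id = id, issue = issue)
  }

  n <- nrow(raw)
  if (n == 0L) {
    rs <- report_set(
      cases = tibble(case_id = character(), receive_date = as.Date(character()),
                     sex = character(), age_years = numeric(), country = character(),
                     reporter = character(), outcomes = list(), indications = list()),
      drugs = tibble(case_id = character(), drug = character(), role = character(),
                     atc = character(), start_date = as.Date(character())),
      reactions = tibble(case_id = character(), pt = character(),
                         event_date = as.Date(character())),
      validate = FALSE
    )
    attr(rs, "problems") <- tibble(row = integer(), case_id = character(),
                                   issue = character())
    return(rs)
  }

  age <- suppressWarnings(as.numeric(raw$age_years))
  age[raw$age_years == ""] <- NA_real_
  keep <- rep(TRUE, n)

  bad <- which(!is.na(age) & (age < 0 | age > 120))
  for (i in bad) note(i, raw$case_id[i], "age_years outside [0, 120]")
  keep[bad] <- FALSE

  split_list <- function(x) {
    out <- stringr::str_split(x, ";")
    out[is.na(x) | x == ""] <- list(character())
    out
  }
  outcomes <- split_list(raw$outcomes)
  bad <- which(lengths(outcomes) == 0L |
                 !map_lgl(outcomes, ~ all(.x %in% pv_outcome_flags)))
  for (i in bad) note(i, raw$case_id[i], "missing or unknown outcome flag")
  keep[bad] <- FALSE

  indications <- split_list(raw$indications)

  parse_drugs <- function(field) {
    if (is.na(field) || field == "") return(NULL)
    parts <- stringr::str_split(stringr::str_split_1(field, ";"), "\\|")
    if (any(lengths(parts) != 4L)) return(NA)
    tibble(
      drug = normalize_drug_name(map_chr(parts, 1L)),
      role = ifelse(map_chr(parts, 2L) == "suspect", "suspect", "concomitant"),
      atc = map_chr(parts, 3L),
      start_date = parse_date_iso(map_chr(parts, 4L))
    )
  }
  parse_reactions <- function(field) {
    if (is.na(field) || field == "") return(NULL)
    parts <- stringr::str_split(stringr::str_split_1(field, ";"), "\\|")
    if (any(lengths(parts) != 2L)) return(NA)
    tibble(
      pt = stringr::str_squish(tolower(map_chr(parts, 1L))),
      event_date = parse_date_iso(map_chr(parts, 2L))
    )
  }

  drug_tabs <- map(raw$drugs, parse_drugs)
  reac_tabs <- map(raw$reactions, parse_reactions)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    if (is.null(drug_tabs[[i]]) || identical(drug_tabs[[i]], NA)) {
      note(i, raw$case_id[i], "empty or malformed drugs field"); keep[i] <- FALSE
    } else if (is.null(reac_tabs[[i]]) || identical(reac_tabs[[i]], NA)) {
      note(i, raw$case_id[i], "empty or malformed reactions field"); keep[i] <- FALSE
    } else if (any(drug_tabs[[i]]$drug == "")) {
      note(i, raw$case_id[i], "empty drug name"); keep[i] <- FALSE
    }
  }

  idx <- which(keep)
  if (length(idx) == 0L) {
    rs <- report_set(
      cases = tibble(case_id = character(), receive_date = as.Date(character()),
                     sex = character(), age_years = numeric(), country = character(),
                     reporter = character(), outcomes = list(), indications = list()),
      drugs = tibble(case_id = character(), drug = character(), role = character(),
                     atc = character(), start_date = as.Date(character())),
      reactions = tibble(case_id = character(), pt = character(),
                         event_date = as.Date(character())),
      validate = FALSE
    )
    attr(rs, "problems") <- bind_rows(problems)
    return(rs)
  }
  cases <- tibble(
    case_id = raw$case_id[idx],
    receive_date = parse_date_iso(raw$receive_date[idx]),
    sex = ifelse(raw$sex[idx] %in% pv_sex_levels, raw$sex[idx], "unspecified"),
    age_years = age[idx],
    country = ifelse(raw$country[idx] == "", "unspecified", raw$country[idx]),
    reporter = ifelse(raw$reporter[idx] %in% pv_reporter_levels,
                      raw$reporter[idx], "unspecified"),
    outcomes = outcomes[idx],
    indications = indications[idx]
  )
  drugs <- bind_rows(setNames(drug_tabs[idx], raw$case_id[idx]), .id = "case_id")
  reactions <- bind_rows(setNames(reac_tabs[idx], raw$case_id[idx]), .id = "case_id")

  rs <- report_set(cases, drugs, reactions)
  attr(rs, "problems") <- if (length(problems)) bind_rows(problems) else
    tibble(row = integer(), case_id = character(), issue = character())
  rs
}

#' Write case reports in the documented CSV dialect
#'
#' Inverse of [read_cases()]: a written file re-reads to a field-by-field
#' identical report set.
#'
#' @param x a `report_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(x, path) {
  validate_report_set(x)
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  drugs <- x$drugs %>%
    mutate(item = paste(.data$drug, .data$role, .data$atc,
                        fmt_date(.data$start_date), sep = "|")) %>%
    group_by(.data$case_id) %>%
    summarise(drugs = paste(.data$item, collapse = ";"), .groups = "drop")
  reac <- x$reactions %>%
    mutate(item = paste(.data$pt, fmt_date(.data$event_date), sep = "|")) %>%
    group_by(.data$case_id) %>%
    summarise(reactions = paste(.data$item, collapse = ";"), .groups = "drop")
  flat <- x$cases %>%
    mutate(
      receive_date = fmt_date(.data$receive_date),
      age_years = ifelse(is.na(.data$age_years), "", format(.data$age_years)),
      outcomes = map_chr(.data$outcomes, paste, collapse = ";"),
      indications = map_chr(.data$indications, paste, collapse = ";")
    ) %>%
    left_join(drugs, by = "case_id") %>%
    left_join(reac, by = "case_id") %>%
    select(all_of(pv_case_columns))
  writeLines(pv_dialect_header, path)
  readr::write_csv(flat, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# term dictionary
# ---------------------------------------------------------------------------

#' Construct a term dictionary
#'
#' A term dictionary maps each preferred term (PT) to exactly one primary
#' high-level group term (HLGT) and one primary system organ class (SOC),
#' mirroring the primary-path convention of hierarchical adverse-event coding.
#' The implied HLGT-to-SOC mapping must itself be functional: one HLGT cannot
#' sit under two SOCs.
#'
#' @param df data frame with character columns `pt`, `hlgt`, `soc`.
#' @return a `term_dictionary` tibble.
#' @export
term_dictionary <- function(df) {
  need <- setdiff(c("pt", "hlgt", "soc"), names(df))
  if (length(need)) stopf("dictionary is missing column(s): %s", paste(need, collapse = ", "))
  d <- as_tibble(df) %>%
    transmute(pt = stringr::str_squish(tolower(.data$pt)),
              hlgt = stringr::str_squish(tolower(.data$hlgt)),
              soc = stringr::str_squish(tolower(.data$soc)))
  exact_dup <- duplicated(d)
  if (any(exact_dup)) {
    warn(sprintf("%d exact duplicate dictionary row(s) collapsed", sum(exact_dup)))
    d <- d[!exact_dup, , drop = FALSE]
  }
  conflict <- unique(d$pt[duplicated(d$pt)])
  if (length(conflict)) {
    stopf("PT(s) mapped to more than one primary parent: %s",
          paste(head(conflict, 5L), collapse = ", "))
  }
  hl <- distinct(d, .data$hlgt, .data$soc)
  bad <- unique(hl$hlgt[duplicated(hl$hlgt)])
  if (length(bad)) {
    stopf("HLGT(s) listed under more than one SOC: %s",
          paste(head(bad, 5L), collapse = ", "))
  }
  class(d) <- c("term_dictionary", class(d))
  d
}

#' Read a term dictionary from CSV
#'
#' @param path CSV with columns `pt`, `hlgt`, `soc`.
#' @return a `term_dictionary` tibble.
#' @export
read_dictionary <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  term_dictionary(readr::read_csv(
    path, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
}

#' Look up the parents of preferred terms
#'
#' Pure lookup: repeated calls return identical parents.
#'
#' @param dictionary a `term_dictionary`.
#' @param pt character vector of preferred terms.
#' @return tibble with one row per element of `pt` (`NA` parents for unknown
#'   terms).
#' @export
lookup_term <- function(dictionary, pt) {
  i <- match(stringr::str_squish(tolower(pt)), dictionary$pt)
  tibble(pt = pt, hlgt = dictionary$hlgt[i], soc = dictionary$soc[i])
}

# ---------------------------------------------------------------------------
# severity
# ---------------------------------------------------------------------------

#' Classify case seriousness from outcome flags
#'
#' Maps outcome-flag sets to a single ordered severity class with precedence
#' critical > serious > non_serious: a case is `critical` if it carries
#' `died` or `life_threatening`; otherwise `serious` if it carries
#' `hospitalized`, `disabled` or `other_serious`; otherwise `non_serious`.
#' The classes are mutually exclusive and every non-empty flag set maps to
#' exactly one class.
#'
#' @param outcomes either a character vector of flags for a single case, or a
#'   list of such vectors (e.g. the `outcomes` list column of a report set).
#' @return character vector of severity classes (`"critical"`, `"serious"`,
#'   `"non_serious"`), length 1 for a single case or `length(outcomes)` for a
#'   list.
#' @export
severity_class <- function(outcomes) {
  if (is.character(outcomes)) outcomes <- list(outcomes)
  if (any(lengths(outcomes) == 0L)) stopf("outcomes must be non-empty")
  vapply(outcomes, function(o) {
    if (any(o %in% c("died", "life_threatening"))) "critical"
    else if (any(o %in% c("hospitalized", "disabled", "other_serious"))) "serious"
    else "non_serious"
  }, character(1))
}
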