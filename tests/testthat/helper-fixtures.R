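# Fixture builders shared across the suite. Everything is constructed in
# code at test time; no stored data files.

# build a report_set from compact per-case specs; drugs/reactions use the
# same "|"-sub-field mini-syntax as the CSV dialect
mk_report_set <- function(specs) {
  parse_date <- function(s) if (is.null(s) || s == "") as.Date(NA) else as.Date(s)
  cases <- list(); drugs <- list(); reacs <- list()
  for (sp in specs) {
    cases[[length(cases) + 1L]] <- tibble::tibble(
      case_id = sp$id,
      receive_date = parse_date(sp$receive %||% "2020-01-01"),
      sex = sp$sex %||% "female",
      age_years = sp$age %||% 40,
      country = sp$country %||% "united_states",
      reporter = sp$reporter %||% "consumer",
      outcomes = list(sp$outcomes %||% "non_serious"),
      indications = list(sp$indications %||% character())
    )
    for (d in sp$drugs %||% "ciprofloxacin|suspect|J01MA02|") {
      f <- strsplit(d, "|", fixed = TRUE)[[1]]
      f <- c(f, rep("", 4 - length(f)))
      drugs[[length(drugs) + 1L]] <- tibble::tibble(
        case_id = sp$id, drug = f[1], role = f[2],
        atc = f[3], start_date = parse_date(f[4])
      )
    }
    for (r in sp$reactions %||% "anxiety|") {
      f <- strsplit(r, "|", fixed = TRUE)[[1]]
      f <- c(f, rep("", 2 - length(f)))
      reacs[[length(reacs) + 1L]] <- tibble::tibble(
        case_id = sp$id, pt = f[1], event_date = parse_date(f[2])
      )
    }
  }
  report_set(dplyr::bind_rows(cases), dplyr::bind_rows(drugs),
             dplyr::bind_rows(reacs))
}

`%||%` <- rlang::`%||%`

# cohort whose marginal counts mirror a published fluoroquinolone
# adverse-event cohort: 44895 cases, 8518 psychiatric, 4367 eye-related,
# 1163 fatal (143 psychiatric incl. 54 completed-suicide cases), with the
# sex and age-group composition of those strata
paper_shaped_cohort <- function() {
  blocks <- list()
  add <- function(n, sex, age, fatal, pts) {
    blocks[[length(blocks) + 1L]] <<- list(n = n, sex = sex, age = age,
                                           fatal = fatal, pts = pts)
  }
  suicide_pts <- c("anxiety", "completed suicide")
  add(18, "male", 50, TRUE, suicide_pts)     # suicide, 35-64
  add(24, "male", 70, TRUE, suicide_pts)     # suicide, 65+
  add(6, "female", 70, TRUE, suicide_pts)
  add(6, "unspecified", 70, TRUE, suicide_pts)
  add(34, "male", 50, TRUE, "anxiety")       # other fatal psychiatric, 35-64
  add(13, "male", 70, TRUE, "anxiety")
  add(42, "female", 70, TRUE, "anxiety")
  add(3165, "male", 30, FALSE, "anxiety")    # non-fatal psychiatric
  add(4705, "female", 30, FALSE, "anxiety")
  add(505, "unspecified", 30, FALSE, "anxiety")
  add(4367, "female", 30, FALSE, "vision blurred")   # eye-related
  add(1020, "male", 70, TRUE, "nausea")      # fatal, non-psychiatric
  add(30990, "female", 30, FALSE, "nausea")  # background

  n_total <- sum(vapply(blocks, `[[`, numeric(1), "n"))
  ids <- sprintf("P%05d", seq_len(n_total))
  off <- 0L
  cases <- list(); reacs <- list()
  for (b in blocks) {
    idx <- ids[(off + 1L):(off + b$n)]
    off <- off + b$n
    cases[[length(cases) + 1L]] <- tibble::tibble(
      case_id = idx, receive_date = as.Date("2020-06-01"), sex = b$sex,
      age_years = b$age, country = "united_states", reporter = "consumer",
      outcomes = rep(list(if (b$fatal) "died" else "non_serious"), b$n),
      indications = rep(list("urinary tract infection"), b$n)
    )
    reacs[[length(reacs) + 1L]] <- tibble::tibble(
      case_id = rep(idx, each = length(b$pts)),
      pt = rep(b$pts, times = b$n),
      event_date = as.Date(NA)
    )
  }
  cases <- dplyr::bind_rows(cases)
  drugs <- tibble::tibble(case_id = cases$case_id, drug = "ciprofloxacin",
                          role = "suspect", atc = "J01MA02",
                          start_date = as.Date(NA))
  report_set(cases, drugs, dplyr::bind_rows(reacs))
}

# two-PT dictionary for focused estimator experiments
small_dictionary <- function() {
  term_dictionary(data.frame(
    pt = c("anxiety", "drug ineffective"),
    hlgt = c("anxiety disorders and symptoms", "therapeutic responses"),
    soc = c("psychiatric disorders", "general disorders")
  ))
}

# single exposed stratum (prob 0.2) against a non-FQ comparator
one_exposure_probs <- c(
  ciprofloxacin = 0.2, levofloxacin = 0, moxifloxacin = 0, ofloxacin = 0,
  gemifloxacin = 0, delafloxacin = 0, multiple_fqs = 0,
  fq_plus_antibiotics = 0, fq_plus_other_meds = 0, non_fq = 0.8
)

# parameter-recovery condition: one planted pair, psi = 5, baseline odds
# 0.02, exposure probability 0.2, clean data (no duplicates, missingness or
# co-medication noise)
recovery_config <- function(n_cases, seed, psi = 5) {
  sim_config(
    n_cases = n_cases,
    exposure_probs = one_exposure_probs,
    baseline_event_odds = c("anxiety" = 0.02, "drug ineffective" = 0.05),
    planted_or = data.frame(exposure = "ciprofloxacin", pt = "anxiety",
                            psi = psi),
    duplicate_fraction = 0, psychotropic_rate = 0,
    missing_rates = c(age = 0, sex = 0, start_date = 0, event_date = 0),
    dictionary = small_dictionary(), seed = seed
  )
}

# all-null condition: every planted reporting odds ratio equals 1
null_config <- function(n_cases, seed) {
  sim_config(
    n_cases = n_cases,
    planted_or = data.frame(exposure = character(), pt = character(),
                            psi = numeric()),
    seed = seed
  )
}

# complete-demographics condition used to test the duplicate ledger: no
# missing fields, so independent reports are essentially never key-identical
complete_demo_config <- function(n_cases, seed, duplicate_fraction = 0.05) {
  sim_config(
    n_cases = n_cases, seed = seed, duplicate_fraction = duplicate_fraction,
    missing_rates = c(age = 0, sex = 0, start_date = 0.35, event_date = 0.30),
    demographic_marginals = list(
      age_group = c("0-17" = 0.02, "18-34" = 0.18, "35-64" = 0.50,
                    "65+" = 0.30, "unspecified" = 0),
      age_group_by_exposure = list(),
      sex = c(male = 0.45, female = 0.55, unspecified = 0)
    )
  )
}
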