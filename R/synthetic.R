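#' Built-in synthetic term dictionary
#'
#' A small synthetic stand-in for a licensed hierarchical adverse-event
#' dictionary: 24 preferred terms under their primary HLGT and SOC, covering
#' the two SOCs the pipeline screens (psychiatric disorders, eye disorders)
#' plus background organ classes so that comparator cases have realistic
#' coding. Term names follow field vocabulary but the mapping itself is
#' synthetic. The same table ships as
#' `inst/extdata/synthetic_dictionary.csv`.
#'
#' @return a `term_dictionary` tibble.
#' @export
default_dictionary <- function() {
  term_dictionary(tibble::tribble(
    ~pt, ~hlgt, ~soc,
    "anxiety", "anxiety disorders and symptoms", "psychiatric disorders",
    "panic attack", "anxiety disorders and symptoms", "psychiatric disorders",
    "insomnia", "sleep disorders and disturbances", "psychiatric disorders",
    "sleep disorder", "sleep disorders and disturbances", "psychiatric disorders",
    "delirium", "deliria (including confusion)", "psychiatric disorders",
    "hallucination", "disturbances in thinking and perception", "psychiatric disorders",
    "suicidal ideation", "suicidal and self-injurious behaviours", "psychiatric disorders",
    "completed suicide", "suicidal and self-injurious behaviours", "psychiatric disorders",
    "depressed mood", "depressed mood disorders and disturbances", "psychiatric disorders",
    "vision blurred", "vision disorders", "eye disorders",
    "visual impairment", "vision disorders", "eye disorders",
    "eye pain", "eye disorders nec", "eye disorders",
    "dry eye", "eye disorders nec", "eye disorders",
    "photophobia", "ocular sensory symptoms", "eye disorders",
    "iris transillumination defect", "anterior eye structural change, deposit and degeneration", "eye disorders",
    "pigment dispersion syndrome", "anterior eye structural change, deposit and degeneration", "eye disorders",
    "mydriasis", "pupil disorders", "eye disorders",
    "nausea", "gastrointestinal signs and symptoms", "gastrointestinal disorders",
    "diarrhoea", "gastrointestinal signs and symptoms", "gastrointestinal disorders",
    "tendonitis", "tendon, ligament and cartilage disorders", "musculoskeletal and connective tissue disorders",
    "arthralgia", "joint disorders", "musculoskeletal and connective tissue disorders",
    "drug ineffective", "therapeutic and nontherapeutic responses", "general disorders and administration site conditions",
    "fatigue", "general system disorders nec", "general disorders and administration site conditions",
    "cardiac arrest", "cardiac arrhythmias", "cardiac disorders"
  ))
}

# generator exposure categories: six monotherapies, three combination
# subtypes, and the non-FQ comparator stratum
pv_sim_categories <- c(pv_fluoroquinolones,
                       "multiple_fqs", "fq_plus_antibiotics", "fq_plus_other_meds",
                       "non_fq")

default_exposure_probs <- c(
  ciprofloxacin = 0.130, levofloxacin = 0.106, moxifloxacin = 0.044,
  ofloxacin = 0.005, gemifloxacin = 0.001, delafloxacin = 0.001,
  multiple_fqs = 0.024, fq_plus_antibiotics = 0.020, fq_plus_other_meds = 0.118,
  non_fq = 0.551
)

default_baseline_event_odds <- c(
  "anxiety" = 0.030, "panic attack" = 0.008, "insomnia" = 0.028,
  "sleep disorder" = 0.010, "delirium" = 0.006, "hallucination" = 0.007,
  "suicidal ideation" = 0.005, "completed suicide" = 0.002,
  "depressed mood" = 0.012,
  "vision blurred" = 0.020, "visual impairment" = 0.012, "eye pain" = 0.010,
  "dry eye" = 0.008, "photophobia" = 0.005,
  "iris transillumination defect" = 0.0008,
  "pigment dispersion syndrome" = 0.0005, "mydriasis" = 0.001,
  "nausea" = 0.060, "diarrhoea" = 0.050, "tendonitis" = 0.030,
  "arthralgia" = 0.040, "drug ineffective" = 0.050, "fatigue" = 0.050,
  "cardiac arrest" = 0.004
)

# default planted reporting odds ratios: a paper-shaped signal landscape
# (shared psychiatric and ocular signals across several agents plus
# moxifloxacin-specific anterior-segment terms, magnitudes scaled to be
# observable at simulation size)
default_planted_or <- function() {
  plant <- function(exposures, pt, psi) tibble(exposure = exposures, pt = pt, psi = psi)
  combos <- c("multiple_fqs", "fq_plus_antibiotics", "fq_plus_other_meds")
  core <- c("ciprofloxacin", "levofloxacin", "moxifloxacin")
  bind_rows(
    plant(c(core, combos), "anxiety", 6),
    plant(c("ciprofloxacin", "levofloxacin", combos), "panic attack", 15),
    plant(c(core, combos), "insomnia", 6),
    plant(core, "delirium", 9),
    plant(core, "hallucination", 6.5),
    plant(c("ciprofloxacin", "levofloxacin", combos), "suicidal ideation", 5.4),
    plant("ciprofloxacin", "completed suicide", 3),
    plant(c("ciprofloxacin", "moxifloxacin", "ofloxacin", combos), "vision blurred", 5),
    plant(c("ciprofloxacin", "moxifloxacin", "ofloxacin"), "photophobia", 12),
    plant(c("ciprofloxacin", "moxifloxacin", "ofloxacin", combos), "visual impairment", 5.5),
    plant(c("ciprofloxacin", "moxifloxacin"), "dry eye", 4),
    plant(c("ciprofloxacin", "moxifloxacin", "ofloxacin"), "eye pain", 6),
    plant("moxifloxacin", "iris transillumination defect", 60),
    plant("moxifloxacin", "pigment dispersion syndrome", 40),
    plant("moxifloxacin", "mydriasis", 15),
    plant(c(pv_fluoroquinolones, combos), "tendonitis", 8)
  )
}

#' Configuration of the synthetic spontaneous-report generator
#'
#' Bundles every knob of [simulate_reports()] with defaults that emulate the
#' marginal shape of a fluoroquinolone adverse-event cohort: exposure-category
#' shares (six monotherapies, three combination subtypes and a non-FQ
#' comparator stratum), per-PT baseline reporting odds in the comparator,
#' planted reporting odds ratios, demographic marginals, per-field missingness,
#' a duplicate-emission fraction, a psychotropic co-medication rate (feeding
#' the exclusion stage), and per-exposure log-normal onset-day parameters.
#'
#' @param n_cases number of core cases to generate (duplicates are emitted on
#'   top of these).
#' @param exposure_probs named probability vector over the generator exposure
#'   categories; must sum to 1.
#' @param baseline_event_odds named positive vector: odds of reporting each PT
#'   in the non-exposed stratum.
#' @param planted_or tibble with columns `exposure`, `pt`, `psi` giving true
#'   reporting odds ratios (`psi >= 0`); absent pairs have true ROR 1.
#' @param demographic_marginals list with named probability vectors `sex`,
#'   `age_group`, `country`, `reporter`, `outcome`, and optionally
#'   `age_group_by_exposure`, a list of per-exposure age-group probability
#'   vectors overriding the shared `age_group` marginal for those strata.
#' @param missing_rates named vector with entries `age`, `sex`, `start_date`,
#'   `event_date` in `[0, 1]`.
#' @param duplicate_fraction probability in `[0, 1)` that a case is emitted a
#'   second time under a fresh `case_id` with identical matching-key fields.
#' @param psychotropic_rate probability that a case carries a psychotropic
#'   (ATC N05/N06/N07B) concomitant drug.
#' @param tto_model list with numeric vectors `meanlog` and `sdlog`, either
#'   length 1 (shared) or named per exposure category: log-normal onset-day
#'   model.
#' @param covariate_or optional list planting demographic effects on event
#'   odds within one SOC, e.g.
#'   `list(soc = "psychiatric disorders", age_group = c("18-34" = 2.5))`;
#'   multipliers apply to the odds of every PT whose primary SOC matches.
#' @param dictionary a `term_dictionary`; defaults to [default_dictionary()].
#' @param seed integer seed; the generator is deterministic given the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 10000,
                       exposure_probs = default_exposure_probs,
                       baseline_event_odds = default_baseline_event_odds,
                       planted_or = default_planted_or(),
                       demographic_marginals = list(),
                       missing_rates = c(age = 0.18, sex = 0.07,
                                         start_date = 0.35, event_date = 0.30),
                       duplicate_fraction = 0.05,
                       psychotropic_rate = 0.04,
                       tto_model = list(meanlog = log(2), sdlog = 1.1),
                       covariate_or = NULL,
                       dictionary = default_dictionary(),
                       seed = 1L) {
  dm_default <- list(
    sex = c(male = 0.3725, female = 0.5350, unspecified = 0.0925),
    age_group = c("0-17" = 0.011, "18-34" = 0.159, "35-64" = 0.440,
                  "65+" = 0.220, "unspecified" = 0.170),
    # age composition differs by agent (moxifloxacin cohorts skew older,
    # ciprofloxacin younger), which also gives the imputation stage a
    # genuinely informative neighbourhood structure
    age_group_by_exposure = list(
      ciprofloxacin = c("0-17" = 0.011, "18-34" = 0.238, "35-64" = 0.452,
                        "65+" = 0.117, "unspecified" = 0.182),
      levofloxacin = c("0-17" = 0.009, "18-34" = 0.121, "35-64" = 0.447,
                       "65+" = 0.206, "unspecified" = 0.217),
      moxifloxacin = c("0-17" = 0.004, "18-34" = 0.090, "35-64" = 0.326,
                       "65+" = 0.416, "unspecified" = 0.164)
    ),
    country = c(united_states = 0.30, great_britain = 0.13, germany = 0.08,
                france = 0.07, italy = 0.05, canada = 0.04, japan = 0.04,
                australia = 0.02, other = 0.08, unspecified = 0.19),
    reporter = c(consumer = 0.68, healthcare_professional = 0.285,
                 unspecified = 0.035),
    outcome = c(died = 0.026, life_threatening = 0.06, hospitalized = 0.14,
                disabled = 0.20, other_serious = 0.424, non_serious = 0.15)
  )
  # replace each supplied marginal wholesale (a recursive merge would keep
  # default per-exposure profiles even when the caller clears them)
  dm <- dm_default
  for (nm in names(demographic_marginals)) dm[[nm]] <- demographic_marginals[[nm]]

  cfg <- structure(list(
    n_cases = as.integer(n_cases),
    exposure_probs = exposure_probs,
    baseline_event_odds = baseline_event_odds,
    planted_or = as_tibble(planted_or),
    demographic_marginals = dm,
    missing_rates = missing_rates,
    duplicate_fraction = duplicate_fraction,
    psychotropic_rate = psychotropic_rate,
    tto_model = tto_model,
    covariate_or = covariate_or,
    dictionary = dictionary,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_cases < 1L) stopf("n_cases must be positive")
  if (!setequal(names(cfg$exposure_probs), pv_sim_categories)) {
    stopf("exposure_probs must be named over: %s",
          paste(pv_sim_categories, collapse = ", "))
  }
  assert_probability_vector(cfg$exposure_probs, "exposure_probs")
  for (nm in c("sex", "age_group", "country", "reporter", "outcome")) {
    assert_probability_vector(cfg$demographic_marginals[[nm]],
                              paste0("demographic_marginals$", nm))
  }
  for (ex in names(cfg$demographic_marginals$age_group_by_exposure %||% list())) {
    assert_probability_vector(
      cfg$demographic_marginals$age_group_by_exposure[[ex]],
      sprintf("age_group_by_exposure$%s", ex)
    )
  }
  if (any(cfg$baseline_event_odds <= 0)) stopf("baseline event odds must be positive")
  if (nrow(cfg$planted_or)) {
    if (any(cfg$planted_or$psi < 0)) stopf("planted psi must be >= 0")
    unknown <- setdiff(cfg$planted_or$pt, names(cfg$baseline_event_odds))
    if (length(unknown)) {
      stopf("planted PT(s) missing from baseline_event_odds: %s",
            paste(head(unknown, 5L), collapse = ", "))
    }
  }
  if (cfg$duplicate_fraction < 0 || cfg$duplicate_fraction >= 1) {
    stopf("duplicate_fraction must be in [0, 1)")
  }
  bad <- setdiff(names(cfg$baseline_event_odds), cfg$dictionary$pt)
  if (length(bad)) {
    stopf("baseline_event_odds PT(s) absent from dictionary: %s",
          paste(head(bad, 5L), collapse = ", "))
  }
  invisible(cfg)
}

#' True reporting odds ratio planted for an exposure/term pair
#'
#' The analytic target the downstream estimator must recover: the planted
#' `psi` when the pair is in the config's `planted_or` table, and 1 otherwise.
#'
#' @param config a `sim_config`.
#' @param exposure a generator exposure category.
#' @param pt a preferred term present in `baseline_event_odds`.
#' @return a single non-negative number.
#' @export
true_ror <- function(config, exposure, pt) {
  if (!pt %in% names(config$baseline_event_odds)) stopf("unknown PT: %s", pt)
  if (!exposure %in% pv_sim_categories) stopf("unknown exposure category: %s", exposure)
  hit <- config$planted_or$psi[config$planted_or$exposure == exposure &
                                 config$planted_or$pt == pt]
  if (length(hit)) hit[[1L]] else 1
}

#' Generate a synthetic spontaneous-report dataset with known ground truth
#'
#' Draws an exposure category, demographics, outcome flag, drug panel and
#' reaction set for each case. Events are generated per PT independently given
#' exposure with odds `psi * baseline_odds` (the planted reporting-odds
#' mechanism); cases drawing no event receive the filler background term
#' `"drug ineffective"` so every case has at least one reaction. Onset days
#' are log-normal (rounded to whole days) and `event_date = start_date +
#' onset`. Field-level missingness, psychotropic co-medication and duplicate
#' emission (clones share every matching-key field under a fresh, larger
#' `case_id`) are applied last. The same config (including seed) yields an
#' identical dataset.
#'
#' @param config a [sim_config()].
#' @return list with elements `reports` (a `report_set`) and `truth` (a
#'   `sim_truth`: the planted table, realized per-pair case counts among
#'   clean core cases, the duplicate ledger, and per-case assignments).
#' @export
simulate_reports <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_reports_impl(config))
}

simulate_reports_impl <- function(cfg) {
  n <- cfg$n_cases
  dm <- cfg$demographic_marginals
  id <- sprintf("C%07d", seq_len(n))

  exposure <- sample(names(cfg$exposure_probs), n, replace = TRUE,
                     prob = cfg$exposure_probs)
  sex <- sample(names(dm$sex), n, TRUE, dm$sex)
  age_group <- sample(names(dm$age_group), n, TRUE, dm$age_group)
  for (ex in names(dm$age_group_by_exposure %||% list())) {
    sel <- exposure == ex
    if (any(sel)) {
      pr <- dm$age_group_by_exposure[[ex]][names(dm$age_group)]
      age_group[sel] <- sample(names(dm$age_group), sum(sel), TRUE, pr)
    }
  }
  age_lo <- c("0-17" = 0, "18-34" = 18, "35-64" = 35, "65+" = 65,
              "unspecified" = 0)[age_group]
  age_hi <- c("0-17" = 17, "18-34" = 34, "35-64" = 64, "65+" = 95,
              "unspecified" = 0)[age_group]
  age <- ifelse(age_group == "unspecified", NA_real_,
                floor(runif(n, age_lo, age_hi + 1)))
  country <- sample(names(dm$country), n, TRUE, dm$country)
  reporter <- sample(names(dm$reporter), n, TRUE, dm$reporter)
  outcome <- sample(names(dm$outcome), n, TRUE, dm$outcome)

  # --- events: odds(event | exposure) = psi * baseline odds, per PT ---------
  pts <- names(cfg$baseline_event_odds)
  cat_idx <- match(exposure, pv_sim_categories)
  psi_mat <- matrix(1, nrow = length(pv_sim_categories), ncol = length(pts),
                    dimnames = list(pv_sim_categories, pts))
  if (nrow(cfg$planted_or)) {
    psi_mat[cbind(match(cfg$planted_or$exposure, pv_sim_categories),
                  match(cfg$planted_or$pt, pts))] <- cfg$planted_or$psi
  }
  cov_mult <- rep(1, n)
  cov_soc_pts <- character()
  if (!is.null(cfg$covariate_or)) {
    cov_soc_pts <- cfg$dictionary$pt[cfg$dictionary$soc == cfg$covariate_or$soc]
    if (!is.null(cfg$covariate_or$age_group)) {
      m <- cfg$covariate_or$age_group[age_group]
      cov_mult <- cov_mult * ifelse(is.na(m), 1, m)
    }
    if (!is.null(cfg$covariate_or$sex)) {
      m <- cfg$covariate_or$sex[sex]
      cov_mult <- cov_mult * ifelse(is.na(m), 1, m)
    }
  }
  event_mat <- matrix(0L, nrow = n, ncol = length(pts))
  for (j in seq_along(pts)) {
    odds <- cfg$baseline_event_odds[[j]] * psi_mat[cat_idx, j]
    if (pts[[j]] %in% cov_soc_pts) odds <- odds * cov_mult
    event_mat[, j] <- rbinom(n, 1L, odds / (1 + odds))
  }
  # filler background PT so every case has >= 1 reaction
  filler <- "drug ineffective"
  no_event <- rowSums(event_mat) == 0L
  event_mat[no_event, match(filler, pts)] <- 1L

  # --- dates ----------------------------------------------------------------
  tm <- cfg$tto_model
  pick <- function(par) {
    if (length(par) == 1L && is.null(names(par))) rep(par, n)
    else {
      v <- par[exposure]
      ifelse(is.na(v), par[[1L]], v)
    }
  }
  onset <- round(rlnorm(n, pick(tm$meanlog), pick(tm$sdlog)))
  start_date <- as.Date("2011-01-01") + sample.int(5100L, n, replace = TRUE) - 1L
  event_date <- start_date + onset
  receive_date <- event_date + rpois(n, 15)

  # --- drugs ----------------------------------------------------------------
  combo_fq <- sample(c("ciprofloxacin", "levofloxacin", "moxifloxacin"),
                     n, TRUE, c(0.5, 0.3, 0.2))
  atc_table <- c(pv_fq_atc, metronidazole = "J01XD01", amoxicillin = "J01CA04",
                 gentamicin = "J01GB03", aspirin = "B01AC06",
                 levothyroxine = "H03AA01", lisinopril = "C09AA03",
                 metformin = "A10BA02", sertraline = "N06AB06",
                 diazepam = "N05BA01", nicotine = "N07BA01")
  base_drug <- ifelse(exposure == "non_fq", "amoxicillin",
                      ifelse(exposure %in% pv_fluoroquinolones, exposure,
                             combo_fq))
  partner <- ifelse(combo_fq == "ciprofloxacin", "levofloxacin", "ciprofloxacin")
  other_med <- sample(c("aspirin", "levothyroxine", "lisinopril", "metformin"),
                      n, TRUE)
  second <- rep(NA_character_, n)
  second[exposure == "multiple_fqs"] <- partner[exposure == "multiple_fqs"]
  second[exposure == "fq_plus_antibiotics"] <- "metronidazole"
  second[exposure == "fq_plus_other_meds"] <- other_med[exposure == "fq_plus_other_meds"]
  second_role <- ifelse(exposure == "multiple_fqs", "suspect", "concomitant")
  has2 <- !is.na(second)
  drug_case <- c(id, id[has2])
  drug_name <- c(base_drug, second[has2])
  drug_role <- c(rep("suspect", n), second_role[has2])
  drug_atc <- unname(atc_table[drug_name])
  drug_start <- c(start_date, start_date[has2])

  has_psy <- runif(n) < cfg$psychotropic_rate
  psy_pick <- sample(c("sertraline", "diazepam", "nicotine"), n, TRUE)
  if (any(has_psy)) {
    drug_case <- c(drug_case, id[has_psy])
    drug_name <- c(drug_name, psy_pick[has_psy])
    drug_role <- c(drug_role, rep("concomitant", sum(has_psy)))
    drug_atc <- c(drug_atc, unname(atc_table[psy_pick[has_psy]]))
    drug_start <- c(drug_start, start_date[has_psy])
  }

  indication_pool <- c("urinary tract infection", "pneumonia", "sinusitis",
                       "bronchitis", "cough", "skin infection",
                       "prostatitis", "diverticulitis", "pyelonephritis",
                       "gastroenteritis")
  ind_probs <- c(0.28, 0.16, 0.13, 0.09, 0.03, 0.12, 0.06, 0.05, 0.05, 0.03)
  ind1 <- sample(indication_pool, n, TRUE, ind_probs)
  ind2 <- sample(indication_pool, n, TRUE, ind_probs)
  indication <- as.list(ind1)
  two <- runif(n) < 0.25 & ind2 != ind1
  indication[two] <- Map(c, ind1[two], ind2[two])

  # --- missingness ----------------------------------------------------------
  mr <- cfg$missing_rates
  age[runif(n) < mr[["age"]]] <- NA_real_
  sex[runif(n) < mr[["sex"]]] <- "unspecified"
  start_missing <- runif(n) < mr[["start_date"]]
  event_missing <- runif(n) < mr[["event_date"]]
  drug_start[start_missing[match(drug_case, id)]] <- NA

  # --- assemble core tables -------------------------------------------------
  ev_idx <- which(event_mat == 1L, arr.ind = TRUE)
  ev_ord <- order(ev_idx[, 1L], ev_idx[, 2L])
  reac_case <- id[ev_idx[ev_ord, 1L]]
  reac_pt <- pts[ev_idx[ev_ord, 2L]]
  reac_date <- event_date[ev_idx[ev_ord, 1L]]
  reac_date[event_missing[ev_idx[ev_ord, 1L]]] <- NA

  cases <- tibble(
    case_id = id, receive_date = receive_date, sex = sex, age_years = age,
    country = country, reporter = reporter,
    outcomes = as.list(outcome), indications = indication
  )
  drugs <- tibble(case_id = drug_case, drug = drug_name, role = drug_role,
                  atc = drug_atc, start_date = drug_start)
  reactions <- tibble(case_id = reac_case, pt = reac_pt, event_date = reac_date)

  # --- duplicates: clone after generation, fresh id, identical fields -------
  dup_idx <- which(runif(n) < cfg$duplicate_fraction)
  dup_ledger <- tibble(original_id = id[dup_idx],
                       clone_id = paste0(id[dup_idx], "D"))
  if (length(dup_idx)) {
    clone_map <- setNames(dup_ledger$clone_id, dup_ledger$original_id)
    cl_cases <- cases[dup_idx, ]
    cl_cases$case_id <- unname(clone_map[cl_cases$case_id])
    cl_drugs <- drugs[drugs$case_id %in% dup_ledger$original_id, ]
    cl_drugs$case_id <- unname(clone_map[cl_drugs$case_id])
    cl_reac <- reactions[reactions$case_id %in% dup_ledger$original_id, ]
    cl_reac$case_id <- unname(clone_map[cl_reac$case_id])
    cases <- bind_rows(cases, cl_cases)
    drugs <- bind_rows(drugs, cl_drugs)
    reactions <- bind_rows(reactions, cl_reac)
  }

  # --- truth ledger ---------------------------------------------------------
  clean <- !has_psy  # cases surviving the exclusion stage
  realized <- tibble(case_id = id[ev_idx[, 1L]], exposure = exposure[ev_idx[, 1L]],
                     pt = pts[ev_idx[, 2L]], clean = clean[ev_idx[, 1L]]) %>%
    filter(.data$clean) %>%
    count(.data$exposure, .data$pt, name = "n_cases")
  truth <- structure(list(
    planted_or = cfg$planted_or,
    realized = realized,
    duplicates = dup_ledger,
    assignments = tibble(case_id = id, exposure = exposure,
                         age_group_true = age_group, sex_true = sex,
                         psychotropic = has_psy),
    n_clean_core = sum(clean),
    clean_exposure_totals = tibble(exposure = exposure[clean]) %>%
      count(.data$exposure, name = "n")
  ), class = "sim_truth")

  list(reports = report_set(cases, drugs, reactions), truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d planted pairs, %d duplicate clones, %d clean core cases\n",
    nrow(x$planted_or), nrow(x$duplicates), x$n_clean_core
  ))
  invisible(x)
}
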