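#' Controlled vocabularies used throughout the pipeline
#'
#' Character constants shared by the reader, the generator and the analysis
#' stages: outcome flags (ordered from most to least severe), sex and reporter
#' codes, the six FDA-approved fluoroquinolones screened by the pipeline, the
#' ATC prefixes excluded as psychotropic co-medication, and the age-group bins.
#'
#' @name vocabularies
#' @keywords internal
NULL

# outcome flags, ordered by severity precedence (most severe first)
pv_outcome_flags <- c(
  "died", "life_threatening", "hospitalized", "disabled",
  "other_serious", "non_serious"
)

pv_sex_levels <- c("male", "female", "unspecified")
pv_reporter_levels <- c("consumer", "healthcare_professional", "unspecified")

#' @rdname vocabularies
#' @format NULL
#' @export
pv_fluoroquinolones <- c(
  "ciprofloxacin", "levofloxacin", "moxifloxacin",
  "ofloxacin", "gemifloxacin", "delafloxacin"
)

# WHO ATC codes of the six fluoroquinolones (J01MA group)
pv_fq_atc <- c(
  ciprofloxacin = "J01MA02", levofloxacin = "J01MA12",
  moxifloxacin = "J01MA14", ofloxacin = "J01MA01",
  gemifloxacin = "J01MA15", delafloxacin = "J01MA23"
)

#' @rdname vocabularies
#' @format NULL
#' @export
pv_psychotropic_atc_prefixes <- c("N05", "N06", "N07B")

pv_age_group_levels <- c("0-17", "18-34", "35-64", "65+", "unspecified")

pv_exposure_levels <- c(pv_fluoroquinolones, "combination", "non_fq")

pv_combination_subtypes <- c(
  "multiple_fqs", "fq_plus_antibiotics", "fq_plus_other_meds", "none"
)

pv_severity_levels <- c("critical", "serious", "non_serious")

pv_hierarchy_levels <- c("PT", "HLGT", "SOC")
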