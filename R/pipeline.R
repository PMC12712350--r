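#' Run the full screening pipeline from a single configuration
#'
#' Orchestrates simulate (or load) -> preprocess -> disproportionality
#' screen -> descriptive tables -> time-to-onset -> risk factors, writing
#' every stage's output with a stable schema plus a reproducible run
#' manifest. Given the same configuration (including its seed) the result
#' tables are byte-identical across runs.
#'
#' The configuration is a named list (or a YAML file with the same
#' structure):
#' \describe{
#'   \item{seed}{integer, the single source of randomness.}
#'   \item{simulate}{optional list of [sim_config()] arguments; when absent,
#'     `input` must point to a cases CSV.}
#'   \item{input}{optional path to a cases CSV (ignored when `simulate` is
#'     present).}
#'   \item{dictionary}{path to a dictionary CSV, or `"default"` for the
#'     built-in synthetic dictionary.}
#'   \item{signals}{list: `levels` (default PT/HLGT/SOC), `min_cases`
#'     (default 3).}
#'   \item{describe}{list: `soc` for the fatal-case report (default
#'     psychiatric disorders).}
#'   \item{tto}{list: `soc` filter (default psychiatric disorders).}
#'   \item{risk}{list: `outcome_soc` (default psychiatric disorders), `k`
#'     (default 5).}
#' }
#'
#' @param config a named list or the path to a YAML config file.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the run manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config_hash <- rlang::hash(cfg)
  checksums <- list()

  # --- stage: obtain cases -------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    sc <- do.call(sim_config, sim_args)
    sim <- simulate_reports(sc)
    rs <- sim$reports
    jsonlite::write_json(
      list(planted_or = sim$truth$planted_or,
           duplicates = sim$truth$duplicates,
           realized = sim$truth$realized),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
    write_cases(rs, file.path(out_dir, "cases.csv"))
  } else {
    rs <- read_cases(cfg$input)
    checksums[[cfg$input]] <- unname(tools::md5sum(cfg$input))
  }
  dictionary <- if (identical(cfg$dictionary, "default")) default_dictionary()
  else {
    checksums[[cfg$dictionary]] <- unname(tools::md5sum(cfg$dictionary))
    read_dictionary(cfg$dictionary)
  }

  # --- stage: preprocess ---------------------------------------------------
  pp <- preprocess(rs)
  write_cases(pp$reports, file.path(out_dir, "clean.csv"))
  jsonlite::write_json(
    list(counts = as.list(pp$counts),
         removed_duplicates = pp$removed_duplicates,
         excluded = pp$excluded),
    file.path(out_dir, "preprocess_report.json"), auto_unbox = TRUE, digits = NA
  )

  # --- stage: disproportionality screen ------------------------------------
  sig <- screen_signals(pp$reports, dictionary,
                        levels = cfg$signals$levels,
                        min_cases = cfg$signals$min_cases)
  write_result_tsv(tidy(sig), file.path(out_dir, "signals.tsv"))

  # --- stage: descriptive --------------------------------------------------
  desc <- stratified_counts(pp$reports, "sex", "exposure_category")
  write_result_tsv(desc, file.path(out_dir, "descriptive_sex.tsv"))
  desc_age <- stratified_counts(pp$reports, "age_group", "exposure_category")
  write_result_tsv(desc_age, file.path(out_dir, "descriptive_age_group.tsv"))
  fatal <- characterize_fatal(pp$reports, dictionary, soc = cfg$describe$soc)
  jsonlite::write_json(
    list(n_subset = fatal$n_subset, n_fatal = fatal$n_fatal,
         fatal_pct = fatal$fatal_pct, pt_ranking = fatal$pt_ranking,
         sex = fatal$sex, age_group = fatal$age_group),
    file.path(out_dir, "fatal_report.json"), auto_unbox = TRUE, digits = NA
  )

  # --- stage: time-to-onset ------------------------------------------------
  tto <- compute_tto(pp$reports, dictionary, soc = cfg$tto$soc)
  tto_summary <- tto$samples %>%
    group_by(.data$exposure_category) %>%
    summarise(
      n = dplyr::n(),
      median_days = median(.data$tto_days),
      q1 = unname(quantile(.data$tto_days, 0.25, type = 7)),
      q3 = unname(quantile(.data$tto_days, 0.75, type = 7)),
      frac_within_7 = mean(.data$tto_days <= 7),
      .groups = "drop"
    )
  write_result_tsv(tto_summary, file.path(out_dir, "tto.tsv"))
  if (nrow(tto$samples)) {
    write_result_tsv(tto_ecdf(tto)$points, file.path(out_dir, "ecdf.tsv"))
  }

  # --- stage: risk factors -------------------------------------------------
  risk <- risk_factor_screen(pp$reports, dictionary,
                             outcome_soc = cfg$risk$outcome_soc,
                             k = cfg$risk$k)
  write_result_tsv(tidy(risk), file.path(out_dir, "odds_ratios.tsv"))

  manifest <- list(
    tool = "pvror",
    version = as.character(utils::packageVersion("pvror")),
    config_hash = config_hash,
    input_checksums = checksums,
    seed = cfg$seed,
    counts = as.list(pp$counts),
    n_signals = sum(sig$is_signal),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (is.unsorted(rev(unlist(pp$counts)))) {
    stopf("internal error: stage counts must be non-increasing")
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

validate_pipeline_config <- function(config) {
  if (!is.list(config)) stopf("config must be a named list or YAML path")
  defaults <- list(
    seed = 1L,
    simulate = NULL,
    input = NULL,
    dictionary = "default",
    signals = list(levels = pv_hierarchy_levels, min_cases = 3),
    describe = list(soc = "psychiatric disorders"),
    tto = list(soc = "psychiatric disorders"),
    risk = list(outcome_soc = "psychiatric disorders", k = 5L)
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    stopf("config must provide either 'simulate' parameters or an 'input' path")
  }
  for (block in c("signals", "describe", "tto", "risk")) {
    cfg[[block]] <- utils::modifyList(defaults[[block]], cfg[[block]] %||% list())
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# stable TSV writer: UTF-8, tab-delimited, "." decimal, ratios at 6
# significant digits so repeated runs are byte-comparable
write_result_tsv <- function(df, path) {
  df[] <- lapply(df, function(col) if (is.double(col)) signif(col, 6) else col)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
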