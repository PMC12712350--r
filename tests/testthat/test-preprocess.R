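test_that("dedup retains the lexicographically smallest id of a duplicate group", {
  rs <- mk_report_set(list(
    list(id = "B", sex = "male", age = 40),
    list(id = "A", sex = "male", age = 40)
  ))
  out <- deduplicate(rs)
  expect_identical(out$reports$cases$case_id, "A")
  expect_identical(out$removed$removed_id, "B")
  expect_identical(out$removed$retained_id, "A")
})

test_that("any differing key field keeps both cases", {
  base <- list(sex = "male", age = 40)
  rs <- mk_report_set(list(
    c(list(id = "A", country = "france"), base),
    c(list(id = "B", country = "germany"), base)
  ))
  out <- deduplicate(rs)
  expect_identical(sort(out$reports$cases$case_id), c("A", "B"))
  # and missing matches missing: two NA ages with equal other fields collapse
  rs2 <- mk_report_set(list(
    list(id = "A", age = NULL), list(id = "B", age = NULL)
  ))
  rs2$cases$age_years <- NA_real_
  expect_identical(deduplicate(rs2)$reports$cases$case_id, "A")
})

test_that("dedup removes exactly the generator's duplicate ledger", {
  sim <- simulate_reports(complete_demo_config(5000, seed = 17))
  out <- deduplicate(sim$reports)
  expect_setequal(out$removed$removed_id, sim$truth$duplicates$clone_id)
  # each clone is matched back to its original
  ledger <- sim$truth$duplicates[
    order(sim$truth$duplicates$clone_id), ]
  removed <- out$removed[order(out$removed$removed_id), ]
  expect_identical(removed$retained_id, ledger$original_id)
})

test_that("clones are always among the removed under the default config", {
  sim <- simulate_reports(sim_config(n_cases = 5000, seed = 19))
  out <- deduplicate(sim$reports)
  expect_true(all(sim$truth$duplicates$clone_id %in% out$removed$removed_id))
})

test_that("dedup and exclusion are idempotent, order-invariant and conserving", {
  sim <- simulate_reports(sim_config(n_cases = 3000, seed = 23))
  rs <- sim$reports

  d1 <- deduplicate(rs)
  d2 <- deduplicate(d1$reports)
  expect_identical(sort(d2$reports$cases$case_id),
                   sort(d1$reports$cases$case_id))
  expect_identical(nrow(d2$removed), 0L)
  expect_identical(nrow(d1$removed) + n_cases(d1$reports), n_cases(rs))

  # shuffling input order changes neither retained set nor classification
  perm <- withr::with_seed(1, sample.int(n_cases(rs)))
  shuffled <- rs
  shuffled$cases <- rs$cases[perm, ]
  dp <- deduplicate(shuffled)
  expect_setequal(dp$reports$cases$case_id, d1$reports$cases$case_id)

  e1 <- exclude_psychotropics(d1$reports)
  expect_identical(nrow(e1$excluded) + n_cases(e1$reports),
                   n_cases(d1$reports))
  e2 <- exclude_psychotropics(e1$reports)
  expect_identical(nrow(e2$excluded), 0L)

  cl_a <- classify_exposure(e1$reports)
  cl_b <- classify_exposure(filter_reports(shuffled, e1$reports$cases$case_id))
  ja <- cl_a$cases[order(cl_a$cases$case_id), c("case_id", "exposure_category",
                                                "combination_subtype")]
  jb <- cl_b$cases[order(cl_b$cases$case_id), c("case_id", "exposure_category",
                                                "combination_subtype")]
  expect_equal(ja, jb, ignore_attr = TRUE)
})

test_that("psychotropic exclusion matches ATC prefixes precisely", {
  rs <- mk_report_set(list(
    list(id = "A", drugs = c("ciprofloxacin|suspect|J01MA02|",
                             "diazepam|concomitant|N05BA01|")),
    list(id = "B", drugs = c("ciprofloxacin|suspect|J01MA02|",
                             "pramipexole|concomitant|N04BC05|")),
    list(id = "C", drugs = c("ciprofloxacin|suspect|J01MA02|",
                             "varenicline|concomitant|N07BA03|")),
    list(id = "D", drugs = "moxifloxacin|suspect|J01MA14,S01AE07|")
  ))
  out <- exclude_psychotropics(rs)
  expect_setequal(out$excluded$case_id, c("A", "C"))
  expect_setequal(out$reports$cases$case_id, c("B", "D"))

  # counted fixture: 10 cases, 3 carrying N06 codes
  specs <- lapply(1:10, function(i) {
    drugs <- "ciprofloxacin|suspect|J01MA02|"
    if (i <= 3) drugs <- c(drugs, "sertraline|concomitant|N06AB06|")
    list(id = sprintf("X%02d", i), drugs = drugs)
  })
  out2 <- exclude_psychotropics(mk_report_set(specs))
  expect_identical(n_cases(out2$reports), 7L)
  expect_identical(nrow(out2$excluded), 3L)
})

test_that("exposure classification follows the monotherapy/combination rules", {
  rs <- mk_report_set(list(
    list(id = "A", drugs = "ciprofloxacin|suspect|J01MA02|"),
    list(id = "B", drugs = c("ciprofloxacin|suspect|J01MA02|",
                             "levofloxacin|suspect|J01MA12|")),
    list(id = "C", drugs = c("ciprofloxacin|suspect|J01MA02|",
                             "metronidazole|concomitant|J01XD01|")),
    list(id = "D", drugs = c("ciprofloxacin|suspect|J01MA02|",
                             "aspirin|concomitant|B01AC06|")),
    list(id = "E", drugs = "lisinopril|suspect|C09AA03|")
  ))
  cl <- classify_exposure(rs)$cases
  got <- setNames(cl$exposure_category, cl$case_id)
  sub <- setNames(cl$combination_subtype, cl$case_id)
  expect_identical(got[["A"]], "ciprofloxacin")
  expect_identical(sub[["A"]], "none")
  expect_identical(got[["B"]], "combination")
  expect_identical(sub[["B"]], "multiple_fqs")
  expect_identical(got[["C"]], "combination")
  expect_identical(sub[["C"]], "fq_plus_antibiotics")
  expect_identical(got[["D"]], "combination")
  expect_identical(sub[["D"]], "fq_plus_other_meds")
  expect_identical(got[["E"]], "non_fq")

  expect_error(classify_exposure(rs, tag_background = FALSE),
               "without any suspect")
})

test_that("classification recovers the generator's exposure assignment", {
  sim <- simulate_reports(sim_config(n_cases = 5000, duplicate_fraction = 0,
                                     psychotropic_rate = 0, seed = 29))
  cl <- classify_exposure(sim$reports)$cases
  truth <- sim$truth$assignments
  combo <- c("multiple_fqs", "fq_plus_antibiotics", "fq_plus_other_meds")
  expected <- ifelse(truth$exposure %in% combo, "combination", truth$exposure)
  expect_identical(cl$exposure_category[match(truth$case_id, cl$case_id)],
                   expected)
})

test_that("age groups bin on the printed boundaries", {
  expect_identical(derive_age_group(c(17, 18, 64, 65, NA, 0)),
                   c("0-17", "18-34", "35-64", "65+", "unspecified", "0-17"))
  expect_error(derive_age_group(-1), "negative")
})

test_that("the preprocessing ledger is monotone and complete", {
  sim <- simulate_reports(sim_config(n_cases = 2000, seed = 31))
  pp <- preprocess(sim$reports)
  expect_true(all(diff(unname(pp$counts)) <= 0))
  expect_identical(unname(pp$counts[["raw"]]), n_cases(sim$reports))
  expect_identical(
    pp$counts[["deduplicated"]] - nrow(pp$excluded),
    pp$counts[["post_exclusion"]]
  )
  expect_true(!is.null(pp$reports$cases$exposure_category))
})
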