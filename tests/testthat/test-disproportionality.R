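test_that("ROR point estimate and log-Wald interval match the closed form", {
  est <- ror_estimate(10, 10, 10, 10)
  expect_identical(est$ror, 1)
  expect_false(est$corrected)

  est <- ror_estimate(30, 70, 100, 900)
  oracle <- ror_oracle(30, 70, 100, 900)
  expect_equal(est$ror, 27 / 7, tolerance = 1e-12)
  expect_equal(est$ci_low, oracle[["lo"]], tolerance = 1e-12)
  expect_equal(est$ci_high, oracle[["hi"]], tolerance = 1e-12)
  # the CI the formula yields at these counts
  expect_equal(round(est$ci_low, 2), 2.40)
  expect_equal(round(est$ci_high, 2), 6.20)
})

test_that("zero cells trigger the continuity correction and stay finite", {
  est <- ror_estimate(0, 10, 10, 980)
  expect_true(est$corrected)
  expect_true(is.finite(est$ror) && est$ror > 0)
  oracle <- ror_oracle(0.5, 10.5, 10.5, 980.5)
  expect_equal(est$ror, oracle[["ror"]], tolerance = 1e-12)
  expect_equal(est$ci_low, oracle[["lo"]], tolerance = 1e-12)
  # non-degenerate tables are left untouched
  expect_false(ror_estimate(1, 10, 10, 980)$corrected)
  # undefined strata error out
  expect_error(ror_estimate(0, 0, 5, 5), "undefined stratum")
})

test_that("ROR transposition and monotonicity identities hold", {
  set.seed(42)
  for (i in 1:50) {
    cells <- sample(1:200, 4, replace = TRUE)
    r1 <- ror_estimate(cells[1], cells[2], cells[3], cells[4])$ror
    r2 <- ror_estimate(cells[2], cells[1], cells[4], cells[3])$ror
    expect_equal(r1 * r2, 1, tolerance = 1e-12)
  }
  rors <- ror_estimate(5:15, 50, 40, 400)$ror
  expect_true(all(diff(rors) > 0))
})

test_that("ROR equals the univariate logistic odds ratio on the same 2x2", {
  a <- 30; b <- 70; c <- 100; d <- 900
  est <- ror_estimate(a, b, c, d)
  exposed <- rep(c(1, 1, 0, 0), times = c(a, b, c, d))
  event <- rep(c(1, 0, 1, 0), times = c(a, b, c, d))
  fit <- glm(event ~ exposed, family = binomial())
  expect_equal(est$ror, exp(coef(fit)[["exposed"]]), tolerance = 1e-6)
})

test_that("contingency tables count cases, not reactions", {
  rs <- mk_report_set(list(
    list(id = "A", drugs = "ciprofloxacin|suspect|J01MA02|",
         reactions = "anxiety|"),
    list(id = "B", drugs = "ciprofloxacin|suspect|J01MA02|",
         reactions = "nausea|"),
    list(id = "C", drugs = "lisinopril|suspect|C09AA03|",
         reactions = "anxiety|"),
    list(id = "D", drugs = "lisinopril|suspect|C09AA03|",
         reactions = "nausea|")
  ))
  rs <- classify_exposure(rs)
  tab <- build_contingency(rs, "ciprofloxacin", "anxiety", "PT")
  expect_identical(unlist(tab), c(a = 1L, b = 1L, c = 1L, d = 1L))

  # two PTs under the same HLGT contribute once at HLGT level
  rs2 <- mk_report_set(list(
    list(id = "A", drugs = "ciprofloxacin|suspect|J01MA02|",
         reactions = c("anxiety|", "panic attack|")),
    list(id = "B", drugs = "lisinopril|suspect|C09AA03|",
         reactions = "nausea|")
  ))
  rs2 <- classify_exposure(rs2)
  tab2 <- build_contingency(rs2, "ciprofloxacin",
                            "anxiety disorders and symptoms", "HLGT")
  expect_identical(tab2$a, 1L)
  expect_identical(sum(unlist(tab2)), 2L)
  expect_error(
    build_contingency(rs2, "ciprofloxacin", "no such term", "PT"),
    "unknown PT term"
  )
})

test_that("screen table cells equal the generator's realized counts", {
  sim <- simulate_reports(sim_config(n_cases = 5000, duplicate_fraction = 0,
                                     psychotropic_rate = 0, seed = 37))
  cl <- classify_exposure(sim$reports)
  sig <- screen_signals(cl, default_dictionary(), levels = "PT",
                        min_cases = 1, include_all_fq = FALSE)
  realized <- sim$truth$realized
  mono <- sig[sig$exposure %in% pv_fluoroquinolones, ]
  for (i in seq_len(nrow(mono))) {
    want <- realized$n_cases[realized$exposure == mono$exposure[i] &
                               realized$pt == mono$term[i]]
    expect_identical(mono$a[i], as.integer(want))
  }
  # combination rows aggregate the three generator subtypes
  combo_rows <- sig[sig$exposure == "combination", ]
  combo_truth <- realized[realized$exposure %in%
                            c("multiple_fqs", "fq_plus_antibiotics",
                              "fq_plus_other_meds"), ]
  for (i in seq_len(nrow(combo_rows))) {
    want <- sum(combo_truth$n_cases[combo_truth$pt == combo_rows$term[i]])
    expect_identical(combo_rows$a[i], as.integer(want))
  }
})

test_that("signal rule applies all three conditions", {
  expect_true(evaluate_signal(2.0, 1.2, 50))
  expect_false(evaluate_signal(24.5, 4.0, 2))   # below the 3-case minimum
  expect_false(evaluate_signal(1.5, 0.9, 100))  # CI crosses 1
  expect_false(evaluate_signal(0.8, 0.5, 100))
})

test_that("screen applies the display rule and conserves counts", {
  sim <- simulate_reports(sim_config(n_cases = 4000, duplicate_fraction = 0,
                                     psychotropic_rate = 0, seed = 41))
  cl <- classify_exposure(sim$reports)
  sig <- screen_signals(cl, default_dictionary(), levels = c("PT", "SOC"))
  expect_true(all(sig$a >= 3))
  expect_true(all(sig$n_cases == sig$a))
  # a + b + c + d is the total case count on every row
  expect_true(all(sig$a + sig$b + sig$c + sig$d == n_cases(cl)))
  # rows are sorted by level then descending ROR
  for (lev in unique(sig$level)) {
    expect_false(is.unsorted(rev(sig$ror[sig$level == lev])))
  }

  # count conservation: a summed over mutually exclusive categories plus the
  # background stratum's events equals the total event-case count per term
  full <- screen_signals(cl, default_dictionary(), levels = "SOC",
                         exposures = setdiff(unique(cl$cases$exposure_category),
                                             "non_fq"),
                         min_cases = 0, include_all_fq = FALSE)
  ev <- cl$reactions %>%
    dplyr::distinct(case_id, pt) %>%
    dplyr::inner_join(tibble::as_tibble(default_dictionary()), by = "pt") %>%
    dplyr::distinct(case_id, soc)
  for (term in unique(full$term)) {
    total_event_cases <- sum(ev$soc == term)
    rows <- full[full$term == term, ]
    # every row's a + c is the dataset-wide event-case count for the term
    expect_true(all(rows$a + rows$c == total_event_cases))
    # categories partition the exposed side, so the background event count
    # (total minus all category a's) is non-negative
    expect_gte(total_event_cases - sum(rows$a), 0)
  }
})

test_that("a strongly planted pair is flagged and the screen recovers psi", {
  sim <- simulate_reports(recovery_config(50000, seed = 43, psi = 8))
  pp <- preprocess(sim$reports)
  sig <- screen_signals(pp$reports, small_dictionary(), levels = "PT",
                        include_all_fq = FALSE)
  row <- sig[sig$term == "anxiety" & sig$exposure == "ciprofloxacin", ]
  expect_true(row$is_signal)
  expect_gt(row$ror, 6)
  expect_lt(row$ror, 10)
})

test_that("tidy and glance summarise a screen", {
  sim <- simulate_reports(sim_config(n_cases = 2000, seed = 47))
  pp <- preprocess(sim$reports)
  sig <- screen_signals(pp$reports)
  td <- tidy(sig)
  expect_false(inherits(td, "pv_signals"))
  g <- glance(sig)
  expect_identical(g$n_pairs, nrow(sig))
  expect_identical(g$n_signals, sum(sig$is_signal))
  p <- autoplot(sig, level = "SOC")
  expect_s3_class(p, "ggplot")
})
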