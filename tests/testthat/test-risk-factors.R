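test_that("kNN imputation aggregates unanimous neighbourhoods and is a no-op
           on complete data", {
  specs <- lapply(1:5, function(i) {
    list(id = sprintf("D%d", i), sex = "male", age = 40, country = "france")
  })
  specs[[6]] <- list(id = "R1", sex = "male", country = "france")
  rs <- mk_report_set(specs)
  rs$cases$age_years[rs$cases$case_id == "R1"] <- NA
  out <- knn_impute(rs, k = 5)
  expect_identical(
    out$reports$cases$age_years[out$reports$cases$case_id == "R1"], 40)
  expect_identical(out$imputed$case_id, "R1")
  expect_identical(out$imputed$field, "age_years")

  # complete data: identical output, empty report
  complete <- mk_report_set(specs[1:5])
  out2 <- knn_impute(complete, k = 3)
  expect_identical(out2$reports$cases, complete$cases)
  expect_identical(nrow(out2$imputed), 0L)

  # k larger than the donor pool is a configuration error
  expect_error(knn_impute(rs, k = 10), "fewer than k")
})

test_that("imputation is deterministic and never alters observed values", {
  sim <- simulate_reports(sim_config(n_cases = 1500, seed = 67))
  cl <- classify_exposure(sim$reports)
  o1 <- knn_impute(cl, k = 5)
  o2 <- knn_impute(cl, k = 5)
  expect_identical(o1$reports$cases, o2$reports$cases)
  obs <- !is.na(cl$cases$age_years)
  expect_identical(o1$reports$cases$age_years[obs], cl$cases$age_years[obs])
  obs_sex <- cl$cases$sex != "unspecified"
  expect_identical(o1$reports$cases$sex[obs_sex], cl$cases$sex[obs_sex])
  expect_true(all(o1$reports$cases$sex %in% c("male", "female")))
  expect_true(all(!is.na(o1$reports$cases$age_years)))
})

test_that("kNN imputation beats marginal-median imputation under MCAR", {
  sim <- simulate_reports(sim_config(
    n_cases = 5000, seed = 71, duplicate_fraction = 0,
    missing_rates = c(age = 0, sex = 0, start_date = 0.3, event_date = 0.3),
    demographic_marginals = list(
      age_group = c("0-17" = 0.1, "18-34" = 0.3, "35-64" = 0.4, "65+" = 0.2,
                    "unspecified" = 0),
      # pronounced age-by-exposure structure so the neighbourhood carries
      # real information about the missing ages
      age_group_by_exposure = list(
        ciprofloxacin = c("0-17" = 0.10, "18-34" = 0.80, "35-64" = 0.10,
                          "65+" = 0, "unspecified" = 0),
        levofloxacin = c("0-17" = 0, "18-34" = 0.10, "35-64" = 0.80,
                         "65+" = 0.10, "unspecified" = 0),
        moxifloxacin = c("0-17" = 0, "18-34" = 0, "35-64" = 0.20,
                         "65+" = 0.80, "unspecified" = 0),
        fq_plus_other_meds = c("0-17" = 0, "18-34" = 0.10, "35-64" = 0.80,
                               "65+" = 0.10, "unspecified" = 0),
        non_fq = c("0-17" = 0, "18-34" = 0.70, "35-64" = 0.30,
                   "65+" = 0, "unspecified" = 0)
      ),
      sex = c(male = 0.45, female = 0.55, unspecified = 0))
  ))
  cl <- classify_exposure(sim$reports)
  truth_age <- cl$cases$age_years
  knockout <- withr::with_seed(72, runif(n_cases(cl)) < 0.2)
  cl$cases$age_years[knockout] <- NA

  out <- knn_impute(cl, k = 5)
  mae_knn <- mean(abs(out$reports$cases$age_years[knockout] -
                        truth_age[knockout]))
  mae_median <- mean(abs(median(truth_age[!knockout]) - truth_age[knockout]))
  expect_lt(mae_knn, mae_median)
})

test_that("univariate logistic OR matches the 2x2 closed form and flags
           separation", {
  a <- 30; b <- 70; c <- 100; d <- 900
  df <- data.frame(
    exposed = rep(c("yes", "yes", "no", "no"), times = c(a, b, c, d)),
    event = rep(c(TRUE, FALSE, TRUE, FALSE), times = c(a, b, c, d))
  )
  res <- logistic_univariate(df, "exposed", "event", reference = "no")
  row <- res[res$level == "yes", ]
  expect_equal(row$or, ror_estimate(a, b, c, d)$ror, tolerance = 1e-6)
  expect_equal(row$p_value, 2 * pnorm(-abs(log(27 / 7) /
    sqrt(1 / a + 1 / b + 1 / c + 1 / d))), tolerance = 1e-6)
  ref <- res[res$level == "no", ]
  expect_identical(ref$or, 1)
  expect_true(is.na(ref$ci_low))

  # zero events in a level raises the separation flag
  df2 <- data.frame(
    g = rep(c("a", "b"), each = 50),
    event = c(rep(c(TRUE, FALSE), 25), rep(FALSE, 50))
  )
  res2 <- suppressWarnings(logistic_univariate(df2, "g", "event",
                                               reference = "a"))
  expect_match(res2$flag[res2$level == "b"], "separation")
})

test_that("null predictors yield nominal CI coverage of 1", {
  set.seed(73)
  covered <- logical(200)
  for (r in seq_len(200)) {
    df <- data.frame(g = sample(c("x", "y"), 2000, replace = TRUE),
                     event = runif(2000) < 0.1)
    res <- logistic_univariate(df, "g", "event", reference = "x")
    row <- res[res$level == "y", ]
    covered[r] <- row$ci_low <= 1 && 1 <= row$ci_high
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("the risk-factor screen uses fixed references and one BH family", {
  sim <- simulate_reports(sim_config(n_cases = 4000, seed = 79))
  pp <- preprocess(sim$reports)
  rk <- risk_factor_screen(pp$reports, default_dictionary(),
                           outcome_soc = "psychiatric disorders")
  refs <- rk[rk$level == rk$reference, ]
  expect_setequal(refs$level[refs$predictor == "exposure_category"],
                  "ciprofloxacin")
  expect_setequal(refs$level[refs$predictor == "sex"], "male")
  expect_setequal(refs$level[refs$predictor == "age_group"], "0-17")
  expect_setequal(refs$level[refs$predictor == "severity"], "non_serious")
  expect_setequal(refs$level[refs$predictor == "therapy"], "monotherapy")
  expect_true(all(refs$or == 1))
  expect_true(all(is.na(refs$p_adjusted)))

  nonref <- rk[rk$level != rk$reference, ]
  expect_equal(nonref$p_adjusted, bh_oracle(nonref$p_value), tolerance = 1e-12)
  expect_true(all(nonref$p_adjusted >= nonref$p_value, na.rm = TRUE))

  g <- glance(rk)
  expect_identical(g$n_levels, nrow(nonref))
  expect_s3_class(autoplot(rk), "ggplot")
})

test_that("a null screen controls the false discovery rate", {
  # no planted drug or demographic effects: few levels should pass BH 0.05
  n_sig <- 0L; n_lev <- 0L
  for (s in 1:30) {
    sim <- simulate_reports(null_config(3000, seed = 100 + s))
    pp <- preprocess(sim$reports)
    rk <- suppressWarnings(risk_factor_screen(
      pp$reports, default_dictionary(),
      outcome_soc = "psychiatric disorders", impute = FALSE,
      predictors = c("exposure_category", "sex", "age_group")
    ))
    nonref <- rk[rk$level != rk$reference & rk$flag == "", ]
    n_sig <- n_sig + sum(nonref$p_adjusted < 0.05, na.rm = TRUE)
    n_lev <- n_lev + nrow(nonref)
  }
  expect_lte(n_sig / n_lev, 0.10)
})
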