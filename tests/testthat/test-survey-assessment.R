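test_that("survey CSV reading validates schema and preserves missingness", {
  path <- write_survey_csv(tiny_survey_df())
  tbl <- read_survey(path, survey_id = "tiny")
  expect_s3_class(tbl, "survey_table")
  expect_equal(nrow(tbl), 3)
  expect_equal(survey_id(tbl), "tiny")

  # missing z-score retained as NA, row kept
  df <- tiny_survey_df()
  df$haz[2] <- NA
  tbl2 <- read_survey(write_survey_csv(df))
  expect_equal(nrow(tbl2), 3)
  expect_true(is.na(tbl2$haz[2]))

  # schema errors name the offender
  expect_error(read_survey(write_survey_csv(tiny_survey_df()[, -5])),
               "wt")
  bad <- tiny_survey_df()
  bad$whz <- c("0.1", "oops", "-1.4")
  expect_error(read_survey(write_survey_csv(bad)), "row 2")
  neg <- tiny_survey_df()
  neg$wt[1] <- -1
  expect_error(read_survey(write_survey_csv(neg)), "positive")
  expect_error(read_survey(tempfile()), "not found")
})

test_that("plausibility filter flags WHO-implausible z-scores when asked", {
  df <- tiny_survey_df()
  df$haz[1] <- 8      # outside [-6, 6]
  df$whz[3] <- -5.5   # outside [-5, 5]
  path <- write_survey_csv(df)
  raw <- read_survey(path)
  expect_equal(sum(is.na(raw$haz)), 0)   # off by default
  filtered <- suppressMessages(read_survey(path,
                                           plausibility_filter = TRUE))
  expect_true(is.na(filtered$haz[1]))
  expect_true(is.na(filtered$whz[3]))
  expect_equal(sum(attr(filtered, "n_flagged")), 2)
})

test_that("weighted moments reduce correctly and are scale invariant", {
  # two-point hand computation: mean (0*1 + 2*3)/4 = 1.5,
  # sd = sqrt((1*2.25 + 3*0.25)/4) = sqrt(0.75)
  tbl <- anthrobias:::new_survey_table(
    data.frame(age = c(20, 30), haz = c(0, 2), whz = c(0, 2),
               waz = c(0, 2), wt = c(1, 3)), "two")
  mom <- weighted_moments(tbl, "haz")
  expect_equal(mom$weighted_mean, 1.5)
  expect_equal(mom$weighted_sd, sqrt(0.75))
  expect_equal(mom$n_used, 2L)

  # uniform weights match unweighted mean / population SD
  z <- c(-2.1, -1.4, 0.3, -0.8, -3)
  tbl_u <- anthrobias:::new_survey_table(
    data.frame(age = 1:5, haz = z, whz = z, waz = z, wt = rep(2, 5)),
    "uniform")
  mom_u <- weighted_moments(tbl_u, "haz")
  expect_equal(mom_u$weighted_mean, mean(z))
  expect_equal(mom_u$weighted_sd, sqrt(mean((z - mean(z))^2)))

  # rescaling weights changes nothing
  tbl_s <- tbl
  tbl_s$wt <- tbl_s$wt * 17
  expect_equal(weighted_moments(tbl_s, "haz"), mom)

  # insufficient data is an explicit error
  tbl_na <- tbl
  tbl_na$haz <- NA_real_
  expect_error(weighted_moments(tbl_na, "haz"), "insufficient")
})

test_that("indicator assessment composes moments with the bias relationship", {
  spec <- synthetic_survey_spec(n_children = 4000, true_mean = -1.5,
                                noise_sd = 0, heaping_fraction = 0,
                                missing_rate = 0, seed = 61)
  tbl <- generate_survey(spec)
  s <- assess_indicator(tbl, "haz")
  # no noise: SD near the reference, bias near zero
  expect_equal(s$weighted_sd, 1, tolerance = 0.05)
  expect_lt(abs(s$bias_point), 0.02)
  # the reported bias is the closed form at the observed moments
  expect_equal(s$bias_point,
               estimate_bias(s$weighted_mean, s$weighted_sd))
  expect_equal(s$estimated_prevalence,
               pnorm((-2 - s$weighted_mean) / s$weighted_sd))
  # point bias always sits inside the likely interval for sd > 0.8
  expect_gte(s$bias_point, s$bias_interval[1] - 1e-12)
  expect_lte(s$bias_point, s$bias_interval[2] + 1e-12)

  noisy <- generate_survey(synthetic_survey_spec(
    n_children = 4000, true_mean = -1.5, noise_sd = 1,
    heaping_fraction = 0, missing_rate = 0, seed = 62))
  sn <- assess_indicator(noisy, "haz")
  expect_equal(sn$weighted_sd, sqrt(2), tolerance = 0.05)
  expect_gt(sn$bias_point, 0.05)
})

test_that("age heaping ratio counts inclusive windows on rounded months", {
  expect_equal(age_heaping_ratio(c(24, 25, 10, 40, 48))$ratio, 3 / 5)
  expect_equal(age_heaping_ratio(rep(24, 10))$ratio, 1)
  expect_equal(age_heaping_ratio(c(5, 10, 30, 55))$ratio, 0)
  # rounding: 23.4 -> 23 qualifies, 22.4 -> 22 does not
  expect_equal(age_heaping_ratio(c(23.4, 22.4))$qualifying_count, 1)
  # defaults exclude the 12-month cluster and expect 9/60 under uniform
  h <- age_heaping_ratio(c(12, 24))
  expect_equal(h$qualifying_count, 1)
  expect_equal(h$uniform_expectation, 9 / 60)
  # weights never enter: same ratio from the ages alone
  tbl <- anthrobias:::new_survey_table(
    data.frame(age = c(24, 10, 36), haz = 0, whz = 0, waz = 0,
               wt = c(100, 1, 0.01)), "w")
  expect_equal(age_heaping_ratio(tbl)$ratio,
               age_heaping_ratio(c(24, 10, 36))$ratio)
  expect_error(age_heaping_ratio(numeric(0)), "no age")
})

test_that("digit preference test flags degenerate rounding, passes clean data", {
  set.seed(41)  # local to this test's fixture construction
  clean <- round(runif(400, 65, 110), 1)
  res <- digit_preference_test(clean, "terminal_digit")
  expect_equal(sum(res$observed), 400)
  expect_length(res$observed, 10)
  expect_gt(res$p_value, 0.001)

  heaped <- round(runif(200, 65, 110))  # every value ends in .0
  res2 <- digit_preference_test(heaped, "terminal_digit")
  expect_lt(res2$p_value, 1e-10)

  ages <- c(rep(24, 50), sample(0:59, 100, replace = TRUE))
  res3 <- digit_preference_test(ages, "integer_month")
  expect_equal(sum(res3$observed), 150)
  expect_lt(res3$p_value, 0.01)

  expect_warning(digit_preference_test(clean[1:10], "terminal_digit"),
                 "unreliable")
  expect_error(digit_preference_test(numeric(0)), "no non-missing")
})

test_that("digit test is calibrated under the uniform null", {
  # under uniformly random decimals the test should almost never report
  # an extreme p-value
  set.seed(7)
  pvals <- replicate(100, {
    digit_preference_test(round(runif(300, 60, 120), 1),
                          "terminal_digit")$p_value
  })
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("heaping-SD correlation computes Pearson rho with guard rails", {
  # exact positive line
  expect_equal(heaping_sd_correlation(c(0.1, 0.2, 0.3),
                                      c(1.0, 1.2, 1.4))$rho, 1)
  # permutation invariance
  x <- c(0.12, 0.31, 0.22, 0.45)
  y <- c(1.05, 1.4, 1.2, 1.6)
  expect_equal(heaping_sd_correlation(x, y)$rho,
               heaping_sd_correlation(rev(x), rev(y))$rho)
  expect_equal(heaping_sd_correlation(x, y)$rho, cor(x, y))
  expect_error(heaping_sd_correlation(c(0.1, 0.2), c(1, 1.2)),
               "insufficient")
  expect_error(heaping_sd_correlation(c(0.2, 0.2, 0.2), c(1, 1.2, 1.4)),
               "zero variance")
})

test_that("whole-survey and collection assessment produce coherent reports", {
  tabs <- generate_survey_collection(k = 5, n_children = 600, seed = 77)
  coll <- assess_survey_collection(tabs)
  expect_equal(nrow(coll$summary), 5)
  expect_s3_class(coll$correlation, "correlation_result")
  expect_equal(coll$correlation$n_surveys, 5)
  # per-survey point bias inside its likely interval
  ok <- with(coll$summary,
             haz_bias_point >= haz_bias_low - 1e-12 &
               haz_bias_point <= haz_bias_high + 1e-12)
  expect_true(all(ok))

  # one sparse indicator degrades to NA rather than aborting
  sparse <- tabs[[1]]
  sparse$whz <- NA_real_
  coll2 <- assess_survey(sparse)
  expect_true(is.na(coll2$indicators$weighted_sd[
    coll2$indicators$indicator == "whz"]))
  expect_false(anyNA(coll2$indicators$weighted_sd[
    coll2$indicators$indicator != "whz"]))

  # JSON and CSV writers round-trip the summary table
  jpath <- tempfile(fileext = ".json")
  write_assessment(coll, jpath, "json")
  j <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(j$correlation$rho, coll$correlation$rho)
  cpath <- tempfile(fileext = ".csv")
  write_assessment(coll, cpath, "csv")
  expect_equal(read.csv(cpath)$heaping_ratio, coll$summary$heaping_ratio)
})
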