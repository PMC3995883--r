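test_that("the same seed reproduces the cohort byte-for-byte", {
  spec <- table1_spec(n_scale = 0.2)
  a <- generate_cohort(spec, seed = 42)
  b <- generate_cohort(spec, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, p1); write_cohort(b, p2)
  expect_identical(readLines(p1), readLines(p2))
  c_ <- generate_cohort(spec, seed = 43)
  expect_false(identical(as.data.frame(a), as.data.frame(c_)))
})

test_that("per-group child streams are independent of other groups", {
  g_nc <- group_spec("NC", 40, dsr_mean = 26.6, dsr_sd = 8.49)
  g_mci <- group_spec("MCI", 30, dsr_mean = 9.4, dsr_sd = 8.88)
  solo <- generate_cohort(cohort_spec(list(g_nc)), seed = 5)
  both <- generate_cohort(cohort_spec(list(g_nc, g_mci)), seed = 5)
  cols <- setdiff(names(solo), "id")  # ids are renumbered cohort-wide
  expect_identical(as.data.frame(solo)[cols],
                   as.data.frame(both)[both$group == "NC", cols])
})

test_that("generated scores are integers on their ranges", {
  co <- generate_cohort(table1_spec(n_scale = 0.5,
                                    include_dementia_mix = TRUE), seed = 3)
  for (col in c("isr", "dsr")) {
    expect_true(all(co[[col]] == round(co[[col]])))
    expect_true(all(co[[col]] >= 0 & co[[col]] <= 56))
  }
  expect_true(all(co$mmse == round(co$mmse) & co$mmse >= 0 & co$mmse <= 30))
  expect_true(all(co$age >= 50 & co$age <= 85))
  expect_true(all(co$education_years >= 0))
  retest <- co$dsr_retest[!is.na(co$dsr_retest)]
  expect_gt(length(retest), 0)
  expect_true(all(retest >= 0 & retest <= 56))
})

test_that("large simulated groups match their target moments", {
  spec <- table1_spec(n_scale = 10000 / 249)  # NC n = 10000
  co <- generate_cohort(spec, seed = 1)
  nc <- co[co$group == "NC", ]
  expect_lt(abs(mean(nc$dsr) - 26.60), 0.3)
  expect_lt(abs(sd(nc$dsr) - 8.49), 0.3)
  expect_lt(abs(mean(nc$age) - 66.94), 0.4)
  expect_lt(abs(mean(nc$education_years) - 12.89), 0.2)
  mci <- co[co$group == "MCI", ]
  expect_lt(abs(mean(mci$dsr) - 9.40), 3 * 8.88 / sqrt(nrow(mci)) + 0.05)
  ad <- co[co$group == "AD", ]
  expect_lt(abs(mean(ad$dsr) - 1.60), 3 * 4.58 / sqrt(nrow(ad)) + 0.05)
  expect_lt(abs(sd(ad$dsr) - 4.58), 0.35)
})

test_that("zero residual noise puts every normative score on the plane", {
  reg <- list(intercept = 31.535, beta_edu = 0.746, beta_age = -0.206,
              residual_sd = 0)
  g <- group_spec("NC", 25, age_mean = 65, age_sd = 0, edu_mean = 12,
                  edu_sd = 0)
  co <- generate_cohort(cohort_spec(list(g), nc_regression = reg), seed = 2)
  expect_true(all(co$age == 65 & co$education_years == 12))
  expect_true(all(co$dsr == round(31.535 + 0.746 * 12 - 0.206 * 65)))
})

test_that("fitting the norming regression recovers the generating model", {
  reg <- list(intercept = 31.535, beta_edu = 0.746, beta_age = -0.206,
              residual_sd = 7.9)
  g <- group_spec("NC", 6000, age_mean = 66.94, age_sd = 8.87,
                  edu_mean = 12.89, edu_sd = 3.30)
  co <- generate_cohort(cohort_spec(list(g), nc_regression = reg), seed = 8)
  fit <- fit_norm_regression(co)
  se <- sqrt(diag(vcov(fit$lm_fit)))
  expect_lt(abs(coef(fit)["beta_edu"] - 0.746), 3 * se["education_years"] + 0.01)
  expect_lt(abs(coef(fit)["beta_age"] + 0.206), 3 * se["age"] + 0.01)
  expect_lt(abs(fit$residual_sd - 7.9), 0.2)
})

test_that("the generator realises the configured MMSE-DSR dependence", {
  g <- group_spec("NC", 480, age_mean = 66.94, age_sd = 8.87,
                  edu_mean = 12.89, edu_sd = 3.30,
                  dsr_mean = 26.60, dsr_sd = 8.49,
                  mmse_mean = 28.41, mmse_sd = 1.50)
  co <- generate_cohort(cohort_spec(list(g), mmse_dsr_partial_r = 0.575),
                        seed = 4)
  res <- partial_corr(co$mmse, co$dsr,
                      data.frame(age = co$age,
                                 education_years = co$education_years))
  expect_lt(abs(res$r - 0.575), 3 * (1 - 0.575^2) / sqrt(480))
})

test_that("the retest subset has the configured size and high reliability", {
  co <- generate_cohort(table1_spec(), seed = 6)
  retested <- !is.na(co$dsr_retest)
  expect_equal(sum(retested), 56)
  expect_true(all(co$group[retested] == "MCI"))
  rel <- retest_reliability(co, group = "MCI")
  expect_equal(rel$n, 56)
  expect_gt(rel$r, 0.75)
})

test_that("infeasible group targets propagate a feasibility error", {
  g <- group_spec("MCI", 10, dsr_mean = 28, dsr_sd = 29)
  expect_error(cohort_spec(list(g)), NA)  # spec construction is fine
  expect_error(generate_cohort(cohort_spec(list(g)), seed = 1),
               "infeasible")
})
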