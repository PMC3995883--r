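test_that("coefficients solve the normal equations on a hand dataset", {
  df <- data.frame(age = c(60, 65, 70, 75, 80),
                   education_years = c(16, 12, 9, 6, 12),
                   dsr = c(33, 28, 21, 15, 24))
  fit <- fit_norm_regression(df)
  X <- cbind(1, df$education_years, df$age)
  beta <- solve(t(X) %*% X, t(X) %*% df$dsr)  # normal-equations oracle
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-10)
  res <- df$dsr - X %*% beta
  expect_equal(fit$residual_sd, sd(res), tolerance = 1e-10)
  expect_equal(fit$n_fit, 5)
})

test_that("expected scores follow the published norming formula", {
  norm <- norm_regression(31.535, 0.746, -0.206, residual_sd = 8.0)
  expect_equal(expected_score(norm, age = 65, education_years = 12), 27.097)
  expect_equal(expected_score(norm, 65, 13) - expected_score(norm, 65, 12),
               0.746)
  flat <- norm_regression(31.535, 0, 0, residual_sd = 8.0)
  expect_equal(expected_score(flat, c(50, 70, 85), c(0, 10, 20)),
               rep(31.535, 3))
})

test_that("T scores standardize the residual to mean 50, SD 10", {
  norm <- norm_regression(31.535, 0.746, -0.206, residual_sd = 8.0)
  e <- expected_score(norm, 70, 10)
  expect_equal(t_score(e, norm, 70, 10), 50)
  expect_equal(t_score(e + 8.0, norm, 70, 10), 60)
  expect_equal(t_score(e - 1.35 * 8.0, norm, 70, 10), 36.5)
  # strictly increasing in the raw score
  raws <- seq(0, 56, by = 4)
  expect_true(all(diff(t_score(raws, norm, 70, 10)) > 0))
})

test_that("the fitting sample has T mean exactly 50 and SD exactly 10", {
  set.seed(33)
  for (i in 1:5) {
    n <- sample(30:200, 1)
    df <- data.frame(age = round(runif(n, 50, 85)),
                     education_years = round(runif(n, 0, 20)))
    df$dsr <- pmin(pmax(round(30 + 0.7 * df$education_years -
                                0.2 * df$age + rnorm(n, 0, 8)), 0), 56)
    fit <- fit_norm_regression(df)
    t <- t_score(df$dsr, fit, df$age, df$education_years)
    expect_equal(mean(t), 50, tolerance = 1e-10)
    expect_equal(sd(t), 10, tolerance = 1e-10)
  }
})

test_that("norming matches a brute-force per-record loop", {
  co <- generate_cohort(table1_spec(n_scale = 0.3), seed = 14)
  nc <- as.data.frame(co)[co$group == "NC", ]
  fit <- fit_norm_regression(nc)
  scored <- apply_norm(co, fit)
  for (i in sample(nrow(scored), 25)) {
    exp_i <- fit$intercept + fit$beta_edu * scored$education_years[i] +
      fit$beta_age * scored$age[i]
    expect_equal(scored$expected[i], exp_i)
    expect_equal(scored$z[i], (scored$dsr[i] - exp_i) / fit$residual_sd)
    expect_equal(scored$t[i], 10 * scored$z[i] + 50)
  }
})

test_that("degenerate and singular fits are caught", {
  df <- data.frame(age = c(60, 65, 70, 75, 80),
                   education_years = c(16, 12, 9, 6, 12))
  df$dsr <- 31.5 + 0.75 * df$education_years - 0.2 * df$age  # exact plane
  w <- capture_warnings(fit <- fit_norm_regression(df))
  expect_match(w, "degenerate", all = FALSE)
  expect_equal(unname(coef(fit)), c(31.5, 0.75, -0.2), tolerance = 1e-8)
  expect_error(t_score(20, fit, 65, 12), "degenerate")

  df$education_years <- 12  # constant predictor
  df$dsr <- 30 - 0.2 * df$age + c(0.1, -0.2, 0.3, 0, -0.2)
  expect_error(fit_norm_regression(df), "vary")
  df2 <- data.frame(age = c(60, 65, 70, 75, 80))
  df2$education_years <- 90 - df2$age  # collinear
  df2$dsr <- 30 - 0.2 * df2$age + c(0.1, -0.2, 0.3, 0, -0.2)
  expect_error(fit_norm_regression(df2))

  expect_error(fit_norm_regression(data.frame(age = 1:3,
                                              education_years = c(2, 4, 8),
                                              dsr = c(1, 2, 3))), "at least 4")
  expect_error(norm_regression(31.5, 0.7, -0.2, residual_sd = 0), "> 0")
})

test_that("the rmse residual convention is selectable and larger", {
  set.seed(8)
  df <- data.frame(age = round(runif(60, 50, 85)),
                   education_years = round(runif(60, 0, 20)))
  df$dsr <- round(30 + 0.7 * df$education_years - 0.2 * df$age + rnorm(60, 0, 8))
  a <- fit_norm_regression(df, residual_sd_method = "sample")
  b <- fit_norm_regression(df, residual_sd_method = "rmse")
  expect_equal(a$residual_sd, sd(residuals(a)))
  expect_equal(b$residual_sd, summary(a$lm_fit)$sigma)
  expect_gt(b$residual_sd, a$residual_sd)  # n-p-1 vs n-1 denominator
})
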