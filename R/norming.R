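# Regression-based demographic norming of the delayed recall score.
# The procedure: (1) fit OLS of the score on education years and age in
# the normative (normal cognition) group; (2) compute each subject's
# expected score from the fitted coefficients; (3) residual = raw -
# expected; (4) Z = residual / residual SD; (5) T = 10 Z + 50, so the
# normative sample has T mean 50 and SD 10 by construction.

#' Fit the demographic norming regression
#'
#' Ordinary least squares of the delayed recall total on education years
#' and age, fitted on the normative group. The residual SD is the n-1
#' sample SD of the residuals by default (`residual_sd_method =
#' "sample"`); the root-mean-square error with the regression's
#' n-p-1 denominator is selectable.
#'
#' @param data data.frame with columns `dsr`, `education_years`, `age`
#'   (e.g. a cohort restricted to the normative group).
#' @param score name of the score column to norm (default `"dsr"`).
#' @param residual_sd_method `"sample"` (n-1) or `"rmse"` (n-p-1).
#' @return A `norm_regression` object: coefficients (`intercept`,
#'   `beta_edu`, `beta_age`), `residual_sd`, `n_fit`, `r_squared`, and
#'   the underlying `lm` fit.
#' @seealso [expected_score()], [t_score()]
#' @export
fit_norm_regression <- function(data, score = "dsr",
                                residual_sd_method = c("sample", "rmse")) {
  residual_sd_method <- match.arg(residual_sd_method)
  needed <- c(score, "education_years", "age")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("norming requires column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(y = data[[score]], education_years = data$education_years,
                   age = data$age)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 4) {
    stop("need at least 4 complete observations to fit the norm", call. = FALSE)
  }
  if (stats::var(df$education_years) == 0 || stats::var(df$age) == 0) {
    stop("education_years and age must both vary in the normative sample",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ education_years + age, data = df)
  if (anyNA(stats::coef(fit))) {
    stop("singular fit: education_years and age are collinear", call. = FALSE)
  }
  res <- stats::residuals(fit)
  residual_sd <- switch(residual_sd_method,
                        sample = stats::sd(res),
                        rmse = summary(fit)$sigma)
  degenerate <- residual_sd < sqrt(.Machine$double.eps)
  if (degenerate) {
    warning("degenerate norm: residuals are (near-)zero; T scores undefined",
            call. = FALSE)
  }
  cf <- stats::coef(fit)
  structure(list(intercept = unname(cf[1]),
                 beta_edu = unname(cf["education_years"]),
                 beta_age = unname(cf["age"]),
                 residual_sd = residual_sd,
                 residual_sd_method = residual_sd_method,
                 n_fit = nrow(df),
                 r_squared = summary(fit)$r.squared,
                 score = score,
                 degenerate = degenerate,
                 lm_fit = fit),
            class = "norm_regression")
}

#' Assemble a norming model from published coefficients
#'
#' Builds a `norm_regression` directly from printed coefficients (no
#' fitting), so published norms can be applied to new subjects.
#'
#' @param intercept,beta_edu,beta_age regression coefficients (score
#'   points; per education year; per year of age).
#' @param residual_sd residual SD in score points (`> 0`).
#' @param score normed score column name.
#' @return A `norm_regression`.
#' @export
norm_regression <- function(intercept, beta_edu, beta_age, residual_sd,
                            score = "dsr") {
  if (residual_sd <= 0) stop("residual_sd must be > 0", call. = FALSE)
  structure(list(intercept = intercept, beta_edu = beta_edu,
                 beta_age = beta_age, residual_sd = residual_sd,
                 residual_sd_method = "published", n_fit = NA_integer_,
                 r_squared = NA_real_, score = score, degenerate = FALSE,
                 lm_fit = NULL),
            class = "norm_regression")
}

#' Expected score for given demographics
#'
#' `intercept + beta_edu * education_years + beta_age * age`, the
#' demographically predicted score around which individual deviations
#' are judged. Vectorised.
#'
#' @param norm a `norm_regression`.
#' @param age age(s) in years.
#' @param education_years education in years.
#' @return Expected score(s).
#' @export
expected_score <- function(norm, age, education_years) {
  stopifnot(inherits(norm, "norm_regression"))
  norm$intercept + norm$beta_edu * education_years + norm$beta_age * age
}

#' Demographically adjusted T score
#'
#' Standardizes the deviation of a raw score from its demographic
#' expectation by the normative residual SD and rescales to the T metric:
#' `T = 10 * (raw - expected) / residual_sd + 50`. T scores are not
#' clipped; values outside 0--100 are legal. Vectorised.
#'
#' @param raw raw score(s).
#' @param norm a `norm_regression`.
#' @param age,education_years demographics matching `raw`.
#' @return T score(s): mean 50, SD 10 in the normative sample.
#' @export
t_score <- function(raw, norm, age, education_years) {
  stopifnot(inherits(norm, "norm_regression"))
  if (norm$degenerate || norm$residual_sd <= 0) {
    stop("degenerate norm (residual SD is zero): T scores undefined",
         call. = FALSE)
  }
  z <- (raw - expected_score(norm, age, education_years)) / norm$residual_sd
  10 * z + 50
}

#' Append expected / Z / T columns to a cohort
#'
#' @param cohort cohort data.frame with `age`, `education_years` and the
#'   normed score column.
#' @param norm a `norm_regression`.
#' @return The cohort with `expected`, `z` and `t` columns appended.
#' @export
apply_norm <- function(cohort, norm) {
  df <- as.data.frame(cohort)
  raw <- df[[norm$score]]
  df$expected <- expected_score(norm, df$age, df$education_years)
  df$z <- (raw - df$expected) / norm$residual_sd
  df$t <- 10 * df$z + 50
  df
}

#' @export
print.norm_regression <- function(x, digits = 4, ...) {
  cat("Demographic norming regression (", x$score, ")\n", sep = "")
  cat(sprintf("  expected = %.*g + %.*g * education_years + %.*g * age\n",
              digits, x$intercept, digits, x$beta_edu, digits, x$beta_age))
  cat(sprintf("  residual SD = %.*g (%s)", digits, x$residual_sd,
              x$residual_sd_method))
  if (!is.na(x$n_fit)) {
    cat(sprintf(", n = %d, R^2 = %.3f", x$n_fit, x$r_squared))
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.norm_regression <- function(object, ...) {
  c(intercept = object$intercept, beta_edu = object$beta_edu,
    beta_age = object$beta_age)
}

#' @export
predict.norm_regression <- function(object, newdata, ...) {
  expected_score(object, newdata$age, newdata$education_years)
}

#' @export
residuals.norm_regression <- function(object, ...) {
  if (is.null(object$lm_fit)) {
    stop("no fitting sample stored for a published norm", call. = FALSE)
  }
  stats::residuals(object$lm_fit)
}

#' @export
summary.norm_regression <- function(object, ...) {
  print(object)
  if (!is.null(object$lm_fit)) print(summary(object$lm_fit)$coefficients)
  invisible(object)
}
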