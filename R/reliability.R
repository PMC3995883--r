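# Reliability and association analyses: test-retest correlation on the
# re-assessed subset (complete-case) and partial correlation between two
# scores controlling for covariates by the residual method.

#' Pearson correlation with test
#'
#' @param x,y numeric vectors (pairs with any missing value are dropped).
#' @return A `correlation_result`: `r`, `n`, `p_value`, `controlled_for`
#'   (empty).
#' @export
pearson <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant variable", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = length(x),
                 p_value = ct$p.value, controlled_for = character(0)),
            class = "correlation_result")
}

#' Partial correlation by the residual method
#'
#' Correlates the residuals of `x` and `y` after least-squares
#' projection on the covariates (plus an intercept): the linear
#' association between the two scores that the covariates cannot
#' explain. With no covariates this reduces exactly to [pearson()].
#' The p-value uses the t transform with `n - 2 - k` degrees of freedom
#' (`k` covariates).
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame (or named list) of numeric covariates;
#'   may be empty.
#' @return A `correlation_result` with `controlled_for` naming the
#'   covariates.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || length(covariates) == 0) {
    return(pearson(x, y))
  }
  cov_df <- as.data.frame(covariates)
  keep <- stats::complete.cases(x, y, cov_df)
  x <- x[keep]; y <- y[keep]
  cov_df <- cov_df[keep, , drop = FALSE]
  k <- ncol(cov_df)
  n <- length(x)
  if (n <= k + 2) {
    stop("need more than ", k + 2, " complete observations for ", k,
         " covariate(s)", call. = FALSE)
  }
  mm <- cbind(1, as.matrix(cov_df))
  rx <- stats::lsfit(mm, x, intercept = FALSE)$residuals
  ry <- stats::lsfit(mm, y, intercept = FALSE)$residuals
  tol_x <- 1e-8 * (stats::sd(x) + .Machine$double.eps)
  tol_y <- 1e-8 * (stats::sd(y) + .Machine$double.eps)
  if (stats::sd(rx) <= tol_x || stats::sd(ry) <= tol_y) {
    stop("degenerate partial correlation: a variable is fully explained by the covariates",
         call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(r = r, n = n, p_value = p,
                 controlled_for = colnames(cov_df)),
            class = "correlation_result")
}

#' Test-retest reliability of the delayed recall score
#'
#' Complete-case Pearson correlation between baseline and retest
#' delayed-recall totals over the re-assessed subset.
#'
#' @param cohort cohort data.frame with `dsr` and `dsr_retest`.
#' @param group optional group label(s) to restrict to (e.g. `"MCI"`).
#' @return A `correlation_result`.
#' @export
retest_reliability <- function(cohort, group = NULL) {
  df <- as.data.frame(cohort)
  if (!is.null(group)) df <- df[df$group %in% group, , drop = FALSE]
  pearson(df$dsr, df$dsr_retest)
}

#' @export
print.correlation_result <- function(x, ...) {
  ctrl <- if (length(x$controlled_for) > 0) {
    sprintf(" | %s", paste(x$controlled_for, collapse = ", "))
  } else ""
  cat(sprintf("r = %.3f (n = %d%s), p = %.3g\n", x$r, x$n, ctrl, x$p_value))
  invisible(x)
}
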