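# Stratified normative tables: per (age band x education band) cell the
# sample mean, SD, 5th/10th percentiles and cohort retention of the
# immediate and delayed recall totals, plus Petersen-style cutoffs.

DEFAULT_AGE_BANDS <- list(c(50, 64), c(65, 74), c(75, 85))

#' Percentile by the weighted-average-at-(n+1)p convention
#'
#' The order-statistic interpolation used by SPSS EXAMINE (R's
#' `quantile` type 6), which yields fractional values such as 3.75 for
#' small strata; other estimators are selectable via `type`.
#'
#' @param x numeric sample.
#' @param p probability in (0, 1), vectorised.
#' @param type `stats::quantile` type (default 6).
#' @return Percentile estimate(s).
#' @export
norm_percentile <- function(x, p, type = 6) {
  unname(stats::quantile(x, probs = p, type = type, names = FALSE))
}

#' Build a stratified normative table
#'
#' Restricts the cohort to the reference group (normal cognition by
#' default) and, per age band crossed with education band (at-or-below /
#' above the split, plus the band total), tabulates n, mean, sample SD
#' (n-1 denominator), 5th and 10th percentiles, and the retention
#' percentage (mean of per-subject `100 * dsr / isr`) for both recall
#' phases. Cells with no subjects are emitted with `n = 0` and missing
#' statistics; single-subject cells carry a mean but no SD and are
#' flagged.
#'
#' @param cohort a `dsr_cohort` or data.frame with `age`,
#'   `education_years`, `isr`, `dsr` (and `group` unless `group = NULL`).
#' @param age_bands list of `c(lo, hi)` closed integer age intervals.
#' @param edu_split education split in years (cells: `<= split`,
#'   `> split`, and `all`).
#' @param group reference group label to restrict to, or `NULL` to use
#'   all rows.
#' @param percentile_type `stats::quantile` type (default 6, the
#'   weighted-average-at-(n+1)p convention).
#' @param retention_method aggregation for [cohort_retention()].
#' @return data.frame with one row per (band x education cell x measure).
#' @export
build_norm_table <- function(cohort, age_bands = DEFAULT_AGE_BANDS,
                             edu_split = 9, group = "NC",
                             percentile_type = 6,
                             retention_method = "mean_of_ratios") {
  df <- as.data.frame(cohort)
  if (!is.null(group)) df <- df[df$group %in% group, , drop = FALSE]
  rows <- list()
  edu_cells <- list(
    list(rule = sprintf("<=%g", edu_split),
         sel = function(e) e <= edu_split),
    list(rule = sprintf(">%g", edu_split),
         sel = function(e) e > edu_split),
    list(rule = "all", sel = function(e) rep(TRUE, length(e)))
  )
  for (band in age_bands) {
    in_band <- df$age >= band[1] & df$age <= band[2]
    for (cell in edu_cells) {
      sub <- df[in_band & cell$sel(df$education_years), , drop = FALSE]
      ret <- cohort_retention(sub$dsr, sub$isr, method = retention_method)
      for (measure in c("ISR", "DSR")) {
        x <- if (measure == "ISR") sub$isr else sub$dsr
        x <- x[!is.na(x)]
        n <- length(x)
        rows[[length(rows) + 1L]] <- data.frame(
          age_lo = band[1], age_hi = band[2], edu = cell$rule,
          measure = measure, n = n,
          mean = if (n >= 1) mean(x) else NA_real_,
          sd = if (n >= 2) stats::sd(x) else NA_real_,
          p5 = if (n >= 1) norm_percentile(x, 0.05, percentile_type) else NA_real_,
          p10 = if (n >= 1) norm_percentile(x, 0.10, percentile_type) else NA_real_,
          retention_pct = ret,
          flag = if (n == 0) "empty" else if (n == 1) "single_subject" else "",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Petersen-style impairment cutoff (norm minus 1.5 SD)
#'
#' The conventional threshold for a memory deficit relative to normative
#' data: `mean - 1.5 * sd`, reported at full precision and rounded to
#' one decimal. Vectorised.
#'
#' @param mean normative mean score(s).
#' @param sd normative SD(s), `>= 0`.
#' @return data.frame with columns `raw` and `rounded`.
#' @examples
#' petersen_cutoff(28.10, 8.54)  # raw 15.29, rounded 15.3
#' @export
petersen_cutoff <- function(mean, sd) {
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  raw <- mean - 1.5 * sd
  data.frame(raw = raw, rounded = round(raw, 1))
}
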