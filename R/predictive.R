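# Base-rate-adjusted predictive values. Sensitivity and specificity are
# properties of the test; the post-test probabilities depend on the
# population prevalence (base rate) through Bayes' rule, so screening
# tables recompute PPV/NPV across a range of plausible base rates.

#' Positive and negative predictive values at a base rate
#'
#' Bayes' rule for a dichotomous screen:
#' `PPV = sens * p / (sens * p + (1 - spec) * (1 - p))` and
#' `NPV = spec * (1 - p) / (spec * (1 - p) + (1 - sens) * p)` with
#' `p` the base rate. Vectorised over all three arguments. A zero
#' denominator (no positive or no negative results possible) yields
#' `NaN` with a warning rather than a fabricated value.
#'
#' @param sens,spec test sensitivity and specificity in `[0, 1]`.
#' @param base_rate assumed prevalence in `(0, 1)`.
#' @return data.frame with `sens`, `spec`, `base_rate`, `ppv`, `npv`
#'   (full precision) and `ppv_2dp`, `npv_2dp` rounded for reporting.
#' @examples
#' predictive(0.980, 0.938, 0.10)  # ppv 0.63, npv 1.00 at 2 dp
#' @export
predictive <- function(sens, spec, base_rate) {
  if (any(sens < 0 | sens > 1) || any(spec < 0 | spec > 1)) {
    stop("sens and spec must lie in [0, 1]", call. = FALSE)
  }
  if (any(base_rate <= 0 | base_rate >= 1)) {
    stop("base_rate must lie strictly inside (0, 1)", call. = FALSE)
  }
  p <- base_rate
  den_pos <- sens * p + (1 - spec) * (1 - p)
  den_neg <- spec * (1 - p) + (1 - sens) * p
  if (any(den_pos == 0) || any(den_neg == 0)) {
    warning("predictive value undefined: the test never returns that result",
            call. = FALSE)
  }
  ppv <- ifelse(den_pos == 0, NaN, sens * p / den_pos)
  npv <- ifelse(den_neg == 0, NaN, spec * (1 - p) / den_neg)
  data.frame(sens = sens, spec = spec, base_rate = p, ppv = ppv, npv = npv,
             ppv_2dp = round(ppv, 2), npv_2dp = round(npv, 2))
}

#' Predictive-value grid over cutoffs and base rates
#'
#' One row per cutoff (with its sensitivity/specificity) and one pair of
#' columns per base rate, formatted `"ppv/npv"` at two decimals — the
#' layout of published screening tables.
#'
#' @param rows data.frame with columns `cutoff`, `sens`, `spec`.
#' @param base_rates numeric vector of prevalences in `(0, 1)`.
#' @return list with `formatted` (character grid) and `values`
#'   (long-format data.frame with full-precision `ppv`/`npv`).
#' @export
pv_grid <- function(rows, base_rates = c(0.1, 0.2, 0.3, 0.4, 0.5)) {
  stopifnot(all(c("cutoff", "sens", "spec") %in% names(rows)))
  long <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    pv <- predictive(rows$sens[i], rows$spec[i], base_rates)
    cbind(cutoff = rows$cutoff[i], pv)
  }))
  fmt <- data.frame(cutoff = rows$cutoff, sens = rows$sens,
                    spec = rows$spec, stringsAsFactors = FALSE)
  for (p in base_rates) {
    cell <- long[long$base_rate == p, ]
    cell <- cell[match(rows$cutoff, cell$cutoff), ]
    fmt[[sprintf("%g%%", 100 * p)]] <-
      sprintf("%.2f/%.2f", cell$ppv, cell$npv)
  }
  list(formatted = fmt, values = long)
}

#' Sample prevalence from counts
#'
#' @param n_cases number of cases.
#' @param n_total number of subjects screened.
#' @param digits rounding for the percentage (default 1, as printed in
#'   prevalence reports).
#' @return list with `proportion` and `percent` (rounded).
#' @examples
#' prevalence(134, 631)$percent  # 21.2
#' @export
prevalence <- function(n_cases, n_total, digits = 1) {
  stopifnot(n_total > 0, n_cases >= 0, n_cases <= n_total)
  prop <- n_cases / n_total
  list(proportion = prop, percent = round(100 * prop, digits))
}
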