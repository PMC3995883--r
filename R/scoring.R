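# Story-recall scoring. The story is segmented into 28 idea units; each
# idea is credited 2 (accurate recall or paraphrase), 1 (vague/partial
# recall) or 0, so totals range 0-56 for both the immediate (ISR) and
# delayed (DSR) phase.

N_IDEAS <- 28L
MAX_SCORE <- 2L * N_IDEAS  # 56

#' Total story-recall score from per-idea credits
#'
#' @param credits integer vector of exactly 28 per-idea credits, each
#'   0, 1 or 2.
#' @return Integer total in 0--56.
#' @examples
#' total_score(rep(2, 28))  # ceiling: 56
#' @export
total_score <- function(credits) {
  if (length(credits) != N_IDEAS) {
    stop("credits must have exactly ", N_IDEAS, " elements (one per idea unit), got ",
         length(credits), call. = FALSE)
  }
  if (anyNA(credits) || !all(credits %in% 0:2)) {
    stop("each idea credit must be 0, 1 or 2", call. = FALSE)
  }
  as.integer(sum(credits))
}

#' Percentage of the story retained after the delay
#'
#' Retention is the delayed total as a percentage of the immediate total,
#' `100 * dsr / isr` — an index of forgetting over the 23--30 minute delay.
#' Vectorised over score pairs.
#'
#' @param dsr delayed recall total(s).
#' @param isr immediate recall total(s); must be positive (retention is
#'   undefined when nothing was registered at immediate recall).
#' @return Retention percentage(s).
#' @export
retention_pct <- function(dsr, isr) {
  if (any(!is.na(isr) & isr <= 0)) {
    stop("retention is undefined when isr <= 0", call. = FALSE)
  }
  100 * dsr / isr
}

#' Cohort-level retention percentage
#'
#' Aggregates subject-level retention over a cohort. The default,
#' `"mean_of_ratios"`, averages per-subject `100 * dsr / isr`;
#' `"ratio_of_means"` instead divides the cohort mean DSR by the cohort
#' mean ISR. The two differ whenever retention covaries with immediate
#' recall; the mean-of-ratios convention weights every subject equally.
#' Subjects with `isr <= 0` (retention undefined) are dropped.
#'
#' @param dsr,isr numeric vectors of delayed and immediate totals.
#' @param method aggregation convention.
#' @return A single retention percentage.
#' @export
cohort_retention <- function(dsr, isr,
                             method = c("mean_of_ratios", "ratio_of_means")) {
  method <- match.arg(method)
  keep <- !is.na(dsr) & !is.na(isr) & isr > 0
  if (!any(keep)) return(NA_real_)
  dsr <- dsr[keep]; isr <- isr[keep]
  switch(method,
         mean_of_ratios = mean(100 * dsr / isr),
         ratio_of_means = 100 * mean(dsr) / mean(isr))
}

#' Read item-level recall credits and total them
#'
#' Reads an optional item-level CSV with columns
#' `id, phase, idea_01 .. idea_28` (phase is `immediate` or `delayed`)
#' and returns one total per row.
#'
#' @param path CSV path.
#' @return data.frame with columns `id`, `phase`, `total`.
#' @export
score_item_file <- function(path) {
  raw <- utils::read.csv(path, fileEncoding = "UTF-8")
  idea_cols <- sprintf("idea_%02d", seq_len(N_IDEAS))
  missing_cols <- setdiff(c("id", "phase", idea_cols), names(raw))
  if (length(missing_cols) > 0L) {
    stop("item file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_phase <- !raw$phase %in% c("immediate", "delayed")
  if (any(bad_phase)) {
    stop("unknown phase at data row ", which(bad_phase)[1], call. = FALSE)
  }
  totals <- vapply(seq_len(nrow(raw)), function(i) {
    total_score(as.numeric(raw[i, idea_cols]))
  }, integer(1))
  data.frame(id = as.character(raw$id), phase = raw$phase, total = totals,
             stringsAsFactors = FALSE)
}
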