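# ROC analysis for an impairment score: lower scores indicate impairment,
# so a subject screens positive when the score falls strictly below the
# threshold. Candidate thresholds are midpoints between adjacent distinct
# observed scores (plus sentinels beyond the extremes), which on integer
# scores makes "<" versus "<=" immaterial and yields the conventional
# half-integer cutoffs.

#' Build a ROC curve
#'
#' Sweeps every midpoint threshold and computes sensitivity and
#' specificity; the AUC is computed by the Mann-Whitney identity
#' `P(case < control) + 0.5 * P(tie)` (midrank form, exact with ties),
#' with a 95 percent confidence interval from the Hanley-McNeil variance
#' formula.
#'
#' @param scores numeric score vector.
#' @param is_case logical vector, `TRUE` for cases (the impaired group).
#' @param orientation `"lower"` (default: low score = positive test) or
#'   `"higher"`.
#' @param conf_level confidence level for the AUC interval.
#' @return A `dsr_roc` object with `thresholds`, `sens`, `spec`, `auc`,
#'   `auc_se`, `auc_ci`, class counts and the orientation.
#' @export
build_roc <- function(scores, is_case, orientation = c("lower", "higher"),
                      conf_level = 0.95) {
  orientation <- match.arg(orientation)
  keep <- !is.na(scores) & !is.na(is_case)
  scores <- scores[keep]
  is_case <- as.logical(is_case[keep])
  n_case <- sum(is_case)
  n_ctrl <- sum(!is_case)
  if (n_case == 0 || n_ctrl == 0) {
    stop("ROC undefined: need at least one case and one control", call. = FALSE)
  }
  s <- if (orientation == "lower") scores else -scores

  # Mann-Whitney AUC via midranks: exact tie handling
  r <- rank(s)
  u <- sum(r[!is_case]) - n_ctrl * (n_ctrl + 1) / 2
  auc <- u / (n_case * n_ctrl)

  # Hanley-McNeil standard error
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_case - 1) * (q1 - auc^2) +
          (n_ctrl - 1) * (q2 - auc^2)) / (n_case * n_ctrl)
  se <- sqrt(max(v, 0))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))

  vals <- sort(unique(s))
  thresholds <- c(vals[1] - 0.5,
                  if (length(vals) > 1) (vals[-1] + vals[-length(vals)]) / 2,
                  vals[length(vals)] + 0.5)
  sens <- vapply(thresholds, function(th) mean(s[is_case] < th), numeric(1))
  spec <- vapply(thresholds, function(th) mean(s[!is_case] >= th), numeric(1))

  structure(list(thresholds = if (orientation == "lower") thresholds
                              else -rev(thresholds),
                 sens = if (orientation == "lower") sens else rev(sens),
                 spec = if (orientation == "lower") spec else rev(spec),
                 auc = auc, auc_se = se, auc_ci = ci,
                 conf_level = conf_level,
                 n_case = n_case, n_ctrl = n_ctrl,
                 orientation = orientation),
            class = "dsr_roc")
}

#' Youden-optimal cutoff from a ROC curve
#'
#' Selects the threshold maximizing the chosen criterion — Youden's
#' J = sensitivity + specificity - 1 by default, or minimum Euclidean
#' distance to the perfect-classification corner. Ties are broken toward
#' higher sensitivity (screening favours detection), then toward the
#' lower threshold.
#'
#' @param curve a `dsr_roc` from [build_roc()].
#' @param criterion `"youden"` or `"closest_topleft"`.
#' @return A list (`cutoff_result`) with `cutoff`, `sens`, `spec`,
#'   `youden_j`.
#' @export
optimal_cutoff <- function(curve, criterion = c("youden", "closest_topleft")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(curve, "dsr_roc"))
  score <- switch(criterion,
                  youden = curve$sens + curve$spec - 1,
                  closest_topleft = -sqrt((1 - curve$sens)^2 +
                                            (1 - curve$spec)^2))
  # round away float jitter in sens + spec so true ties reach the tie-breaks
  ord <- order(-round(score, 12), -curve$sens, curve$thresholds)
  i <- ord[1]
  structure(list(cutoff = curve$thresholds[i], sens = curve$sens[i],
                 spec = curve$spec[i],
                 youden_j = curve$sens[i] + curve$spec[i] - 1,
                 criterion = criterion),
            class = "cutoff_result")
}

#' Stratified cutoff table
#'
#' For each diagnostic contrast and each stratum (whole sample, then
#' each age band crossed with education: all, at-or-below and above the
#' split), builds the ROC and reports the optimal cutoff with its
#' sensitivity, specificity and AUC. Strata missing a class are emitted
#' with missing statistics and a flag rather than failing.
#'
#' @param cohort cohort data.frame with `age`, `education_years`,
#'   `group` and the score column.
#' @param contrasts named list of `c(case =, control =)` group pairs,
#'   e.g. `list(MCI = c(case = "MCI", control = "NC"))`.
#' @param age_bands list of `c(lo, hi)` age intervals.
#' @param edu_split education split in years.
#' @param score score column (default `"dsr"`).
#' @param criterion cutoff criterion, see [optimal_cutoff()].
#' @return data.frame, one row per (contrast x stratum).
#' @export
stratified_cutoffs <- function(cohort, contrasts,
                               age_bands = DEFAULT_AGE_BANDS,
                               edu_split = 9, score = "dsr",
                               criterion = "youden") {
  df <- as.data.frame(cohort)
  strata <- list(list(name = "mean", sel = rep(TRUE, nrow(df))))
  for (band in age_bands) {
    in_band <- df$age >= band[1] & df$age <= band[2]
    nm <- sprintf("%d-%d", band[1], band[2])
    strata <- c(strata, list(
      list(name = nm, sel = in_band),
      list(name = sprintf("%s/edu<=%g", nm, edu_split),
           sel = in_band & df$education_years <= edu_split),
      list(name = sprintf("%s/edu>%g", nm, edu_split),
           sel = in_band & df$education_years > edu_split)
    ))
  }
  rows <- list()
  for (cn in names(contrasts)) {
    pair <- contrasts[[cn]]
    for (st in strata) {
      sub <- df[st$sel & df$group %in% pair, , drop = FALSE]
      is_case <- sub$group == pair[["case"]]
      n_case <- sum(is_case)
      n_ctrl <- sum(!is_case)
      if (n_case == 0 || n_ctrl == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = cn, stratum = st$name, n_case = n_case,
          n_ctrl = n_ctrl, cutoff = NA_real_, sens = NA_real_,
          spec = NA_real_, youden_j = NA_real_, auc = NA_real_,
          flag = "missing_class", stringsAsFactors = FALSE)
        next
      }
      curve <- build_roc(sub[[score]], is_case)
      best <- optimal_cutoff(curve, criterion)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = cn, stratum = st$name, n_case = n_case,
        n_ctrl = n_ctrl, cutoff = best$cutoff, sens = best$sens,
        spec = best$spec, youden_j = best$youden_j, auc = curve$auc,
        flag = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.dsr_roc <- function(x, ...) {
  cat(sprintf("ROC: %d cases vs %d controls (%s score is positive)\n",
              x$n_case, x$n_ctrl,
              if (x$orientation == "lower") "lower" else "higher"))
  cat(sprintf("  AUC = %.3f (%.0f%% CI %.3f-%.3f, Hanley-McNeil)\n",
              x$auc, 100 * x$conf_level, x$auc_ci[1], x$auc_ci[2]))
  best <- optimal_cutoff(x)
  cat(sprintf("  Youden-optimal cutoff %.2f: sens %.3f, spec %.3f, J = %.3f\n",
              best$cutoff, best$sens, best$spec, best$youden_j))
  invisible(x)
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("cutoff %.2f (%s): sens %.3f, spec %.3f, J = %.3f\n",
              x$cutoff, x$criterion, x$sens, x$spec, x$youden_j))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x a `dsr_roc`.
#' @param mark_optimal mark the Youden-optimal point.
#' @param ... passed to `plot`.
#' @export
plot.dsr_roc <- function(x, mark_optimal = TRUE, ...) {
  ord <- order(1 - x$spec, x$sens)
  graphics::plot(c(0, (1 - x$spec)[ord], 1), c(0, x$sens[ord], 1),
                 type = "l", xlab = "1 - specificity",
                 ylab = "Sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  if (mark_optimal) {
    best <- optimal_cutoff(x)
    graphics::points(1 - best$spec, best$sens, pch = 19)
    graphics::text(1 - best$spec, best$sens,
                   sprintf(" %.1f", best$cutoff), adj = c(0, 1))
  }
  invisible(x)
}

#' @export
coef.dsr_roc <- function(object, ...) {
  c(auc = object$auc, ci_low = object$auc_ci[1], ci_high = object$auc_ci[2])
}
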