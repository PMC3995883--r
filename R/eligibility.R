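# Operational diagnostic classification from tabular scale scores alone.
# Imaging and clinician-judgment criteria cannot be operationalised from a
# score table, so the dementia arm is labelled "AD_candidate", not AD.

# Education-adjusted MMSE screening thresholds (exclusive lower bounds)
# for "normal-range" global cognition, as used in Chinese normative work.
MMSE_THRESHOLDS <- c(higher = 26, middle = 23, primary = 22, illiterate = 19)

#' Education-adjusted MMSE threshold
#'
#' Returns the exclusive lower bound on MMSE for normal-range global
#' cognition at a given education level: a subject screens normal when
#' `mmse > mmse_min(level)`.
#'
#' @param education_level one of `"illiterate"`, `"primary"`, `"middle"`,
#'   `"higher"` (vectorised).
#' @return Numeric threshold(s).
#' @examples
#' mmse_min("higher")      # 26
#' mmse_min("illiterate")  # 19
#' @export
mmse_min <- function(education_level) {
  bad <- !education_level %in% names(MMSE_THRESHOLDS)
  if (any(bad)) {
    stop("unknown education level: ",
         paste(unique(education_level[bad]), collapse = ", "), call. = FALSE)
  }
  unname(MMSE_THRESHOLDS[education_level])
}

#' Classify subjects by the operational screening rules
#'
#' Applies the scale-based diagnostic gates to each record and returns one
#' label per subject:
#'
#' * `NC`: CDR global 0, MMSE above the education-adjusted threshold,
#'   preserved daily living (ADL < 16).
#' * `MCI`: CDR global 0.5 with memory domain 0.5, normal-range MMSE,
#'   ADL < 16, no depression (HAMD-17 <= 12), no vascular features
#'   (HIS <= 4).
#' * `AD_candidate`: MMSE at or below the education-adjusted threshold,
#'   CDR global >= 0.5, impaired daily living (ADL >= 16), HIS <= 4,
#'   HAMD-17 <= 12. ("Candidate" because imaging and clinical-judgment
#'   criteria are outside the scope of tabular screening.)
#' * otherwise `excluded`, with a reason from the first failing gate in the
#'   fixed order: depression (HAMD-17 > 12), vascular (HIS > 4), then
#'   the residual cognitive/functional profile mismatch.
#'
#' Exactly one label is assigned per record (the three inclusion profiles
#' are mutually exclusive by construction: NC and MCI differ on CDR global;
#' AD requires ADL >= 16 while NC/MCI require ADL < 16).
#'
#' @param cohort a `dsr_cohort` or data.frame with columns
#'   `mmse`, `education_level`, `adl`, `cdr_global`, `cdr_memory`,
#'   `his`, `hamd17`.
#' @return data.frame with columns `id` (if present), `label`
#'   (`NC`, `MCI`, `AD_candidate`, `excluded`) and `reason`
#'   (`NA` unless excluded).
#' @export
classify_cohort <- function(cohort) {
  needed <- c("mmse", "education_level", "adl", "cdr_global", "cdr_memory",
              "his", "hamd17")
  for (col in needed) {
    if (!col %in% names(cohort)) {
      stop("classification requires column '", col, "'", call. = FALSE)
    }
    if (anyNA(cohort[[col]])) {
      stop("missing value in mandatory field '", col, "' at row ",
           which(is.na(cohort[[col]]))[1], call. = FALSE)
    }
  }
  thr <- mmse_min(cohort$education_level)
  mmse_ok <- cohort$mmse > thr
  adl_ok <- cohort$adl < 16
  no_depr <- cohort$hamd17 <= 12
  no_vasc <- cohort$his <= 4

  is_nc <- cohort$cdr_global == 0 & mmse_ok & adl_ok
  is_mci <- cohort$cdr_global == 0.5 & cohort$cdr_memory == 0.5 &
    mmse_ok & adl_ok & no_depr & no_vasc
  is_ad <- !mmse_ok & cohort$cdr_global >= 0.5 & cohort$adl >= 16 &
    no_vasc & no_depr

  label <- rep("excluded", nrow(cohort))
  label[is_nc] <- "NC"
  label[is_mci] <- "MCI"
  label[is_ad] <- "AD_candidate"

  reason <- rep(NA_character_, nrow(cohort))
  excl <- label == "excluded"
  reason[excl & !no_depr] <- "depression"
  reason[excl & no_depr & !no_vasc] <- "vascular"
  reason[excl & no_depr & no_vasc] <- "cognitive_functional_profile"

  out <- data.frame(label = label, reason = reason, stringsAsFactors = FALSE)
  if ("id" %in% names(cohort)) out <- cbind(id = as.character(cohort$id), out)
  out
}

#' @rdname classify_cohort
#' @param record a single subject as a named list or one-row data.frame.
#' @export
classify_subject <- function(record) {
  res <- classify_cohort(as.data.frame(record, stringsAsFactors = FALSE))
  list(label = res$label[1], reason = res$reason[1])
}
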