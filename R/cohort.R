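# Canonical column order for cohort CSV files. `dsr_retest` is optional in
# content (may be all-NA) but the column is always present.
COHORT_COLUMNS <- c(
  "id", "age", "education_years", "education_level", "sex", "group",
  "mmse", "adl", "cdr_global", "cdr_memory", "his", "hamd17",
  "isr", "dsr", "dsr_retest"
)

EDUCATION_LEVELS <- c("illiterate", "primary", "middle", "higher")
SEX_LEVELS <- c("male", "female")
GROUP_LEVELS <- c("NC", "MCI", "AD", "VaD", "other_dementia",
                  "depression", "VCI", "unclassified")
CDR_LEVELS <- c(0, 0.5, 1, 2, 3)

#' Construct a cohort table of subject records
#'
#' A cohort table is a `data.frame` with one row per subject and a fixed,
#' documented column set: demographics (`age`, `education_years`,
#' `education_level`, `sex`), the operational group label, clinical scale
#' scores (`mmse`, `adl`, `cdr_global`, `cdr_memory`, `his`, `hamd17`) and
#' story-recall totals (`isr`, `dsr`, optional `dsr_retest`).
#'
#' Structural problems (missing columns, unknown factor levels, duplicated
#' ids) are always errors.  Range violations of the subject-record
#' invariants (recall totals in 0--56, MMSE in 0--30, age in the 50--85
#' study window) are collected: with `strict = TRUE` any violation is an
#' error, otherwise the violations are kept as the `"flags"` attribute and
#' reported with a warning.
#'
#' @param records data.frame containing at least the canonical columns.
#' @param provenance character tag, e.g. `"read_from_file"` or
#'   `"simulated(seed=42)"`.
#' @param strict logical; fail on invariant violations instead of flagging.
#' @return A `dsr_cohort` object (a data.frame).
#' @export
cohort_table <- function(records, provenance = "constructed", strict = FALSE) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(setdiff(COHORT_COLUMNS, "dsr_retest"),
                          names(records))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"dsr_retest" %in% names(records)) records$dsr_retest <- NA_real_
  records <- records[COHORT_COLUMNS]

  records$id <- as.character(records$id)
  for (col in c("age", "education_years", "mmse", "adl", "cdr_global",
                "cdr_memory", "his", "hamd17", "isr", "dsr", "dsr_retest")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  check_levels <- function(col, levels) {
    bad <- !is.na(records[[col]]) & !(records[[col]] %in% levels)
    if (any(bad)) {
      stop(sprintf("column '%s' has unknown value(s): %s (row %s)", col,
                   paste(unique(records[[col]][bad]), collapse = ", "),
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
  }
  check_levels("education_level", EDUCATION_LEVELS)
  check_levels("sex", SEX_LEVELS)
  check_levels("group", GROUP_LEVELS)
  check_levels("cdr_global", CDR_LEVELS)
  check_levels("cdr_memory", CDR_LEVELS)

  if (anyDuplicated(records$id)) {
    stop("subject ids are not unique: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "),
         call. = FALSE)
  }

  flags <- validate_records(records)
  if (strict && length(flags) > 0L) {
    stop("cohort invariant violation(s):\n  ",
         paste(flags, collapse = "\n  "), call. = FALSE)
  }
  if (length(flags) > 0L) {
    warning(length(flags), " record(s) violate cohort invariants; kept and flagged",
            call. = FALSE)
  }

  structure(records,
            class = c("dsr_cohort", "data.frame"),
            provenance = provenance,
            flags = flags)
}

# Range invariants on subject records. Returns a character vector of
# human-readable violations, one per (row, rule), each naming the row.
validate_records <- function(records) {
  flags <- character(0)
  add <- function(bad, fmt) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      flags <<- c(flags, sprintf(fmt, rows, records$id[rows]))
    }
    invisible(NULL)
  }
  out_of <- function(x, lo, hi) !is.na(x) & (x < lo | x > hi)
  add(out_of(records$isr, 0, 56),
      "row %d (id %s): isr outside 0-56 (scoring scheme maximum)")
  add(out_of(records$dsr, 0, 56),
      "row %d (id %s): dsr outside 0-56 (scoring scheme maximum)")
  add(out_of(records$dsr_retest, 0, 56),
      "row %d (id %s): dsr_retest outside 0-56 (scoring scheme maximum)")
  add(out_of(records$mmse, 0, 30),
      "row %d (id %s): mmse outside 0-30")
  add(out_of(records$age, 50, 85),
      "row %d (id %s): age outside the 50-85 study window")
  add(!is.na(records$his) & records$his < 0,
      "row %d (id %s): his negative")
  add(!is.na(records$hamd17) & records$hamd17 < 0,
      "row %d (id %s): hamd17 negative")
  add(!is.na(records$education_years) & records$education_years < 0,
      "row %d (id %s): education_years negative")
  flags
}

#' Read a cohort CSV
#'
#' Reads a comma-separated, UTF-8, headered file into a [cohort_table()].
#' Missing optional values are empty strings in the file and `NA` in R.
#'
#' @param path path to a CSV file with the canonical cohort columns.
#' @param strict logical; fail on any subject-record invariant violation.
#' @return A `dsr_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8", check.names = FALSE)
  missing_cols <- setdiff(setdiff(COHORT_COLUMNS, "dsr_retest"), names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"dsr_retest" %in% names(raw)) raw$dsr_retest <- ""
  numeric_cols <- setdiff(COHORT_COLUMNS,
                          c("id", "education_level", "sex", "group"))
  for (col in numeric_cols) {
    txt <- trimws(raw[[col]])
    val <- suppressWarnings(as.numeric(txt))
    bad <- nzchar(txt) & is.na(val)
    if (any(bad)) {
      stop(sprintf("unparseable value '%s' in column '%s' at data row %d",
                   txt[which(bad)[1]], col, which(bad)[1]), call. = FALSE)
    }
    raw[[col]] <- val
  }
  for (col in c("id", "education_level", "sex", "group")) {
    raw[[col]] <- ifelse(nzchar(trimws(raw[[col]])), trimws(raw[[col]]),
                         NA_character_)
  }
  cohort_table(raw, provenance = "read_from_file", strict = strict)
}

#' Write a cohort table to CSV
#'
#' Emits the canonical header even for an empty table; `NA` values
#' (e.g. an absent `dsr_retest`) become empty fields, so
#' `read_cohort(write_cohort(x))` is the identity.
#'
#' @param cohort a `dsr_cohort` (or compatible data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!is.data.frame(cohort)) stop("cohort must be a data.frame", call. = FALSE)
  if (!"dsr_retest" %in% names(cohort)) cohort$dsr_retest <- NA_real_
  out <- as.data.frame(cohort)[COHORT_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @export
print.dsr_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d subject(s) [%s]\n", nrow(x),
              attr(x, "provenance") %||% "unknown"))
  tab <- table(factor(x$group, levels = GROUP_LEVELS))
  tab <- tab[tab > 0]
  if (length(tab) > 0) {
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  flags <- attr(x, "flags")
  if (length(flags) > 0) cat("  flagged records:", length(flags), "\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more row(s)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
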