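# End-to-end pipeline: obtain a cohort (file or simulation), classify,
# build norms, fit the norming regression and T scores, run ROC contrasts,
# recompute predictive values over base rates, and summarise reliability
# -- writing a deterministic, manifest-stamped report bundle.

#' Pipeline configuration
#'
#' @param input either a file path to a cohort CSV, or a
#'   [cohort_spec()] to simulate from.
#' @param contrasts named list of `c(case =, control =)` group pairs.
#' @param age_bands list of `c(lo, hi)` age intervals.
#' @param edu_split education split in years.
#' @param base_rates prevalences for the predictive-value grid.
#' @param norm_group reference group for norms and the norming
#'   regression.
#' @param seed root seed (used only when simulating).
#' @param out_dir output directory for [run_pipeline()].
#' @return A `pipeline_config` list (validated).
#' @export
pipeline_config <- function(input = table1_spec(),
                            contrasts = list(
                              MCI = c(case = "MCI", control = "NC"),
                              AD = c(case = "AD", control = "NC")),
                            age_bands = DEFAULT_AGE_BANDS,
                            edu_split = 9,
                            base_rates = c(0.1, 0.2, 0.3, 0.4, 0.5),
                            norm_group = "NC",
                            seed = 1L,
                            out_dir = tempfile("dsr_report_")) {
  if (!(is.character(input) || inherits(input, "cohort_spec"))) {
    stop("input must be a CSV path or a cohort_spec", call. = FALSE)
  }
  if (length(contrasts) == 0 || is.null(names(contrasts))) {
    stop("contrasts must be a named list", call. = FALSE)
  }
  known <- if (inherits(input, "cohort_spec")) {
    vapply(input$groups, function(g) g$label, character(1))
  } else NULL
  for (cn in names(contrasts)) {
    pair <- contrasts[[cn]]
    if (!all(c("case", "control") %in% names(pair))) {
      stop("contrast '", cn, "' needs named case and control groups",
           call. = FALSE)
    }
    if (!all(pair %in% GROUP_LEVELS)) {
      stop("contrast '", cn, "' references unknown group label(s): ",
           paste(setdiff(pair, GROUP_LEVELS), collapse = ", "), call. = FALSE)
    }
    if (!is.null(known) && !all(pair %in% known)) {
      stop("contrast '", cn, "' references group(s) absent from the simulation spec: ",
           paste(setdiff(pair, known), collapse = ", "), call. = FALSE)
    }
  }
  bad_band <- vapply(age_bands,
                     function(b) length(b) != 2 || b[1] > b[2], logical(1))
  if (any(bad_band)) stop("invalid age band(s)", call. = FALSE)
  if (any(base_rates <= 0 | base_rates >= 1)) {
    stop("base rates must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(list(input = input, contrasts = contrasts,
                 age_bands = age_bands, edu_split = edu_split,
                 base_rates = base_rates, norm_group = norm_group,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full validation pipeline
#'
#' Executes every stage in order — cohort acquisition, operational
#' classification, stratified norms with Petersen cutoffs, the norming
#' regression with T scores, per-contrast ROC curves with Youden
#' cutoffs, the predictive-value grid at the configured base rates, and
#' reliability summaries — and writes a report bundle (CSV tables, a
#' JSON ROC summary, a markdown report and a manifest with the seed and
#' package version) to `config$out_dir`. The bundle is deterministic
#' given the seed. Any stage failure removes partial outputs and
#' re-raises the error tagged with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with every stage's in-memory result and the
#'   written file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  res <- tryCatch({
    stage <- "cohort"
    cohort <- if (inherits(config$input, "cohort_spec")) {
      generate_cohort(config$input, seed = config$seed)
    } else {
      read_cohort(config$input)
    }

    stage <- "classify"
    labels <- classify_cohort(cohort)

    stage <- "norms"
    norms <- build_norm_table(cohort, age_bands = config$age_bands,
                              edu_split = config$edu_split,
                              group = config$norm_group)
    dsr_cells <- norms[norms$measure == "DSR" & norms$n >= 2, ]
    petersen <- cbind(dsr_cells[c("age_lo", "age_hi", "edu", "n")],
                      petersen_cutoff(dsr_cells$mean, dsr_cells$sd))

    stage <- "norming_regression"
    nc <- as.data.frame(cohort)
    nc <- nc[nc$group %in% config$norm_group, , drop = FALSE]
    norm_fit <- fit_norm_regression(nc)
    scored <- apply_norm(cohort, norm_fit)

    stage <- "roc"
    roc_list <- list()
    cutoff_rows <- list()
    df <- as.data.frame(cohort)
    for (cn in names(config$contrasts)) {
      pair <- config$contrasts[[cn]]
      sub <- df[df$group %in% pair, , drop = FALSE]
      curve <- build_roc(sub$dsr, sub$group == pair[["case"]])
      best <- optimal_cutoff(curve)
      roc_list[[cn]] <- curve
      cutoff_rows[[cn]] <- data.frame(contrast = cn, cutoff = best$cutoff,
                                      sens = best$sens, spec = best$spec,
                                      stringsAsFactors = FALSE)
    }
    strat <- stratified_cutoffs(df, config$contrasts,
                                age_bands = config$age_bands,
                                edu_split = config$edu_split)

    stage <- "predictive_values"
    pv_rows <- do.call(rbind, cutoff_rows)
    grids <- lapply(seq_len(nrow(pv_rows)), function(i) {
      pv_grid(pv_rows[i, ], config$base_rates)
    })
    names(grids) <- pv_rows$contrast

    stage <- "reliability"
    rel <- list()
    if (any(!is.na(df$dsr_retest))) {
      rel$retest <- retest_reliability(df)
    }
    rel$mmse_partial <- partial_corr(
      df$mmse, df$dsr,
      df[c("age", "education_years")])

    stage <- "write"
    paths <- write_report_bundle(out_dir, config, cohort, labels, norms,
                                 petersen, norm_fit, scored, roc_list,
                                 strat, grids, rel)

    list(cohort = cohort, labels = labels, norms = norms,
         petersen = petersen, norm_fit = norm_fit, scored = scored,
         roc = roc_list, stratified_cutoffs = strat, pv_grids = grids,
         reliability = rel, paths = paths)
  }, error = function(e) {
    if (created) unlink(out_dir, recursive = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

write_report_bundle <- function(out_dir, config, cohort, labels, norms,
                                petersen, norm_fit, scored, roc_list,
                                strat, grids, rel) {
  p <- function(f) file.path(out_dir, f)
  write_cohort(cohort, p("cohort.csv"))
  utils::write.csv(labels, p("classification.csv"), row.names = FALSE)
  utils::write.csv(norms, p("norms.csv"), row.names = FALSE)
  utils::write.csv(petersen, p("petersen_cutoffs.csv"), row.names = FALSE)
  utils::write.csv(scored, p("tscores.csv"), row.names = FALSE)
  utils::write.csv(strat, p("stratified_cutoffs.csv"), row.names = FALSE)
  for (cn in names(grids)) {
    utils::write.csv(grids[[cn]]$formatted,
                     p(sprintf("pv_grid_%s.csv", cn)), row.names = FALSE)
  }
  roc_json <- lapply(roc_list, function(curve) {
    list(auc = curve$auc, auc_ci = curve$auc_ci,
         n_case = curve$n_case, n_ctrl = curve$n_ctrl,
         thresholds = curve$thresholds, sens = curve$sens,
         spec = curve$spec)
  })
  jsonlite::write_json(roc_json, p("roc.json"), auto_unbox = TRUE,
                       digits = NA)
  rel_json <- lapply(rel, function(r) {
    list(r = r$r, n = r$n, p_value = r$p_value,
         controlled_for = r$controlled_for)
  })
  jsonlite::write_json(rel_json, p("reliability.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package = "dsrscreen",
    version = as.character(utils::packageVersion("dsrscreen")),
    seed = config$seed,
    input = if (inherits(config$input, "cohort_spec")) "simulated"
            else config$input,
    n_subjects = nrow(cohort),
    age_bands = config$age_bands,
    edu_split = config$edu_split,
    base_rates = config$base_rates,
    contrasts = lapply(config$contrasts, as.list)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  write_markdown_report(p("report.md"), cohort, norms, petersen, norm_fit,
                        roc_list, strat, grids, rel)
  list.files(out_dir, full.names = TRUE)
}

write_markdown_report <- function(path, cohort, norms, petersen, norm_fit,
                                  roc_list, strat, grids, rel) {
  lines <- c("# Story recall screening validation report", "")
  tab <- table(as.data.frame(cohort)$group)
  lines <- c(lines, sprintf("Cohort: %d subjects (%s).", nrow(cohort),
                            paste(sprintf("%s %d", names(tab), tab),
                                  collapse = ", ")), "")
  lines <- c(lines, "## Norming regression", sprintf(
    "expected = %.3f + %.3f x education_years %+.3f x age (residual SD %.2f, n = %d, R^2 = %.3f)",
    norm_fit$intercept, norm_fit$beta_edu, norm_fit$beta_age,
    norm_fit$residual_sd, norm_fit$n_fit, norm_fit$r_squared), "")
  lines <- c(lines, "## ROC contrasts")
  for (cn in names(roc_list)) {
    curve <- roc_list[[cn]]
    best <- optimal_cutoff(curve)
    lines <- c(lines, sprintf(
      "- %s: AUC %.3f (95%% CI %.3f-%.3f); Youden cutoff %.1f, sens %.3f, spec %.3f",
      cn, curve$auc, curve$auc_ci[1], curve$auc_ci[2], best$cutoff,
      best$sens, best$spec))
  }
  lines <- c(lines, "", "## Petersen cutoffs (norm - 1.5 SD, DSR)")
  for (i in seq_len(nrow(petersen))) {
    lines <- c(lines, sprintf("- age %d-%d, education %s: %.1f",
                              petersen$age_lo[i], petersen$age_hi[i],
                              petersen$edu[i], petersen$rounded[i]))
  }
  lines <- c(lines, "", "## Reliability")
  if (!is.null(rel$retest)) {
    lines <- c(lines, sprintf("- test-retest r = %.3f (n = %d)",
                              rel$retest$r, rel$retest$n))
  }
  lines <- c(lines, sprintf(
    "- MMSE-DSR partial r (age, education controlled) = %.3f (n = %d)",
    rel$mmse_partial$r, rel$mmse_partial$n), "")
  writeLines(lines, path)
  invisible(path)
}
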