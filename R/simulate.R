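# Seeded synthetic-cohort generator. Emulates the group-conditional score
# structure of an elderly memory-clinic sample: bounded integer recall and
# MMSE scores with printed group means/SDs, an age+education regression
# structure in the normal-cognition group, a configurable MMSE-DSR
# residual correlation (Gaussian copula), and clinical gate scores
# consistent with each operational group label.

#' Specification of one diagnostic group
#'
#' Holds the target distribution of one group: sample size, demographic
#' normals, and bounded-score moments for the recall totals and MMSE.
#' Score distributions are realised as moment-matched truncated normals
#' on the score range, falling back to censored (clipped) normals when
#' the target moments imply a floor/ceiling mass no truncated normal can
#' carry (e.g. severely impaired groups with mean 1.6, SD 4.6 on 0--56).
#'
#' @param label group label (one of the cohort group levels).
#' @param n group size (>= 1).
#' @param age_mean,age_sd age distribution in years (clipped to 50--85,
#'   rounded to whole years).
#' @param edu_mean,edu_sd education distribution in years (clipped to
#'   0--22, rounded).
#' @param dsr_mean,dsr_sd,isr_mean,isr_sd target moments of the delayed
#'   and immediate recall totals on 0--56.
#' @param mmse_mean,mmse_sd target MMSE moments on 0--30.
#' @param hamd_mean,hamd_sd depression-scale moments (bounded consistent
#'   with the group's inclusion gate).
#' @param male_frac proportion of male subjects.
#' @param retest_frac proportion of the group re-tested (delayed recall
#'   only); `0` disables the retest column.
#' @param retest_r latent test-retest correlation for the re-tested
#'   subset.
#' @return A `group_spec` list.
#' @export
group_spec <- function(label, n,
                       age_mean = 67, age_sd = 9,
                       edu_mean = 12, edu_sd = 3.5,
                       dsr_mean = 20, dsr_sd = 9,
                       isr_mean = 22, isr_sd = 9,
                       mmse_mean = 27, mmse_sd = 2,
                       hamd_mean = 4, hamd_sd = 3,
                       male_frac = 0.5,
                       retest_frac = 0, retest_r = 0.9) {
  stopifnot(label %in% GROUP_LEVELS, n >= 1,
            age_sd >= 0, edu_sd >= 0, dsr_sd >= 0, isr_sd >= 0,
            mmse_sd >= 0, hamd_sd >= 0,
            dsr_mean >= 0, dsr_mean <= 56, isr_mean >= 0, isr_mean <= 56,
            male_frac >= 0, male_frac <= 1,
            retest_frac >= 0, retest_frac <= 1, abs(retest_r) <= 1)
  structure(list(label = label, n = as.integer(n),
                 age_mean = age_mean, age_sd = age_sd,
                 edu_mean = edu_mean, edu_sd = edu_sd,
                 dsr_mean = dsr_mean, dsr_sd = dsr_sd,
                 isr_mean = isr_mean, isr_sd = isr_sd,
                 mmse_mean = mmse_mean, mmse_sd = mmse_sd,
                 hamd_mean = hamd_mean, hamd_sd = hamd_sd,
                 male_frac = male_frac,
                 retest_frac = retest_frac, retest_r = retest_r),
            class = "group_spec")
}

#' Specification of a whole synthetic cohort
#'
#' @param groups list of [group_spec()] objects.
#' @param nc_regression `NULL`, or a list
#'   `list(intercept =, beta_edu =, beta_age =, residual_sd =)` giving the
#'   generating regression of delayed recall on education and age in the
#'   normal-cognition group. With `intercept = NULL` the intercept is
#'   derived so the group's marginal mean equals its `dsr_mean` target.
#' @param mmse_dsr_partial_r within-group latent correlation between the
#'   MMSE and delayed-recall score residuals (Gaussian copula).
#' @param seed default root seed used by [generate_cohort()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups, nc_regression = NULL,
                        mmse_dsr_partial_r = 0.575, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "group_spec")),
            abs(mmse_dsr_partial_r) <= 1)
  if (!is.null(nc_regression)) {
    needed <- c("beta_edu", "beta_age", "residual_sd")
    if (!all(needed %in% names(nc_regression))) {
      stop("nc_regression needs beta_edu, beta_age and residual_sd",
           call. = FALSE)
    }
    if (nc_regression$residual_sd < 0) {
      stop("nc_regression residual_sd must be >= 0", call. = FALSE)
    }
  }
  structure(list(groups = groups, nc_regression = nc_regression,
                 mmse_dsr_partial_r = mmse_dsr_partial_r,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' The default memory-clinic cohort specification
#'
#' Encodes the printed group-conditional distributions of a 631-subject
#' memory-clinic validation sample: normal cognition (n = 249, DSR
#' 26.60 +/- 8.49), MCI (n = 134, DSR 9.40 +/- 8.88) and Alzheimer-type
#' dementia (n = 97, DSR 1.60 +/- 4.58), with the corresponding
#' age/education/MMSE structure, a 56-subject MCI retest subset, and —
#' by default — the published norming-regression structure
#' (slopes +0.746 per education year, -0.206 per year of age) inside the
#' normal-cognition group, with the intercept anchored so the group keeps
#' its marginal mean.
#'
#' @param n_scale multiplies every group size (rounded, minimum 1) for
#'   larger or smaller simulations.
#' @param nc_regression logical; include the normal-cognition regression
#'   structure (otherwise that group is moment-matched like the others).
#' @param include_dementia_mix logical; add vascular and mixed dementia
#'   groups drawn from the pooled all-dementia distribution.
#' @param seed default root seed.
#' @return A [cohort_spec()].
#' @export
table1_spec <- function(n_scale = 1, nc_regression = TRUE,
                        include_dementia_mix = FALSE, seed = 1L) {
  sz <- function(n) max(1L, as.integer(round(n * n_scale)))
  groups <- list(
    group_spec("NC", sz(249), age_mean = 66.94, age_sd = 8.87,
               edu_mean = 12.89, edu_sd = 3.30,
               dsr_mean = 26.60, dsr_sd = 8.49,
               isr_mean = 30.03, isr_sd = 8.58,
               mmse_mean = 28.41, mmse_sd = 1.50,
               hamd_mean = 3.78, hamd_sd = 3.30,
               male_frac = 158 / 249),
    group_spec("MCI", sz(134), age_mean = 69.91, age_sd = 8.38,
               edu_mean = 11.32, edu_sd = 3.84,
               dsr_mean = 9.40, dsr_sd = 8.88,
               isr_mean = 13.91, isr_sd = 8.79,
               mmse_mean = 26.98, mmse_sd = 2.04,
               hamd_mean = 3.84, hamd_sd = 3.12,
               male_frac = 76 / 134,
               retest_frac = 56 / 134, retest_r = 0.887),
    group_spec("AD", sz(97), age_mean = 71.09, age_sd = 9.04,
               edu_mean = 10.63, edu_sd = 4.49,
               dsr_mean = 1.60, dsr_sd = 4.58,
               isr_mean = 4.02, isr_sd = 6.06,
               mmse_mean = 15.69, mmse_sd = 5.91,
               hamd_mean = 2.42, hamd_sd = 2.12,
               male_frac = 54 / 97)
  )
  if (include_dementia_mix) {
    mix <- function(label, n) {
      group_spec(label, sz(n), age_mean = 70.93, age_sd = 9.15,
                 edu_mean = 10.55, edu_sd = 4.39,
                 dsr_mean = 1.63, dsr_sd = 4.32,
                 isr_mean = 4.49, isr_sd = 5.96,
                 mmse_mean = 16.28, mmse_sd = 6.06,
                 hamd_mean = 2.78, hamd_sd = 2.47,
                 male_frac = 81 / 161)
    }
    groups <- c(groups, list(mix("VaD", 14), mix("other_dementia", 50)))
  }
  reg <- NULL
  if (nc_regression) {
    # residual SD chosen so the marginal DSR SD stays at the Table target:
    # var(DSR) = beta_edu^2 var(edu) + beta_age^2 var(age) + residual^2
    explained <- 0.746^2 * 3.30^2 + 0.206^2 * 8.87^2
    reg <- list(intercept = NULL, beta_edu = 0.746, beta_age = -0.206,
                residual_sd = sqrt(8.49^2 - explained))
  }
  cohort_spec(groups, nc_regression = reg, seed = seed)
}

# Deterministic per-group child seed from the root seed, so adding or
# reordering other groups does not perturb a group's stream.
child_seed <- function(root_seed, index) {
  as.integer((16807 * (as.numeric(root_seed) %% 2147483647) +
                104729 * index) %% 2147483647)
}

# Education level from completed years of schooling.
education_level_from_years <- function(years) {
  as.character(cut(years, breaks = c(-Inf, 0.5, 6.5, 9.5, Inf),
                   labels = c("illiterate", "primary", "middle", "higher"),
                   right = TRUE))
}

# Moment-match a score marginal on [lower, upper]: truncated normal when
# feasible, censored normal when the target moments demand boundary mass.
match_score_marginal <- function(mean, sd, lower, upper) {
  tryCatch(solve_bounded_normal(mean, sd, lower, upper, "truncated"),
           error = function(e) {
             solve_bounded_normal(mean, sd, lower, upper, "censored")
           })
}

# Generate one group's records. All randomness comes from the current RNG
# state; the draw order is fixed so the stream is reproducible.
generate_group <- function(gs, nc_regression, partial_r) {
  n <- gs$n
  age <- round(pmin(pmax(stats::rnorm(n, gs$age_mean, gs$age_sd), 50), 85))
  edu <- round(pmin(pmax(stats::rnorm(n, gs$edu_mean, gs$edu_sd), 0), 22))
  z1 <- stats::rnorm(n)        # latent driver of the delayed-recall score
  eps_mmse <- stats::rnorm(n)
  eps_retest <- stats::rnorm(n)
  u_sex <- stats::runif(n)

  use_regression <- identical(gs$label, "NC") && !is.null(nc_regression)
  if (use_regression) {
    b_e <- nc_regression$beta_edu
    b_a <- nc_regression$beta_age
    s_r <- nc_regression$residual_sd
    icpt <- nc_regression$intercept
    if (is.null(icpt)) {
      icpt <- gs$dsr_mean - b_e * gs$edu_mean - b_a * gs$age_mean
    }
    dsr_cont <- icpt + b_e * edu + b_a * age + s_r * z1
    dsr_q <- function(u, z) {           # conditional marginal for retest
      icpt + b_e * edu + b_a * age + s_r * z
    }
    dsr <- round(pmin(pmax(dsr_cont, 0), 56))
  } else {
    fit <- match_score_marginal(gs$dsr_mean, gs$dsr_sd, 0, 56)
    dsr_cont <- qbounded_normal(stats::pnorm(z1), fit$mu, fit$sigma,
                                0, 56, fit$type)
    dsr_q <- function(u, z) {
      qbounded_normal(u, fit$mu, fit$sigma, 0, 56, fit$type)
    }
    dsr <- round(dsr_cont)
  }

  isr_fit <- match_score_marginal(gs$isr_mean, gs$isr_sd, 0, 56)
  isr <- round(rbounded_normal(n, isr_fit$mu, isr_fit$sigma, 0, 56,
                               isr_fit$type))

  z2 <- partial_r * z1 + sqrt(1 - partial_r^2) * eps_mmse
  mmse_fit <- match_score_marginal(gs$mmse_mean, gs$mmse_sd, 0, 30)
  mmse <- round(qbounded_normal(stats::pnorm(z2), mmse_fit$mu,
                                mmse_fit$sigma, 0, 30, mmse_fit$type))

  dsr_retest <- rep(NA_real_, n)
  if (gs$retest_frac > 0) {
    k <- max(1L, as.integer(round(gs$retest_frac * n)))
    r <- gs$retest_r
    z3 <- r * z1 + sqrt(1 - r^2) * eps_retest
    retest_cont <- dsr_q(stats::pnorm(z3), z3)
    dsr_retest[seq_len(k)] <- round(pmin(pmax(retest_cont[seq_len(k)], 0), 56))
  }

  gates <- gate_scores(gs, n)
  data.frame(
    id = NA_character_,
    age = age, education_years = edu,
    education_level = education_level_from_years(edu),
    sex = ifelse(u_sex < gs$male_frac, "male", "female"),
    group = gs$label,
    mmse = mmse, adl = gates$adl, cdr_global = gates$cdr_global,
    cdr_memory = gates$cdr_memory, his = gates$his, hamd17 = gates$hamd17,
    isr = isr, dsr = dsr, dsr_retest = dsr_retest,
    stringsAsFactors = FALSE
  )
}

# Clinical gate scores consistent with the operational group label:
# CDR stage, daily-living impairment, ischemia and depression scales.
gate_scores <- function(gs, n) {
  hamd_bounded <- function(lo, hi) {
    m <- min(max(gs$hamd_mean, lo + 0.1), hi - 0.1)
    if (gs$hamd_sd <= 0) return(rep(round(m), n))
    fit <- match_score_marginal(m, min(gs$hamd_sd, (hi - lo) / 2 - 0.1),
                                lo, hi)
    round(rbounded_normal(n, fit$mu, fit$sigma, lo, hi, fit$type))
  }
  switch(gs$label,
    NC = list(cdr_global = rep(0, n), cdr_memory = rep(0, n),
              adl = sample(8:14, n, replace = TRUE),
              his = sample(0:2, n, replace = TRUE),
              hamd17 = hamd_bounded(0, 12)),
    MCI = list(cdr_global = rep(0.5, n), cdr_memory = rep(0.5, n),
               adl = sample(8:15, n, replace = TRUE),
               his = sample(0:4, n, replace = TRUE),
               hamd17 = hamd_bounded(0, 12)),
    AD = list(cdr_global = sample(c(1, 2), n, replace = TRUE,
                                  prob = c(0.7, 0.3)),
              cdr_memory = sample(c(1, 2), n, replace = TRUE,
                                  prob = c(0.6, 0.4)),
              adl = sample(16:34, n, replace = TRUE),
              his = sample(0:4, n, replace = TRUE),
              hamd17 = hamd_bounded(0, 12)),
    VaD = list(cdr_global = sample(c(1, 2), n, replace = TRUE),
               cdr_memory = sample(c(0.5, 1), n, replace = TRUE),
               adl = sample(16:34, n, replace = TRUE),
               his = sample(7:12, n, replace = TRUE),
               hamd17 = hamd_bounded(0, 12)),
    VCI = list(cdr_global = rep(0.5, n), cdr_memory = rep(0.5, n),
               adl = sample(8:15, n, replace = TRUE),
               his = sample(7:12, n, replace = TRUE),
               hamd17 = hamd_bounded(0, 12)),
    depression = list(cdr_global = sample(c(0, 0.5), n, replace = TRUE),
                      cdr_memory = sample(c(0, 0.5), n, replace = TRUE),
                      adl = sample(8:15, n, replace = TRUE),
                      his = sample(0:4, n, replace = TRUE),
                      hamd17 = sample(13:30, n, replace = TRUE)),
    other_dementia = list(cdr_global = sample(c(1, 2, 3), n, replace = TRUE,
                                              prob = c(0.5, 0.35, 0.15)),
                          cdr_memory = sample(c(1, 2), n, replace = TRUE),
                          adl = sample(16:40, n, replace = TRUE),
                          his = sample(0:6, n, replace = TRUE),
                          hamd17 = hamd_bounded(0, 12)),
    # unclassified / fallback: unconstrained plausible values
    list(cdr_global = sample(CDR_LEVELS, n, replace = TRUE),
         cdr_memory = sample(CDR_LEVELS, n, replace = TRUE),
         adl = sample(8:30, n, replace = TRUE),
         his = sample(0:8, n, replace = TRUE),
         hamd17 = sample(0:20, n, replace = TRUE))
  )
}

#' Generate a synthetic cohort
#'
#' Draws every group of a [cohort_spec()] with a fixed per-group child
#' stream derived from the root seed: the same seed yields an identical
#' table, and adding a group leaves existing groups' records unchanged.
#' Scores are integers on their ranges (recall 0--56, MMSE 0--30);
#' moment matching is performed on the continuous bounded normal before
#' integer rounding, which perturbs the sample moments by well under one
#' score point.
#'
#' @param spec a [cohort_spec()].
#' @param seed root seed; defaults to the seed stored in `spec`.
#' @return A `dsr_cohort` with provenance `"simulated(seed=...)"`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  parts <- vector("list", length(spec$groups))
  for (i in seq_along(spec$groups)) {
    gs <- spec$groups[[i]]
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(child_seed(seed, i))
    parts[[i]] <- generate_group(gs, spec$nc_regression,
                                 spec$mmse_dsr_partial_r)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  records <- do.call(rbind, parts)
  records$id <- sprintf("S%04d", seq_len(nrow(records)))
  cohort_table(records, provenance = sprintf("simulated(seed=%d)", seed))
}
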