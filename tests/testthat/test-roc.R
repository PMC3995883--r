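test_that("AUC handles separation, symmetry and ties correctly", {
  r1 <- build_roc(c(0, 1, 10, 11), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r1$auc, 1.0)
  expect_equal(r1$auc_ci, c(1, 1))  # Hanley-McNeil variance vanishes at 1
  r2 <- build_roc(c(3, 5, 9, 3, 5, 9), rep(c(TRUE, FALSE), each = 3))
  expect_equal(r2$auc, 0.5)
  r3 <- build_roc(c(5, 7, 5, 9), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r3$auc, 0.625)  # 4 pairs: 2 wins + 1 tie at half credit
  expect_error(build_roc(c(1, 2), c(TRUE, TRUE)), "control")
})

test_that("Mann-Whitney AUC equals pair counting and the trapezoid rule", {
  set.seed(101)
  for (i in 1:1000) {
    n1 <- sample(2:12, 1); n0 <- sample(2:12, 1)
    cases <- sample(0:20, n1, replace = TRUE)
    ctrls <- sample(0:20, n0, replace = TRUE)
    r <- build_roc(c(cases, ctrls), rep(c(TRUE, FALSE), c(n1, n0)))
    expect_equal(r$auc, brute_auc(cases, ctrls), tolerance = 1e-12)
    expect_equal(r$auc, trapezoid_auc(r$sens, r$spec), tolerance = 1e-12)
  }
})

test_that("the swept curve is monotone with (0,0) and (1,1) endpoints", {
  set.seed(7)
  scores <- c(rpois(40, 8), rpois(60, 15))
  is_case <- rep(c(TRUE, FALSE), c(40, 60))
  r <- build_roc(scores, is_case)
  ord <- order(r$thresholds, decreasing = TRUE)  # threshold decreasing
  expect_true(all(diff(r$sens[ord]) <= 0))
  expect_true(all(diff(r$spec[ord]) >= 0))
  pts <- cbind(r$sens, 1 - r$spec)
  expect_true(any(pts[, 1] == 0 & pts[, 2] == 0))
  expect_true(any(pts[, 1] == 1 & pts[, 2] == 1))
})

test_that("AUC is invariant under monotone transforms and flips with orientation", {
  set.seed(55)
  scores <- sample(0:56, 80, replace = TRUE)
  is_case <- runif(80) < 0.4
  ref <- build_roc(scores, is_case)$auc
  expect_equal(build_roc(scores^3, is_case)$auc, ref)
  expect_equal(build_roc(exp(scores / 10), is_case)$auc, ref)
  expect_equal(build_roc(scores, is_case, orientation = "higher")$auc,
               1 - ref)
})

test_that("the Youden cutoff matches exhaustive search with fixed tie-breaks", {
  toy <- build_roc(c(3, 6, 8, 7, 9, 12),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  best <- optimal_cutoff(toy)
  ora <- exhaustive_youden(c(3, 6, 8, 7, 9, 12),
                           c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(best$youden_j, ora$jmax)
  expect_true(best$cutoff %in% ora$best)

  set.seed(77)
  for (i in 1:200) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    scores <- sample(0:25, n1 + n0, replace = TRUE)
    is_case <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- build_roc(scores, is_case)
    b <- optimal_cutoff(r)
    o <- exhaustive_youden(scores, is_case)
    expect_equal(b$youden_j, o$jmax, tolerance = 1e-12)
    # tie-breaks: highest sensitivity, then the lower threshold
    at_max <- which(abs(r$sens + r$spec - 1 - o$jmax) < 1e-12)
    best_sens <- max(r$sens[at_max])
    expect_equal(b$sens, best_sens)
    expect_equal(b$cutoff,
                 min(r$thresholds[at_max][r$sens[at_max] == best_sens]))
  }
})

test_that("perfectly separating data yield J = 1 at an interclass cutoff", {
  r <- build_roc(c(2, 4, 9, 11), c(TRUE, TRUE, FALSE, FALSE))
  best <- optimal_cutoff(r)
  expect_equal(best$sens, 1)
  expect_equal(best$spec, 1)
  expect_equal(best$youden_j, 1)
  expect_gt(best$cutoff, 4)
  expect_lt(best$cutoff, 9)
})

test_that("AUC agrees with an established ROC implementation", {
  co <- generate_cohort(table1_spec(n_scale = 0.4), seed = 18)
  sub <- as.data.frame(co)[co$group %in% c("NC", "MCI"), ]
  ours <- build_roc(sub$dsr, sub$group == "MCI")
  ref <- pROC::roc(response = sub$group == "MCI", predictor = sub$dsr,
                   direction = ">", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("stratified tables have the published layout and conserve counts", {
  co <- generate_cohort(table1_spec(n_scale = 0.6), seed = 9)
  contrasts <- list(MCI = c(case = "MCI", control = "NC"),
                    AD = c(case = "AD", control = "NC"))
  tab <- stratified_cutoffs(co, contrasts)
  expect_equal(nrow(tab), 20)  # 2 contrasts x (mean + 3 bands x 3 edu cells)
  expect_equal(sum(tab$contrast == "MCI"), 10)
  # the three age bands partition the sample
  mci_bands <- tab[tab$contrast == "MCI" &
                     tab$stratum %in% c("50-64", "65-74", "75-85"), ]
  whole <- tab[tab$contrast == "MCI" & tab$stratum == "mean", ]
  expect_equal(sum(mci_bands$n_case), whole$n_case)
  expect_equal(sum(mci_bands$n_ctrl), whole$n_ctrl)
  expect_true(all(tab$youden_j >= -1 & tab$youden_j <= 1, na.rm = TRUE))
})

test_that("strata missing a class are flagged rather than fatal", {
  df <- data.frame(age = c(55, 56, 57, 70),
                   education_years = c(12, 12, 5, 12),
                   group = c("NC", "NC", "MCI", "MCI"),
                   dsr = c(30, 28, 7, 9), stringsAsFactors = FALSE)
  tab <- stratified_cutoffs(df, list(MCI = c(case = "MCI", control = "NC")))
  missing_row <- tab[tab$stratum == "65-74", ]
  expect_equal(missing_row$flag, "missing_class")
  expect_true(is.na(missing_row$cutoff))
  sep <- tab[tab$stratum == "50-64/edu<=9", ]  # 1 case, 0 controls
  expect_equal(sep$flag, "missing_class")
  whole <- tab[tab$stratum == "mean", ]
  expect_equal(whole$sens, 1)
  expect_equal(whole$spec, 1)
})
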