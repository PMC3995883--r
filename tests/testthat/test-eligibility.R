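base_record <- function(...) {
  rec <- list(mmse = 28, education_level = "higher", adl = 10,
              cdr_global = 0, cdr_memory = 0, his = 1, hamd17 = 3)
  mods <- list(...)
  rec[names(mods)] <- mods
  rec
}

test_that("education-adjusted MMSE thresholds match the screening convention", {
  expect_equal(mmse_min("higher"), 26)
  expect_equal(mmse_min("middle"), 23)
  expect_equal(mmse_min("primary"), 22)
  expect_equal(mmse_min("illiterate"), 19)
  expect_true(all(diff(mmse_min(c("higher", "middle", "primary",
                                  "illiterate"))) < 0))
  expect_error(mmse_min("postgraduate"), "unknown")
})

test_that("the operational profiles classify as NC, MCI and AD candidate", {
  expect_equal(classify_subject(base_record())$label, "NC")
  expect_equal(classify_subject(base_record(
    cdr_global = 0.5, cdr_memory = 0.5, mmse = 27, adl = 12,
    hamd17 = 5, his = 2))$label, "MCI")
  expect_equal(classify_subject(base_record(
    mmse = 18, cdr_global = 1, cdr_memory = 1, adl = 20,
    his = 2, hamd17 = 4))$label, "AD_candidate")
  # the MMSE gate is an exclusive bound: mmse exactly at threshold fails NC
  expect_equal(classify_subject(base_record(mmse = 26))$label, "excluded")
  expect_equal(classify_subject(base_record(mmse = 20,
    education_level = "illiterate"))$label, "NC")
})

test_that("exclusion reasons follow the fixed gate order", {
  # depression gate first, even with an otherwise AD-consistent profile
  res <- classify_subject(base_record(mmse = 18, cdr_global = 1,
                                      adl = 20, hamd17 = 14))
  expect_equal(res$label, "excluded")
  expect_equal(res$reason, "depression")
  res2 <- classify_subject(base_record(mmse = 18, cdr_global = 1,
                                       adl = 20, his = 6))
  expect_equal(res2$reason, "vascular")
  res3 <- classify_subject(base_record(mmse = 18, cdr_global = 0, adl = 10))
  expect_equal(res3$reason, "cognitive_functional_profile")
  # depression precedes vascular when both gates fail
  res4 <- classify_subject(base_record(hamd17 = 15, his = 8, mmse = 18,
                                       cdr_global = 1, adl = 20))
  expect_equal(res4$reason, "depression")
})

test_that("classification is a partition: exactly one label per record", {
  set.seed(5)
  grid <- expand.grid(
    mmse = c(15, 20, 24, 27, 30),
    education_level = c("illiterate", "middle", "higher"),
    adl = c(10, 16, 25),
    cdr_global = c(0, 0.5, 1),
    cdr_memory = c(0, 0.5, 1),
    his = c(2, 6),
    hamd17 = c(5, 14),
    stringsAsFactors = FALSE
  )
  res <- classify_cohort(grid)
  expect_equal(nrow(res), nrow(grid))
  expect_true(all(res$label %in% c("NC", "MCI", "AD_candidate", "excluded")))
  expect_true(all(is.na(res$reason) == (res$label != "excluded")))

  # independent re-derivation of the inclusion profiles, record by record
  for (i in sample(nrow(grid), 80)) {
    r <- grid[i, ]
    ok_mmse <- r$mmse > mmse_min(r$education_level)
    manual <-
      if (r$cdr_global == 0 && ok_mmse && r$adl < 16) "NC"
      else if (r$cdr_global == 0.5 && r$cdr_memory == 0.5 && ok_mmse &&
                 r$adl < 16 && r$hamd17 <= 12 && r$his <= 4) "MCI"
      else if (!ok_mmse && r$cdr_global >= 0.5 && r$adl >= 16 &&
                 r$his <= 4 && r$hamd17 <= 12) "AD_candidate"
      else "excluded"
    expect_equal(res$label[i], manual)
  }
})

test_that("raising the depression score above 12 never yields MCI or AD", {
  set.seed(9)
  for (i in 1:40) {
    rec <- base_record(
      mmse = sample(10:30, 1),
      education_level = sample(c("illiterate", "primary", "middle", "higher"), 1),
      adl = sample(8:30, 1),
      cdr_global = sample(c(0, 0.5, 1, 2), 1),
      cdr_memory = sample(c(0, 0.5, 1), 1),
      his = sample(0:8, 1),
      hamd17 = sample(13:30, 1))
    label <- classify_subject(rec)$label
    expect_false(label %in% c("MCI", "AD_candidate"))
  }
})

test_that("missing mandatory fields are named in the error", {
  df <- as.data.frame(base_record(), stringsAsFactors = FALSE)
  df$his <- NA
  expect_error(classify_cohort(df), "his")
  expect_error(classify_cohort(df[setdiff(names(df), "adl")]), "adl")
})
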