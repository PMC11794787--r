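test_that("age normalization converts every supported unit to years", {
  expect_equal(normalize_age("120", "MON"), 10)
  expect_equal(normalize_age("1.2", "DEC"), 12)
  expect_equal(normalize_age("12", "YR"), 12)
  expect_equal(normalize_age("365.25", "DY"), 1)
  expect_equal(normalize_age("52.1775", "WK"), 1)
  expect_equal(normalize_age("8766", "HR"), 1)
  expect_true(is.na(normalize_age("", "")))
  expect_true(is.na(normalize_age("12", "")))      # unknown unit
  expect_true(is.na(normalize_age("-3", "YR")))    # negative
  expect_true(is.na(normalize_age("abc", "YR")))
})

test_that("target-drug matching is case-insensitive substring over synonyms", {
  drug <- tibble::tibble(
    drugname = c("KYMRIAH", "kymriah 1 infusion", "RITUXIMAB", ""),
    prod_ai = c("", "", "", "tisagenlecleucel"),
    role_cod = c("PS", "SS", "PS", "C"))
  expect_equal(match_target_drug(drug), c(TRUE, TRUE, FALSE, TRUE))
  # role restriction
  expect_equal(match_target_drug(drug, roles = c("PS", "SS")),
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("classification flags CVAE, CRS and fatality as specified", {
  fx <- labeled_fixture(fixture_quarter(n_background = 0))
  lab <- fx$lab$labels
  # a report with Hypotension only is CVAE (vascular SOC)
  hypo_ids <- unique(fx$lab$reac$primaryid[fx$lab$reac$pt == "Hypotension"])
  expect_true(all(lab$is_cvae[lab$primaryid %in% hypo_ids]))
  # tachycardia reports are CVAE and, in the fixture, all carry CRS
  tk <- unique(fx$lab$reac$primaryid[fx$lab$reac$pt == "Tachycardia"])
  expect_true(all(lab$is_cvae[lab$primaryid %in% tk]))
  expect_true(all(lab$has_crs[lab$primaryid %in% tk]))
  # hospitalization alone is not fatal
  expect_true(all(!lab$is_fatal | lab$primaryid %in%
                    fx$refined$outc$primaryid[fx$refined$outc$outc_cod == "DE"]))
})

test_that("unmapped PTs are counted and treated as non-cardiovascular", {
  b <- fixture_quarter(n_background = 0)
  small_map <- default_pt_map()[default_pt_map()$pt != "Shock", ]
  refined <- refine_bundle(b)
  lab <- label_reports(refined, pt_map = small_map)
  expect_gt(attr(lab$labels, "n_unmapped_pts"), 0)
  shock_only <- setdiff(
    unique(refined$reac$primaryid[refined$reac$pt == "Shock"]),
    unique(refined$reac$primaryid[refined$reac$pt %in%
                                    c("Hypotension", "Tachycardia",
                                      "Cardiac arrest")]))
  expect_true(all(!lab$labels$is_cvae[lab$labels$primaryid %in% shock_only]))
})

test_that("cohort partitions are exhaustive and percentages close", {
  fx <- labeled_fixture(fixture_quarter(n_background = 500))
  cohort <- fx$cohort
  expect_equal(sum(cohort$is_cvae) + sum(!cohort$is_cvae), nrow(cohort))
  cv <- cohort[cohort$is_cvae, ]
  expect_equal(sum(cv$is_fatal) + sum(!cv$is_fatal), nrow(cv))
  sm <- cohort_summary(cohort, by = "cvae")
  for (sec in unique(sm$categorical$section)) {
    for (g in unique(sm$categorical$group)) {
      p <- sm$categorical$pct[sm$categorical$section == sec &
                                sm$categorical$group == g]
      expect_equal(sum(p), 100, tolerance = 1e-8)
    }
  }
  # age quartiles ordered
  expect_true(all(sm$age$q1 <= sm$age$median & sm$age$median <= sm$age$q3))
})

test_that("shrinking the synonym list never grows the cohort", {
  fx <- labeled_fixture(fixture_quarter(n_background = 500))
  refined <- fx$refined
  full <- build_cohort(label_reports(refined)$labels)
  fewer <- build_cohort(label_reports(
    refined, synonyms = "KYMRIAH")$labels)
  expect_lte(nrow(fewer), nrow(full))
  expect_true(all(fewer$primaryid %in% full$primaryid))
})

test_that("a cohort of one gives only 0/100 percentages", {
  fx <- labeled_fixture(fixture_quarter(n_background = 0))
  one <- fx$cohort[1, , drop = FALSE]
  sm <- cohort_summary(one, by = "cvae")
  pct <- sm$categorical$pct
  expect_true(all(pct[!is.na(pct)] %in% c(0, 100)))  # NA = empty group
})

test_that("reports with missing age are excluded from the cohort", {
  b <- fixture_quarter(n_background = 0)
  b$demo$age[1] <- ""
  fx <- labeled_fixture(b)
  expect_equal(nrow(fx$cohort), 567L)
})
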