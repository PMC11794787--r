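mk_demo <- function(pid, cid, fda) {
  tibble::tibble(primaryid = as.character(pid), caseid = as.character(cid),
                 fda_dt = as.character(fda), event_dt = "", age = "",
                 age_cod = "", sex = "", occr_country = "", occp_cod = "")
}

test_that("the latest FDA_DT wins, ties broken by highest PRIMARYID", {
  d <- mk_demo(c(1, 2), c(7, 7), c("20220101", "20220301"))
  expect_equal(deduplicate_reports(d)$primaryid, "2")

  d2 <- mk_demo(c(5, 9), c(7, 7), c("20220301", "20220301"))
  expect_equal(deduplicate_reports(d2)$primaryid, "9")

  # all-distinct caseids: output is input (sorted by caseid)
  d3 <- mk_demo(3:1, c(30, 20, 10), "20220101")
  out <- deduplicate_reports(d3)
  expect_equal(out$primaryid, c("1", "2", "3"))
})

test_that("invalid keys are excluded; missing FDA_DT loses ties but survives alone", {
  d <- mk_demo(c(1, 2, 3), c("x", 5, 5), c("20220101", "", "20220101"))
  out <- deduplicate_reports(d)
  expect_equal(attr(out, "n_excluded"), 1L)
  expect_equal(out$primaryid, "3")  # blank fda_dt treated as 0, loses
  solo <- mk_demo(4, 6, "")
  expect_equal(deduplicate_reports(solo)$primaryid, "4")
})

test_that("deduplication is idempotent and permutation invariant", {
  withr::local_seed(11)
  for (i in 1:20) {
    d <- random_demo(80)
    once <- deduplicate_reports(d)
    expect_equal(as.data.frame(deduplicate_reports(once)),
                 as.data.frame(once), ignore_attr = TRUE)
    shuffled <- d[sample.int(nrow(d)), , drop = FALSE]
    expect_equal(as.data.frame(deduplicate_reports(shuffled)),
                 as.data.frame(once), ignore_attr = TRUE)
  }
})

test_that("deduplication matches the group/sort/take-last oracle", {
  withr::local_seed(4)
  for (i in 1:50) {
    d <- random_demo(sample(2:200, 1))
    expect_equal(as.data.frame(deduplicate_reports(d)),
                 as.data.frame(dedup_oracle(d)), ignore_attr = TRUE)
  }
})

test_that("deletions remove exactly the listed caseids, after dedup", {
  d <- mk_demo(1:3, 1:3, "20220101")
  out <- apply_deletions(d, c(2))
  expect_equal(out$caseid, c("1", "3"))
  expect_equal(attr(out, "n_deleted"), 1L)
  # disjoint set: identity
  out2 <- apply_deletions(d, c(99))
  expect_equal(out2$caseid, d$caseid)
  expect_equal(attr(out2, "n_deleted"), 0L)
})

test_that("cardinality: survivors = distinct valid caseids minus deletions", {
  withr::local_seed(9)
  for (i in 1:10) {
    d <- random_demo(150, n_cases = 60)
    del <- sample(1:60, 10)
    dd <- apply_deletions(deduplicate_reports(d), del)
    expected <- length(setdiff(unique(as.numeric(d$caseid)), del))
    expect_equal(nrow(dd), expected)
  }
})

test_that("refine_bundle removes generator duplicates and deletions exactly", {
  g <- generate_reports(generator_config(seed = 21, n_reports = 1000))
  refined <- refine_bundle(g$bundle)
  s <- attr(refined, "refine_summary")
  expect_equal(s$input_rows - s$unique_cases,
               length(g$truth$duplicate_primaryids))
  lost <- setdiff(g$bundle$demo$primaryid, refined$demo$primaryid)
  expected_lost <- c(g$truth$duplicate_primaryids,
                     g$truth$reports$final_primaryid[g$truth$reports$deleted])
  expect_setequal(as.integer(lost), expected_lost)
  # children follow the surviving primaryids
  for (tb in c("drug", "reac", "outc", "ther")) {
    expect_true(all(refined[[tb]]$primaryid %in% refined$demo$primaryid))
  }
})
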