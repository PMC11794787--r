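mk_tto_bundle <- function(event_dt, start_dt) {
  n <- length(event_dt)
  pid <- as.character(seq_len(n))
  demo <- tibble::tibble(primaryid = pid, caseid = pid, fda_dt = "20230301",
                         event_dt = event_dt, age = "10", age_cod = "YR",
                         sex = "M", occr_country = "US", occp_cod = "MD")
  drug <- tibble::tibble(primaryid = pid, caseid = pid, drug_seq = "1",
                         role_cod = "PS", drugname = "TISAGENLECLEUCEL",
                         prod_ai = "TISAGENLECLEUCEL")
  reac <- tibble::tibble(primaryid = pid, caseid = pid, pt = "Pyrexia")
  outc <- tibble::tibble(primaryid = character(), caseid = character(),
                         outc_cod = character())
  ther <- tibble::tibble(primaryid = pid, caseid = pid, dsg_drug_seq = "1",
                         start_dt = start_dt)
  assemble_quarter(demo, drug, reac, outc, ther)
}

test_that("onset days = event date minus earliest target therapy start", {
  b <- mk_tto_bundle(c("20220104", "202201", "20220101"),
                     c("20220101", "20220101", "20220104"))
  tto <- compute_tto(b)
  expect_equal(tto$days, c(3L, NA, NA))  # partial event and negative excluded
  excl <- attr(tto, "exclusions")
  expect_equal(unname(excl["missing_event"]), 1)
  expect_equal(unname(excl["negative"]), 1)
})

test_that("therapy start joins through the drug sequence of the target drug", {
  b <- mk_tto_bundle("20220110", "20220101")
  # an extra non-target drug with an earlier start must not shorten the TTO
  b$drug <- dplyr::bind_rows(b$drug, tibble::tibble(
    primaryid = "1", caseid = "1", drug_seq = "2", role_cod = "C",
    drugname = "VANCOMYCIN", prod_ai = "VANCOMYCIN"))
  b$ther <- dplyr::bind_rows(b$ther, tibble::tibble(
    primaryid = "1", caseid = "1", dsg_drug_seq = "2", start_dt = "20211201"))
  expect_equal(compute_tto(b)$days, 9L)
})

test_that("summaries use type-7 linear interpolation quantiles", {
  s <- tto_summary(c(1, 2, 3, 4, 5))
  expect_equal(unlist(s[c("median", "q1", "q3")]),
               c(median = 3, q1 = 2, q3 = 4))
  s2 <- tto_summary(c(1, 2, 3, 4))
  expect_equal(unlist(s2[c("q1", "median", "q3")]),
               c(q1 = 1.75, median = 2.5, q3 = 3.25))
  s3 <- tto_summary(7)
  expect_equal(unlist(s3[c("q1", "median", "q3")]),
               c(q1 = 7, median = 7, q3 = 7))
  expect_error(tto_summary(NA_real_), "no onset")
})

test_that("summaries are permutation invariant and shift equivariant", {
  withr::local_seed(2)
  x <- sample(0:60, 40, replace = TRUE)
  s <- tto_summary(x)
  expect_equal(tto_summary(rev(sort(x))), s)
  s5 <- tto_summary(x + 5)
  expect_equal(s5$median, s$median + 5)
  expect_equal(s5$q1, s$q1 + 5)
})

test_that("rank-sum test: exact enumeration on small tie-free samples", {
  w <- wilcoxon_two_sample(c(1, 2), c(3, 4))
  expect_equal(w$p, 1 / 3)
  expect_equal(w$method, "exact")
  # same multiset in both groups: p near 1; identical constants: p = 1
  expect_gt(wilcoxon_two_sample(c(1, 5, 9), c(1, 5, 9))$p, 0.9)
  expect_equal(wilcoxon_two_sample(c(2, 2), c(2, 2, 2))$p, 1)
})

test_that("clearly shifted large samples give tiny p-values", {
  withr::local_seed(8)
  x <- rlnorm(150, log(3), 0.8)
  y <- rlnorm(150, log(9), 0.8)
  expect_lt(wilcoxon_two_sample(x, y)$p, 1e-3)
})

test_that("exact and corrected-normal p agree closely on tie-free n 8-10", {
  # full sweep of all rank splits; the continuity-corrected normal
  # approximation stays within 0.05 of the exact enumeration everywhere
  worst <- 0
  for (n in 8:10) {
    for (nx in 2:(n - 2)) {
      splits <- utils::combn(n, nx)
      for (j in seq_len(ncol(splits))) {
        x <- splits[, j]; y <- setdiff(seq_len(n), x)
        p_exact <- wilcoxon_two_sample(x, y)$p
        p_norm <- suppressWarnings(
          stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
        worst <- max(worst, abs(p_exact - p_norm))
      }
    }
  }
  expect_lt(worst, 0.05)
})

test_that("generated CVAE onsets are earlier than non-CVAE onsets", {
  hits <- 0L
  for (seed in 1:10) {
    g <- generate_reports(generator_config(seed = seed, n_reports = 3000,
                                           target_share = 0.2,
                                           duplicate_rate = 0,
                                           deletion_rate = 0,
                                           partial_date_rate = 0))
    fx <- labeled_fixture(g$bundle)
    tto <- compute_tto(fx$refined)
    d <- tto$days[match(fx$cohort$primaryid, tto$primaryid)]
    ok <- !is.na(d)
    m_cv <- median(d[ok & fx$cohort$is_cvae])
    m_nc <- median(d[ok & !fx$cohort$is_cvae])
    hits <- hits + (m_cv < m_nc)
  }
  expect_gte(hits, 9L)
})
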