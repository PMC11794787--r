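test_that("the design matrix encodes ATC flags and restrictions correctly", {
  fx <- labeled_fixture(fixture_quarter(n_background = 0))
  d <- build_design(fx$cohort, fx$lab$atc_flags, "cvae")
  # levetiracetam (class N) carriers in the fixture are CVAE reports
  lev_ids <- fx$lab$atc_flags$primaryid[fx$lab$atc_flags$atc1 == "N"]
  expect_true(all(d$atc_N[d$primaryid %in% lev_ids] == 1))
  expect_true(all(d$atc_N[!d$primaryid %in% lev_ids] == 0))
  # fatal analysis: restricted to CVAE, cardiovascular class excluded
  d2 <- build_design(fx$cohort, fx$lab$atc_flags, "fatal_within_cvae")
  expect_true(all(d2$primaryid %in% fx$cohort$primaryid[fx$cohort$is_cvae]))
  expect_false("atc_C" %in% names(d2))
  expect_true("atc_C" %in% names(d))
  # target-only reports carry all-zero flags
  no_co <- setdiff(d$primaryid, fx$lab$atc_flags$primaryid)
  flags <- d[d$primaryid %in% no_co, grep("^atc_", names(d))]
  expect_true(all(as.matrix(flags) == 0))
})

test_that("constant outcomes and constant covariates are refused/skipped", {
  fx <- labeled_fixture(fixture_quarter(n_background = 0))
  all_cv <- fx$cohort[fx$cohort$is_cvae, ]
  expect_error(build_design(all_cv, fx$lab$atc_flags, "cvae"), "constant")
  d <- sim_design(200, c(x1 = 0.5))
  d$x2 <- 1L
  expect_warning(res <- univariate_screen(d), "constant covariate")
  expect_equal(res$note[res$variable == "x2"], "constant")
})

test_that("fits agree with a hand-rolled IRLS reference on random designs", {
  withr::local_seed(31)
  for (i in 1:20) {
    n <- sample(60:140, 1)
    k <- sample(1:3, 1)
    betas <- setNames(runif(k, -1, 1), paste0("x", seq_len(k)))
    d <- sim_design(n, betas, seed = sample.int(1e6, 1))
    if (length(unique(d$y)) < 2) next
    fit <- multivariate_fit(d, names(betas))
    ref <- irls_oracle(as.matrix(d[names(betas)]), d$y)
    expect_lt(max(abs(fit$beta - ref[-1])), 1e-6)
  }
})

test_that("wald chi-square, OR and CI are internally consistent", {
  d <- sim_design(500, c(x1 = log(2), x2 = 0), seed = 77)
  res <- two_stage_regression(d, report_age_t = FALSE)
  expect_equal(res$or, exp(res$beta))
  expect_equal(res$ci_low, exp(res$beta - 1.96 * res$se))
  expect_equal(res$ci_high, exp(res$beta + 1.96 * res$se))
  expect_equal(res$wald_chi2, (res$beta / res$se)^2)
  # intercept score equation: fitted probabilities sum to event count
  fit <- glm(y ~ x1 + x2, binomial(), d)
  expect_equal(sum(fitted(fit)), sum(d$y))
})

test_that("strong effects are selected, nulls mostly not", {
  sel_strong <- 0L; sel_null <- 0L
  for (seed in 1:30) {
    d <- sim_design(568, c(strong = log(4.6), null = 0), seed = seed)
    res <- univariate_screen(d)
    sel_strong <- sel_strong + res$selected[res$variable == "strong"]
    sel_null <- sel_null + res$selected[res$variable == "null"]
  }
  expect_gte(sel_strong, 29L)   # > 95% power at this effect size
  expect_lte(sel_null, 5L)      # near-nominal false selection
})

test_that("age is also summarized by a two-sample t statistic when asked", {
  fx <- labeled_fixture(fixture_quarter(n_background = 0))
  d <- build_design(fx$cohort, fx$lab$atc_flags, "fatal_within_cvae")
  res <- univariate_screen(d, report_age_t = TRUE)
  t_ref <- t.test(d$age[d$y == 1], d$age[d$y == 0])$statistic
  expect_equal(res$t_stat[res$variable == "age"], unname(t_ref))
  expect_true(all(is.na(res$t_stat[res$variable != "age"])))
})

test_that("separation is flagged but coefficients still reported", {
  d <- tibble::tibble(primaryid = 1:40, y = rep(c(0L, 1L), each = 20),
                      x1 = rep(c(0L, 1L), each = 20))
  res <- multivariate_fit(d, "x1")
  expect_true(res$separation)
  expect_true(is.finite(res$beta))
})
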