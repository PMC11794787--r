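# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package paths they verify.

# group by caseid, sort each group by (fda_dt, primaryid), take the last
dedup_oracle <- function(demo) {
  cid <- as.numeric(demo$caseid)
  fda <- ifelse(grepl("^[0-9]{8}$", trimws(demo$fda_dt)),
                as.numeric(demo$fda_dt), 0)
  pid <- as.numeric(demo$primaryid)
  keep <- vapply(split(seq_len(nrow(demo)), cid), function(ix) {
    ix[order(fda[ix], pid[ix])][length(ix)]
  }, integer(1))
  keep <- keep[order(cid[keep])]
  demo[keep, , drop = FALSE]
}

# random DEMO rows with duplicated caseids, shuffled
random_demo <- function(n, n_cases = max(1L, n %/% 2L)) {
  tibble::tibble(
    primaryid = as.character(sample.int(10 * n, n)),
    caseid = as.character(sample.int(n_cases, n, replace = TRUE)),
    fda_dt = format(as.Date("2020-01-01") +
                      sample.int(1000, n, replace = TRUE), "%Y%m%d"),
    event_dt = "", age = "", age_cod = "", sex = "", occr_country = "",
    occp_cod = ""
  )
}

# two-sided Fisher p by hypergeometric enumeration over fixed margins
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || b + d == 0) return(1)
  x <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(x, m1, m2, k)
  pobs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# two-sided exact rank-sum p by enumeration of all rank splits (no ties)
wilcox_oracle <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(n, nx)
  us <- apply(splits, 2, function(s) sum(s) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# logistic ML fit by hand-rolled IRLS (with intercept); returns coefficients
irls_oracle <- function(X, y, tol = 1e-10, maxit = 200) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      return(drop(beta_new))
    }
    beta <- drop(beta_new)
  }
  drop(beta)
}

# binary-covariate logistic simulation used by the regression tests
sim_design <- function(n, betas, intercept = -1, seed = 1) {
  withr::with_seed(seed, {
    X <- sapply(seq_along(betas), function(i) stats::rbinom(n, 1, 0.3))
    colnames(X) <- names(betas)
    eta <- intercept + drop(X %*% betas)
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    out <- tibble::as_tibble(as.data.frame(X))
    out$y <- y
    out$primaryid <- seq_len(n)
    out
  })
}

# tiny helper: labeled pipeline objects from a bundle
labeled_fixture <- function(bundle) {
  refined <- refine_bundle(bundle)
  lab <- label_reports(refined)
  cohort <- build_cohort(lab$labels)
  list(refined = refined, lab = lab, cohort = cohort,
       comparator = comparator_reports(lab$labels),
       cohort_reac = lab$reac[lab$reac$primaryid %in% cohort$primaryid, ,
                              drop = FALSE])
}
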