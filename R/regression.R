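#' Build the covariate design for the risk-factor analysis
#'
#' One row per cohort report with the binary outcome, age in years, sex
#' (male = 1, female = 0), and one indicator per ATC level-1 class of
#' non-target concomitant medication (plus the pooled `other` class).  For
#' the fatal-within-CVAE outcome the design is restricted to cardiovascular
#' reports and the cardiovascular medication class (`C`) is excluded, as is
#' conventional when death among cardiovascular events is the endpoint.
#' The target drug itself never contributes a flag (its antineoplastic
#' class would otherwise be constant).
#'
#' Rows with missing age or sex are dropped listwise.
#'
#' @param cohort Labeled cohort tibble.
#' @param atc_flags Long tibble `primaryid`, `atc1` from [label_reports()].
#' @param outcome `"cvae"` or `"fatal_within_cvae"`.
#' @return Tibble: `primaryid`, `y`, `age`, `sex`, and `atc_<class>`
#'   columns.  Errors if the outcome is constant.
#' @export
build_design <- function(cohort, atc_flags,
                         outcome = c("cvae", "fatal_within_cvae")) {
  outcome <- match.arg(outcome)
  dat <- cohort
  if (outcome == "fatal_within_cvae") {
    dat <- dat[dat$is_cvae, , drop = FALSE]
  }
  y <- if (outcome == "cvae") as.integer(dat$is_cvae)
       else as.integer(dat$is_fatal)
  sex <- ifelse(dat$sex == "M", 1L, ifelse(dat$sex == "F", 0L, NA_integer_))
  classes <- setdiff(names(atc1_labels), if (outcome == "fatal_within_cvae") "C")
  flags <- atc_flags[atc_flags$primaryid %in% dat$primaryid, , drop = FALSE]
  design <- tibble(primaryid = dat$primaryid, y = y,
                   age = dat$age_years, sex = sex)
  for (cl in classes) {
    ids <- flags$primaryid[flags$atc1 == cl]
    design[[paste0("atc_", cl)]] <- as.integer(design$primaryid %in% ids)
  }
  keep <- !is.na(design$age) & !is.na(design$sex)
  design <- design[keep, , drop = FALSE]
  if (nrow(design) == 0L || length(unique(design$y)) < 2L) {
    stop("outcome is constant (or design empty); fit refused", call. = FALSE)
  }
  design
}

fit_logistic <- function(formula, data) {
  warn <- character(0)
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  # separation shows up as boundary fitted probabilities, failed
  # convergence, or runaway coefficients at the last iterate
  sep <- any(grepl("fitted probabilities numerically 0 or 1", warn)) ||
    !fit$converged || max(abs(coef(fit)), na.rm = TRUE) > 15
  list(fit = fit, separation = sep, converged = fit$converged)
}

logistic_rows <- function(fit_obj, variables, stage) {
  fit <- fit_obj$fit
  cf <- summary(fit)$coefficients
  rows <- lapply(variables, function(v) {
    if (!v %in% rownames(cf)) return(NULL)
    beta <- cf[v, "Estimate"]; se <- cf[v, "Std. Error"]
    wald <- (beta / se)^2
    tibble(variable = v, stage = stage,
           wald_chi2 = wald, p = pchisq(wald, df = 1, lower.tail = FALSE),
           beta = beta, se = se, or = exp(beta),
           ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
           separation = fit_obj$separation, converged = fit_obj$converged,
           note = NA_character_)
  })
  bind_rows(rows)
}

#' Univariate screen of candidate risk factors
#'
#' Fits one single-covariate logistic regression per variable (age as a
#' continuous slope, sex and each ATC class as indicators) and marks
#' variables with Wald p < 0.05 as selected for the multivariate stage.
#' For the fatal-within-CVAE outcome the two-sample t statistic of age by
#' outcome is additionally reported (`t_stat`), mirroring the mixed
#' univariate conventions of routine pharmacovigilance reports.  Constant
#' covariates are skipped with a note; complete separation is flagged, the
#' coefficient still reported.
#'
#' @param design Tibble from [build_design()].
#' @param report_age_t Also report the age t statistic (default: TRUE).
#' @return Tibble of per-variable results with a `selected` column.
#' @export
univariate_screen <- function(design, report_age_t = TRUE) {
  vars <- setdiff(names(design), c("primaryid", "y"))
  rows <- lapply(vars, function(v) {
    x <- design[[v]]
    if (length(unique(x)) < 2L) {
      warning("skipping constant covariate: ", v, call. = FALSE)
      return(tibble(variable = v, stage = "univariate", wald_chi2 = NA_real_,
                    p = NA_real_, beta = NA_real_, se = NA_real_,
                    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    separation = FALSE, converged = NA, note = "constant"))
    }
    f <- fit_logistic(stats::reformulate(v, "y"), design)
    logistic_rows(f, v, "univariate")
  })
  out <- bind_rows(rows)
  out$t_stat <- NA_real_
  if (report_age_t && "age" %in% vars) {
    tt <- tryCatch(t.test(design$age[design$y == 1],
                          design$age[design$y == 0]),
                   error = function(e) NULL)
    if (!is.null(tt)) out$t_stat[out$variable == "age"] <- unname(tt$statistic)
  }
  out$selected <- !is.na(out$p) & out$p < 0.05
  out
}

#' Multivariate logistic fit of the selected variables
#'
#' Maximum-likelihood logistic regression (IRLS as implemented by
#' `stats::glm`, coefficient-change tolerance 1e-8, at most 100 iterations)
#' of the outcome on all selected variables jointly.  Wald chi-square,
#' odds ratios and 95% CIs per variable; non-convergence or separation is
#' flagged on every row, coefficients reported at the last iterate.
#'
#' @param design Tibble from [build_design()].
#' @param selected Nonempty character vector of design column names.
#' @return Tibble of per-variable results (`stage = "multivariate"`).
#' @export
multivariate_fit <- function(design, selected) {
  if (length(selected) == 0L) stop("no variables selected", call. = FALSE)
  stopifnot(all(selected %in% names(design)))
  f <- fit_logistic(stats::reformulate(selected, "y"), design)
  logistic_rows(f, selected, "multivariate")
}

#' Two-stage risk-factor analysis
#'
#' The screening convention used throughout pharmacovigilance reports:
#' univariate logistic screen at p < 0.05, then one multivariate logistic
#' model of the selected variables.  No multiplicity correction is applied
#' across the screened variables.
#'
#' @inheritParams univariate_screen
#' @return Tibble stacking the univariate and multivariate rows.
#' @export
two_stage_regression <- function(design, report_age_t = TRUE) {
  uni <- univariate_screen(design, report_age_t = report_age_t)
  sel <- uni$variable[uni$selected]
  if (length(sel) == 0L) {
    message("no variables passed the univariate screen")
    return(uni)
  }
  multi <- multivariate_fit(design, sel)
  multi$t_stat <- NA_real_
  multi$selected <- NA
  bind_rows(uni, multi)
}
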