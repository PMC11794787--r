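#' Default preferred-term catalog for the generator
#'
#' Each PT carries its SOC and a background reporting rate (per report, in
#' the comparator population).  Rates are order-of-magnitude realistic for
#' a spontaneous-report database: common systemic terms a few percent,
#' cardiovascular terms well below one percent.
#'
#' @return Tibble `pt`, `soc`, `background_rate`.
#' @export
default_generator_pts <- function() {
  m <- default_pt_map()
  pts <- c(Hypotension = 0.010, Hypertension = 0.006, Tachycardia = 0.008,
           Shock = 0.003, "Cardiac arrest" = 0.002, "Heart failure" = 0.003,
           "Pericardial effusion" = 0.002, "Mitral valve disease" = 0.001,
           "Capillary leak syndrome" = 0.001,
           Pyrexia = 0.060, Neutropenia = 0.040, Headache = 0.050,
           Vomiting = 0.050, Seizure = 0.015, "Acute kidney injury" = 0.015,
           Hypoxia = 0.010)
  tibble(pt = names(pts),
         soc = m$soc[match(names(pts), m$pt)],
         background_rate = unname(pts))
}

#' Generator configuration with validated defaults
#'
#' The defaults define the study-like conditions the test-suite simulations
#' run under; see the methods vignette for the rationale behind each value.
#'
#' @param seed Integer seed driving all sampling.
#' @param n_reports Number of distinct reports (cases) to draw.
#' @param target_share Probability a report names the target drug.
#' @param pediatric_share Probability a report's patient is under 18.
#' @param pt_catalog Tibble `pt`, `soc`, `background_rate`.
#' @param injected_ror Named numeric: reporting-odds multiplier applied to
#'   the named PTs on target reports only (1 = null).
#' @param crs_given_cvae P(CRS PT co-reported | target report with a
#'   cardiovascular PT).
#' @param crs_given_target P(CRS | target report without a cardiovascular
#'   PT).
#' @param crs_background P(CRS | non-target report).
#' @param tto_lognormal List with `cvae` and `non_cvae` elements, each
#'   `c(meanlog, sdlog)` of the log-normal onset-day distribution.
#' @param fatality_model List: `intercept`, `age` (log-OR per year),
#'   `cvae` (log-OR), `classes` (named log-ORs per ATC class flag).
#' @param class_prevalence Named numeric: per-report probability of a
#'   concomitant drug in each ATC level-1 class.
#' @param duplicate_rate Fraction of reports re-emitted as a later version
#'   (same CASEID, new PRIMARYID, later FDA_DT).
#' @param deletion_rate Fraction of CASEIDs put on the deletion list.
#' @param partial_date_rate Fraction of event/start dates emitted at
#'   YYYYMM precision.
#' @param atc_catalog Tibble `drugname`, `atc1` naming one or more
#'   representative drugs per class.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_reports = 20000L,
                             target_share = 0.03,
                             pediatric_share = 0.5,
                             pt_catalog = default_generator_pts(),
                             injected_ror = c(Hypotension = 30),
                             crs_given_cvae = 0.9,
                             crs_given_target = 0.3,
                             crs_background = 0.002,
                             tto_lognormal = list(
                               cvae = c(meanlog = log(3), sdlog = 1.0),
                               non_cvae = c(meanlog = log(7), sdlog = 1.2)),
                             fatality_model = list(
                               intercept = -0.4, age = -0.094, cvae = 0.5,
                               classes = c(R = log(1.82))),
                             class_prevalence = c(
                               A = 0.15, B = 0.10, C = 0.08, D = 0.05,
                               G = 0.05, H = 0.10, J = 0.20, L = 0.25,
                               M = 0.06, N = 0.15, P = 0.03, R = 0.10,
                               S = 0.03),
                             duplicate_rate = 0.10,
                             deletion_rate = 0.02,
                             partial_date_rate = 0.10,
                             atc_catalog = default_atc_map()) {
  cfg <- list(seed = as.integer(seed), n_reports = as.integer(n_reports),
              target_share = target_share, pediatric_share = pediatric_share,
              pt_catalog = pt_catalog, injected_ror = injected_ror,
              crs_given_cvae = crs_given_cvae,
              crs_given_target = crs_given_target,
              crs_background = crs_background,
              tto_lognormal = tto_lognormal,
              fatality_model = fatality_model,
              class_prevalence = class_prevalence,
              duplicate_rate = duplicate_rate,
              deletion_rate = deletion_rate,
              partial_date_rate = partial_date_rate,
              atc_catalog = atc_catalog)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  fr <- c(target_share = cfg$target_share,
          pediatric_share = cfg$pediatric_share,
          crs_given_cvae = cfg$crs_given_cvae,
          crs_given_target = cfg$crs_given_target,
          crs_background = cfg$crs_background,
          duplicate_rate = cfg$duplicate_rate,
          deletion_rate = cfg$deletion_rate,
          partial_date_rate = cfg$partial_date_rate)
  if (any(fr < 0 | fr > 1)) {
    stop("generator rates/fractions must lie in [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "), call. = FALSE)
  }
  if (cfg$n_reports < 1L) stop("n_reports must be >= 1", call. = FALSE)
  pc <- cfg$pt_catalog
  if (any(pc$background_rate <= 0 | pc$background_rate >= 1)) {
    stop("background rates must lie in (0, 1)", call. = FALSE)
  }
  if (length(cfg$injected_ror)) {
    if (any(cfg$injected_ror <= 0)) {
      stop("odds multipliers must be positive", call. = FALSE)
    }
    missing_pt <- setdiff(names(cfg$injected_ror), pc$pt)
    if (length(missing_pt)) {
      stop("injected_ror names absent from pt_catalog: ",
           paste(missing_pt, collapse = ", "), call. = FALSE)
    }
  }
  bad_cls <- setdiff(names(cfg$fatality_model$classes),
                     names(cfg$class_prevalence))
  if (length(bad_cls)) {
    stop("fatality_model classes without a prevalence: ",
         paste(bad_cls, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

fmt_dt <- function(d) format(d, "%Y%m%d")

#' Generate a FAERS-like quarter with known ground truth
#'
#' Draws `n_reports` independent spontaneous reports: the target drug with
#' probability `target_share`; every PT in the catalog per report with
#' background odds, multiplied by the injected odds ratio on target
#' reports; a guaranteed anchor reaction so no report is reaction-free;
#' CRS co-reporting at the configured conditional rates; therapy-start and
#' event dates consistent with the group-specific log-normal onset times;
#' death from the logistic fatality model over age, cardiovascular status
#' and co-medication class flags; versioned duplicates (same CASEID, later
#' FDA_DT, higher PRIMARYID) at `duplicate_rate`; and a deletion list at
#' `deletion_rate`.  All sampling is driven by `config$seed`; a fixed seed
#' and config reproduce the output exactly.
#'
#' @param config A `generator_config`.
#' @return List with `bundle` (a `faers_bundle` of string tables, as read
#'   from disk) and `truth` (list: per-report tibble `reports`, the injected
#'   parameters, `duplicate_primaryids` — the superseded versions a correct
#'   dedup must remove — and `deleted_caseids`).
#' @export
generate_reports <- function(config = generator_config()) {
  validate_generator_config(config)
  withr::with_seed(config$seed, generate_reports_impl(config))
}

generate_reports_impl <- function(cfg) {
  n <- cfg$n_reports
  caseid <- 10000000L + seq_len(n)
  primaryid <- 100000000L + seq_len(n)
  is_target <- runif(n) < cfg$target_share
  pediatric <- runif(n) < cfg$pediatric_share
  age <- ifelse(pediatric, sample(0:17, n, replace = TRUE),
                sample(18:90, n, replace = TRUE))
  sex <- sample(c("M", "F", ""), n, replace = TRUE, prob = c(.55, .41, .04))
  country <- sample(c("US", "JP", "CA", "ES", "AU", "GB", "FR", "DE", "IT", "BR"),
                    n, replace = TRUE,
                    prob = c(.60, .05, .04, .03, .02, .02, .02, .02, .02, .18))
  occp <- sample(c("MD", "PH", "OT", "CN", ""), n, replace = TRUE,
                 prob = c(.50, .20, .12, .12, .06))

  # reactions: each catalog PT Bernoulli per report, odds multiplied on
  # target reports for injected PTs
  pc <- cfg$pt_catalog
  mult <- rep(1, nrow(pc))
  idx <- match(names(cfg$injected_ror), pc$pt)
  mult[idx] <- cfg$injected_ror
  pt_hits <- matrix(FALSE, n, nrow(pc))
  for (j in seq_len(nrow(pc))) {
    p0 <- pc$background_rate[j]
    pj <- ifelse(is_target, plogis(qlogis(p0) + log(mult[j])), p0)
    pt_hits[, j] <- runif(n) < pj
  }
  cv_col <- pc$soc %in% cardiovascular_socs
  is_cvae <- rowSums(pt_hits[, cv_col, drop = FALSE]) > 0
  anchor <- sample(c("Pyrexia", "Headache", "Vomiting", "Fatigue", "Rash"),
                   n, replace = TRUE)
  p_crs <- ifelse(is_target,
                  ifelse(is_cvae, cfg$crs_given_cvae, cfg$crs_given_target),
                  cfg$crs_background)
  has_crs <- runif(n) < p_crs

  # concomitant medication class flags
  classes <- names(cfg$class_prevalence)
  flag_mat <- matrix(FALSE, n, length(classes),
                     dimnames = list(NULL, classes))
  for (cl in classes) {
    flag_mat[, cl] <- runif(n) < cfg$class_prevalence[[cl]]
  }

  # death via the logistic fatality model
  fm <- cfg$fatality_model
  lin <- fm$intercept + fm$age * age + fm$cvae * as.numeric(is_cvae)
  for (cl in names(fm$classes)) {
    lin <- lin + fm$classes[[cl]] * flag_mat[, cl]
  }
  died <- runif(n) < plogis(lin)

  # dates: therapy start early in the quarter, onset log-normal by group
  start <- as.Date("2023-01-01") + sample(0:45, n, replace = TRUE)
  tl <- cfg$tto_lognormal
  days <- ifelse(is_cvae,
                 rlnorm(n, tl$cvae[["meanlog"]], tl$cvae[["sdlog"]]),
                 rlnorm(n, tl$non_cvae[["meanlog"]], tl$non_cvae[["sdlog"]]))
  days <- pmax(0L, as.integer(round(days)))
  event <- start + days
  fda <- event + sample(1:30, n, replace = TRUE)
  ev_partial <- runif(n) < cfg$partial_date_rate
  st_partial <- runif(n) < cfg$partial_date_rate
  event_dt <- ifelse(ev_partial, format(event, "%Y%m"), fmt_dt(event))
  start_dt <- ifelse(st_partial, format(start, "%Y%m"), fmt_dt(start))

  # ages emitted in mixed units: a slice of pediatric ages goes out in months
  as_months <- pediatric & runif(n) < 0.15
  age_val <- ifelse(as_months, as.character(age * 12L), as.character(age))
  age_cod <- ifelse(as_months, "MON", "YR")

  demo <- tibble(primaryid = as.character(primaryid),
                 caseid = as.character(caseid),
                 fda_dt = fmt_dt(fda), event_dt = event_dt,
                 age = age_val, age_cod = age_cod, sex = sex,
                 occr_country = country, occp_cod = occp)

  # drug/ther tables: suspect drug row + one row per flagged class
  atc <- cfg$atc_catalog
  class_drug <- vapply(classes, function(cl) {
    nm <- atc$drugname[atc$atc1 == cl]
    if (length(nm)) nm[1] else "UNMAPPED COMPOUND"
  }, character(1))
  suspect_pool <- c("PEMBROLIZUMAB", "INFLIXIMAB", "ADALIMUMAB",
                    "BLINATUMOMAB", "METHOTREXATE", "PARACETAMOL")
  suspect <- ifelse(is_target, "TISAGENLECLEUCEL",
                    sample(suspect_pool, n, replace = TRUE))
  drug_rows <- list(tibble(primaryid = as.character(primaryid),
                           caseid = as.character(caseid),
                           drug_seq = "1", role_cod = "PS",
                           drugname = suspect, prod_ai = suspect))
  seq_no <- rep(1L, n)
  for (cl in classes) {
    sel <- which(flag_mat[, cl])
    if (!length(sel)) next
    seq_no[sel] <- seq_no[sel] + 1L
    drug_rows[[length(drug_rows) + 1L]] <-
      tibble(primaryid = as.character(primaryid[sel]),
             caseid = as.character(caseid[sel]),
             drug_seq = as.character(seq_no[sel]), role_cod = "C",
             drugname = class_drug[[cl]], prod_ai = class_drug[[cl]])
  }
  drug <- arrange(bind_rows(drug_rows), .data$primaryid,
                  as.integer(.data$drug_seq))

  ther <- tibble(primaryid = as.character(primaryid),
                 caseid = as.character(caseid),
                 dsg_drug_seq = "1", start_dt = start_dt)

  # reactions table: anchor PT + sampled catalog PTs + CRS
  reac_rows <- list(tibble(primaryid = as.character(primaryid),
                           caseid = as.character(caseid), pt = anchor))
  for (j in seq_len(nrow(pc))) {
    sel <- which(pt_hits[, j])
    if (!length(sel)) next
    reac_rows[[length(reac_rows) + 1L]] <-
      tibble(primaryid = as.character(primaryid[sel]),
             caseid = as.character(caseid[sel]), pt = pc$pt[j])
  }
  sel <- which(has_crs)
  if (length(sel)) {
    reac_rows[[length(reac_rows) + 1L]] <-
      tibble(primaryid = as.character(primaryid[sel]),
             caseid = as.character(caseid[sel]), pt = crs_pt)
  }
  reac <- distinct(arrange(bind_rows(reac_rows), .data$primaryid, .data$pt))

  # outcomes: DE for deaths; a sampled non-fatal outcome for others
  has_outc <- died | runif(n) < 0.6
  outc_cod <- ifelse(died, "DE",
                     sample(c("HO", "OT", "LT", "DS"), n, replace = TRUE,
                            prob = c(.5, .3, .1, .1)))
  outc <- tibble(primaryid = as.character(primaryid[has_outc]),
                 caseid = as.character(caseid[has_outc]),
                 outc_cod = outc_cod[has_outc])

  # versioned duplicates: same CASEID, higher PRIMARYID, later FDA_DT
  n_dup <- floor(cfg$duplicate_rate * n)
  dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
  dup_old_pid <- as.character(primaryid[dup_idx])
  dup_new_pid <- as.character(200000000L + seq_along(dup_idx))
  if (n_dup > 0) {
    dup_demo <- demo[dup_idx, , drop = FALSE]
    dup_demo$primaryid <- dup_new_pid
    dup_demo$fda_dt <- fmt_dt(fda[dup_idx] + sample(1:60, n_dup, replace = TRUE))
    demo <- bind_rows(demo, dup_demo)
    clone <- function(tb) {
      sel <- tb$primaryid %in% dup_old_pid
      cp <- tb[sel, , drop = FALSE]
      cp$primaryid <- dup_new_pid[match(cp$primaryid, dup_old_pid)]
      bind_rows(tb, cp)
    }
    drug <- clone(drug); reac <- clone(reac)
    outc <- clone(outc); ther <- clone(ther)
  }

  n_del <- floor(cfg$deletion_rate * n)
  deleted <- if (n_del > 0) sort(sample(caseid, n_del)) else integer(0)

  truth_reports <- tibble(
    caseid = caseid, primaryid = primaryid,
    final_primaryid = as.integer(ifelse(seq_len(n) %in% dup_idx,
                                        dup_new_pid[match(seq_len(n), dup_idx)],
                                        primaryid)),
    is_target = is_target, pediatric = pediatric, age = age,
    is_cvae = is_cvae, has_crs = has_crs, died = died,
    tto_days = days, deleted = caseid %in% deleted
  )
  truth_flags <- as_tibble(flag_mat)
  truth_flags$caseid <- caseid

  bundle <- assemble_quarter(demo, drug, reac, outc, ther,
                             deleted_caseids = deleted)
  truth <- list(
    reports = truth_reports,
    class_flags = truth_flags,
    injected_ror = cfg$injected_ror,
    tto_medians = c(cvae = exp(cfg$tto_lognormal$cvae[["meanlog"]]),
                    non_cvae = exp(cfg$tto_lognormal$non_cvae[["meanlog"]])),
    fatality_model = cfg$fatality_model,
    duplicate_primaryids = sort(as.integer(dup_old_pid)),
    deleted_caseids = deleted
  )
  list(bundle = bundle, truth = truth)
}

#' Write a generated quarter (and its ground truth) to a directory
#'
#' Emits the five tables plus the deletion list with [write_quarter()],
#' optionally splitting reports into consecutive quarters by FDA_DT to
#' exercise cross-quarter deduplication, and stores the ground truth as
#' JSON beside the data files.
#'
#' @param config A `generator_config`.
#' @param dir Output directory.
#' @param quarters Number of quarter files to split into (by FDA_DT order).
#' @return The `generate_reports()` result, invisibly.
#' @export
simulate_to_dir <- function(config, dir, quarters = 1L) {
  gen <- generate_reports(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  demo <- gen$bundle$demo
  ord <- order(demo$fda_dt, demo$primaryid)
  bins <- if (quarters > 1L) {
    cut(seq_along(ord), breaks = quarters, labels = FALSE)
  } else {
    rep(1L, length(ord))
  }
  tags <- sprintf("23Q%d", seq_len(quarters))
  for (q in seq_len(quarters)) {
    ids <- demo$primaryid[ord[bins == q]]
    sub <- lapply(gen$bundle[c("demo", "drug", "reac", "outc", "ther")],
                  function(tb) tb[tb$primaryid %in% ids, , drop = FALSE])
    del <- if (q == quarters) gen$bundle$deleted_caseids else numeric(0)
    b <- assemble_quarter(sub$demo, sub$drug, sub$reac, sub$outc, sub$ther,
                          deleted_caseids = del)
    write_quarter(b, dir, tags[q])
  }
  truth_json <- gen$truth
  truth_json$reports <- NULL
  truth_json$class_flags <- NULL
  jsonlite::write_json(truth_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(gen)
}
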