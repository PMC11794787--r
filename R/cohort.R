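age_unit_factors <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                      DY = 1 / 365.25, HR = 1 / 8766)

#' Convert FAERS age values to years
#'
#' FAERS ages arrive as free-text numbers with a unit code (decades, years,
#' months, weeks, days, hours).  Unparseable values, negative values and
#' missing unit codes come back `NA`.
#'
#' @param value Character (or numeric) vector of age values.
#' @param unit Character vector of unit codes (`DEC`, `YR`, `MON`, `WK`,
#'   `DY`, `HR`); recycled if length 1.
#' @return Numeric vector of ages in years.
#' @examples
#' normalize_age(c("120", "1.2", ""), c("MON", "DEC", ""))
#' @export
normalize_age <- function(value, unit) {
  if (length(unit) == 1L) unit <- rep(unit, length(value))
  stopifnot(length(value) == length(unit))
  v <- suppressWarnings(as.numeric(trimws(as.character(value))))
  f <- age_unit_factors[toupper(trimws(unit))]
  out <- unname(v * f)
  out[!is.finite(out) | out < 0] <- NA_real_
  out
}

synonym_pattern <- function(synonyms) {
  stopifnot(length(synonyms) >= 1L)
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", toupper(trimws(synonyms)))
  paste(esc, collapse = "|")
}

#' Flag DRUG rows naming the target drug
#'
#' A row matches when its DRUGNAME or PROD_AI contains any synonym,
#' case-insensitively, after trimming.  Optionally restricted to given role
#' codes (PS/SS/C/I); by default every role counts.
#'
#' @param drug Tibble of DRUG rows.
#' @param synonyms Non-empty character vector of name fragments.
#' @param roles Optional character vector of role codes to admit.
#' @return Logical vector, one element per DRUG row.
#' @export
match_target_drug <- function(drug, synonyms = target_drug_synonyms,
                              roles = NULL) {
  pat <- synonym_pattern(synonyms)
  hit <- grepl(pat, toupper(drug$drugname)) |
    grepl(pat, toupper(drug$prod_ai))
  if (!is.null(roles)) {
    hit <- hit & toupper(trimws(drug$role_cod)) %in% toupper(roles)
  }
  hit
}

occp_labels <- c(MD = "physician", PH = "pharmacist",
                 OT = "other health professional", HP = "other health professional",
                 CN = "consumer", LW = "other")

#' Label deduplicated reports for the case/non-case analysis
#'
#' Joins the five tables of a refined bundle into one row per report with
#' normalized demographics and the analysis flags: target-drug use,
#' pediatric age (< 18 years), cardiovascular adverse event (any PT whose
#' SOC is in [cardiovascular_socs]), fatal outcome (outcome code `DE`),
#' cytokine-release-syndrome co-report (exact PT match, case-insensitive),
#' and ATC level-1 classes of non-target concomitant drugs.
#'
#' PTs absent from `pt_map` are treated as non-cardiovascular and counted in
#' the `"n_unmapped_pts"` attribute.  Non-target drugs absent from `atc_map`
#' contribute the pooled class `"other"`.
#'
#' @param bundle A refined `faers_bundle` (see [refine_bundle()]).
#' @param pt_map Tibble with columns `pt`, `soc`.
#' @param atc_map Tibble with columns `drugname`, `atc1`.
#' @param synonyms Target-drug synonyms.
#' @param roles Optional DRUG role codes counted for target identification.
#' @return List with `labels` (one row per report: demographics + flags),
#'   `atc_flags` (long tibble `primaryid`, `atc1` over non-target drugs) and
#'   `reac` (long tibble `primaryid`, `pt`, `soc`, distinct per report).
#' @export
label_reports <- function(bundle, pt_map = default_pt_map(),
                          atc_map = default_atc_map(),
                          synonyms = target_drug_synonyms, roles = NULL) {
  demo <- bundle$demo
  # reactions, binary per report
  reac <- distinct(tibble(primaryid = bundle$reac$primaryid,
                          pt = trimws(bundle$reac$pt)))
  key <- tolower(reac$pt)
  soc <- pt_map$soc[match(key, tolower(trimws(pt_map$pt)))]
  n_unmapped <- sum(is.na(soc) & nzchar(reac$pt))
  reac$soc <- soc
  cv_ids <- unique(reac$primaryid[!is.na(reac$soc) &
                                    reac$soc %in% cardiovascular_socs])
  crs_ids <- unique(reac$primaryid[tolower(reac$pt) == tolower(crs_pt)])
  de_ids <- unique(bundle$outc$primaryid[
    toupper(trimws(bundle$outc$outc_cod)) == "DE"])
  is_target_row <- match_target_drug(bundle$drug, synonyms, roles)
  target_ids <- unique(bundle$drug$primaryid[is_target_row])
  # ATC flags over non-target drug rows
  nt <- bundle$drug[!is_target_row, , drop = FALSE]
  atc_key <- toupper(trimws(atc_map$drugname))
  cls <- atc_map$atc1[match(toupper(trimws(nt$drugname)), atc_key)]
  cls2 <- atc_map$atc1[match(toupper(trimws(nt$prod_ai)), atc_key)]
  cls[is.na(cls)] <- cls2[is.na(cls)]
  cls[is.na(cls)] <- "other"
  has_drugname <- nzchar(trimws(nt$drugname)) | nzchar(trimws(nt$prod_ai))
  atc_flags <- distinct(tibble(primaryid = nt$primaryid[has_drugname],
                               atc1 = cls[has_drugname]))
  npts <- table(reac$primaryid)
  occ_code <- toupper(trimws(demo$occp_cod))
  rep_lab <- unname(occp_labels[occ_code])
  unknown <- is.na(rep_lab)
  rep_lab[unknown] <- ifelse(nzchar(occ_code[unknown]), "other", "missing")
  sex <- toupper(trimws(demo$sex))
  sex[!sex %in% c("M", "F")] <- "missing"
  labels <- tibble(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    age_years = normalize_age(demo$age, demo$age_cod),
    sex = sex,
    country = toupper(trimws(demo$occr_country)),
    reporter = unname(rep_lab),
    event_dt = demo$event_dt,
    fda_dt = demo$fda_dt,
    year = ifelse(grepl("^[0-9]{4}", trimws(demo$fda_dt)),
                  as.integer(substr(trimws(demo$fda_dt), 1, 4)), NA_integer_),
    is_target = demo$primaryid %in% target_ids,
    is_cvae = demo$primaryid %in% cv_ids,
    is_fatal = demo$primaryid %in% de_ids,
    has_crs = demo$primaryid %in% crs_ids,
    n_pts = as.integer(npts[demo$primaryid])
  )
  labels$n_pts[is.na(labels$n_pts)] <- 0L
  labels$is_pediatric <- !is.na(labels$age_years) & labels$age_years < 18
  attr(labels, "n_unmapped_pts") <- n_unmapped
  list(labels = labels, atc_flags = atc_flags, reac = reac)
}

#' Extract the analysis cohort: pediatric target-drug reports
#'
#' The cohort comprises deduplicated reports that name the target drug and
#' have a known age strictly below 18 years; reports with missing age are
#' excluded (conservative, reproducible).
#'
#' @param labels Labels tibble from [label_reports()].
#' @return The cohort subset of `labels`.
#' @export
build_cohort <- function(labels) {
  out <- labels[labels$is_target & labels$is_pediatric, , drop = FALSE]
  if (nrow(out) == 0L) warning("empty cohort", call. = FALSE)
  out
}

#' Select the comparator (non-case) population
#'
#' All deduplicated reports of other drugs, i.e. reports that do not name
#' the target drug at all (a target report outside the pediatric cohort is
#' still a target report, not a non-case); optionally restricted to
#' pediatric reports.
#'
#' @param labels Labels tibble from [label_reports()].
#' @param scope `"all"` (default) or `"pediatric"`.
#' @return Subset of `labels`.
#' @export
comparator_reports <- function(labels, scope = c("all", "pediatric")) {
  scope <- match.arg(scope)
  out <- labels[!labels$is_target, , drop = FALSE]
  if (scope == "pediatric") out <- out[out$is_pediatric, , drop = FALSE]
  out
}

#' Headline cohort counts and shares
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @return Named list: `n`, `n_cvae`, `pct_cvae`, `n_non_cvae`,
#'   `pct_non_cvae`, `n_fatal_cvae`, `pct_fatal_within_cvae`,
#'   `n_crs_within_cvae`, `pct_crs_within_cvae`.
#' @export
cohort_overview <- function(cohort) {
  n <- nrow(cohort)
  n_cvae <- sum(cohort$is_cvae)
  n_fatal <- sum(cohort$is_cvae & cohort$is_fatal)
  n_crs <- sum(cohort$is_cvae & cohort$has_crs)
  list(
    n = n,
    n_cvae = n_cvae,
    pct_cvae = 100 * n_cvae / n,
    n_non_cvae = n - n_cvae,
    pct_non_cvae = 100 * (n - n_cvae) / n,
    n_fatal_cvae = n_fatal,
    pct_fatal_within_cvae = if (n_cvae > 0) 100 * n_fatal / n_cvae else NA_real_,
    n_crs_within_cvae = n_crs,
    pct_crs_within_cvae = if (n_cvae > 0) 100 * n_crs / n_cvae else NA_real_
  )
}

summary_block <- function(values, groups, group_levels, section) {
  rows <- list()
  totals <- c(table(factor(groups, levels = group_levels)))
  totals <- c(totals, Total = length(groups))
  cats <- unique(values)
  for (g in c(group_levels, "Total")) {
    v <- if (g == "Total") values else values[groups == g]
    denom <- totals[[g]]
    tab <- table(factor(v, levels = cats))
    rows[[g]] <- tibble(section = section, category = names(tab), group = g,
                        n = as.integer(tab),
                        pct = if (denom > 0) 100 * as.integer(tab) / denom
                              else rep(NA_real_, length(tab)))
  }
  bind_rows(rows)
}

#' Demographic summary of a labeled cohort
#'
#' Table-1-style descriptive summary: sex, top-5 countries, receipt year
#' (from FDA_DT) and reporter type as counts with percentages per column
#' (denominator = column size, missing categories included), plus median and
#' quartile age per group.  Grouping is either cardiovascular vs not
#' (`by = "cvae"`, whole cohort) or fatal vs non-fatal (`by = "fatal"`,
#' restricted to cardiovascular reports).
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param by `"cvae"` or `"fatal"`.
#' @param top_countries How many countries to list individually.
#' @return List with `categorical` (tibble: section, category, group, n,
#'   pct) and `age` (tibble: group, n, median, q1, q3).
#' @export
cohort_summary <- function(cohort, by = c("cvae", "fatal"),
                           top_countries = 5L) {
  by <- match.arg(by)
  if (by == "fatal") cohort <- cohort[cohort$is_cvae, , drop = FALSE]
  if (nrow(cohort) == 0L) {
    warning("empty cohort: empty summary", call. = FALSE)
    return(list(categorical = tibble(section = character(), category = character(),
                                     group = character(), n = integer(),
                                     pct = numeric()),
                age = tibble(group = character(), n = integer(),
                             median = numeric(), q1 = numeric(), q3 = numeric())))
  }
  groups <- if (by == "cvae") {
    ifelse(cohort$is_cvae, "CVAE", "non-CVAE")
  } else {
    ifelse(cohort$is_fatal, "Fatal", "Non-fatal")
  }
  levels <- if (by == "cvae") c("CVAE", "non-CVAE") else c("Fatal", "Non-fatal")
  sex_vals <- c(M = "Male", `F` = "Female", missing = "Missing")[cohort$sex]
  country <- cohort$country
  top <- names(sort(table(country[nzchar(country)]), decreasing = TRUE))
  top <- head(top, top_countries)
  country_cat <- ifelse(country %in% top, country,
                        ifelse(nzchar(country), "Other", "Missing"))
  year_cat <- ifelse(is.na(cohort$year), "Missing", as.character(cohort$year))
  cat_tbl <- bind_rows(
    summary_block(unname(sex_vals), groups, levels, "Gender"),
    summary_block(country_cat, groups, levels, "Country"),
    summary_block(year_cat, groups, levels, "Received year"),
    summary_block(tools::toTitleCase(cohort$reporter), groups, levels,
                  "Reporter type")
  )
  age_tbl <- bind_rows(lapply(c(levels, "Total"), function(g) {
    a <- if (g == "Total") cohort$age_years else cohort$age_years[groups == g]
    a <- a[!is.na(a)]
    q <- if (length(a)) quantile(a, c(.25, .5, .75), type = 7, names = FALSE)
         else rep(NA_real_, 3)
    tibble(group = g, n = length(a), median = q[2], q1 = q[1], q3 = q[3])
  }))
  list(categorical = cat_tbl, age = age_tbl)
}
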