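round_numeric <- function(df, digits = 4) {
  df[] <- lapply(df, function(x) if (is.numeric(x)) round(x, digits) else x)
  df
}

list_quarter_tags <- function(dir) {
  f <- list.files(dir, pattern = "^DEMO.+\\.txt$")
  sub("^DEMO(.+)\\.txt$", "\\1", f)
}

#' Run the full pharmacovigilance pipeline
#'
#' Orchestrates ingest, deduplication/deletion, cohort labeling, ROR signal
#' screening, time-to-onset contrasts, CRS-overlap/mortality tabulation and
#' the two-stage logistic risk-factor analysis, writing plain CSV/JSON
#' stage outputs plus a machine-readable `summary.json` and a `MANIFEST` of
#' completed stages.  Outputs are deterministic for identical inputs (no
#' timestamps), so reruns are byte-identical.
#'
#' @param input A `faers_bundle`, or a directory of quarter files named
#'   `<TABLE><yy>Q<q>.txt` (all quarters found are merged).
#' @param out_dir Output directory (created if needed).
#' @param pt_map,atc_map Mapping tibbles (see [read_pt_map()],
#'   [read_atc_map()]).
#' @param synonyms Target-drug synonyms.
#' @param comparator `"all"` (default) or `"pediatric"`.
#' @param zero_correction Haldane-Anscombe correction in the ROR stage.
#' @param roles Optional DRUG role codes counted for target identification.
#' @param verbose Log stage progress to stderr.
#' @return Invisible list of the in-memory stage results.
#' @export
run_faers_pipeline <- function(input, out_dir,
                               pt_map = default_pt_map(),
                               atc_map = default_atc_map(),
                               synonyms = target_drug_synonyms,
                               comparator = c("all", "pediatric"),
                               zero_correction = FALSE,
                               roles = NULL, verbose = TRUE) {
  comparator <- match.arg(comparator)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  note_stage <- function(s) {
    manifest <<- c(manifest, s)
    writeLines(manifest, file.path(out_dir, "MANIFEST"))
    vlog(verbose, "stage done: ", s)
  }
  res <- list()

  # ingest
  bundle <- if (inherits(input, "faers_bundle")) input else {
    tags <- list_quarter_tags(input)
    if (!length(tags)) stop("no quarter files found in ", input, call. = FALSE)
    merge_quarters(lapply(sort(tags), function(tg) read_quarter(input, tg)))
  }
  note_stage("ingest")

  refined <- refine_bundle(bundle)
  res$refine <- attr(refined, "refine_summary")
  note_stage("dedup")

  lab <- label_reports(refined, pt_map, atc_map, synonyms, roles)
  cohort <- build_cohort(lab$labels)
  comp <- comparator_reports(lab$labels, comparator)
  utils::write.csv(round_numeric(cohort), file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  res$cohort <- cohort
  note_stage("cohort")

  cohort_reac <- lab$reac[lab$reac$primaryid %in% cohort$primaryid, ,
                          drop = FALSE]
  comp_reac <- lab$reac[lab$reac$primaryid %in% comp$primaryid, ,
                        drop = FALSE]
  pts <- cardiovascular_pts(cohort_reac)
  signals <- screen_signals(cohort_reac, comp_reac,
                            nrow(cohort), nrow(comp), pts = pts,
                            zero_correction = zero_correction)
  utils::write.csv(round_numeric(signals), file.path(out_dir, "signals.csv"),
                   row.names = FALSE)
  res$signals <- signals
  note_stage("signal")

  tto <- compute_tto(refined, synonyms, roles)
  ctto <- tto$days[match(cohort$primaryid, tto$primaryid)]
  tto_out <- list()
  if (sum(!is.na(ctto) & cohort$is_cvae) > 0 &&
      sum(!is.na(ctto) & !cohort$is_cvae) > 0) {
    cmp1 <- tto_compare(ctto, cohort$is_cvae, c("CVAE", "non-CVAE"))
    tto_out$cvae_vs_non_cvae <- list(summary = cmp1$summary, test = cmp1$test)
  }
  cv <- cohort$is_cvae
  if (sum(!is.na(ctto[cv]) & cohort$is_fatal[cv]) > 0 &&
      sum(!is.na(ctto[cv]) & !cohort$is_fatal[cv]) > 0) {
    cmp2 <- tto_compare(ctto[cv], cohort$is_fatal[cv],
                        c("Fatal CVAE", "Non-fatal CVAE"))
    tto_out$fatal_vs_non_fatal <- list(summary = cmp2$summary,
                                       test = cmp2$test)
  }
  jsonlite::write_json(tto_out, file.path(out_dir, "tto.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  res$tto <- tto_out
  note_stage("tto")

  ov <- overlap_table(cohort, cohort_reac, pts = pts)
  utils::write.csv(round_numeric(ov), file.path(out_dir, "overlap.csv"),
                   row.names = FALSE)
  res$overlap <- ov
  note_stage("overlap")

  reg <- list()
  for (oc in c("cvae", "fatal_within_cvae")) {
    fn <- file.path(out_dir, sprintf("regression_%s.csv",
                                     if (oc == "cvae") "cvae" else "fatal"))
    tab <- tryCatch({
      design <- build_design(cohort, lab$atc_flags, oc)
      two_stage_regression(design)
    }, error = function(e) {
      vlog(verbose, "regression (", oc, ") skipped: ", conditionMessage(e))
      tibble(variable = character(), stage = character(), note = character())
    })
    utils::write.csv(round_numeric(tab), fn, row.names = FALSE)
    reg[[oc]] <- tab
  }
  res$regression <- reg
  note_stage("regress")

  ovw <- cohort_overview(cohort)
  summary <- c(
    list(package_version = as.character(utils::packageVersion("faersignal")),
         comparator_scope = comparator,
         n_comparator = nrow(comp),
         n_signals = sum(signals$is_signal),
         n_unmapped_pts = attr(lab$labels, "n_unmapped_pts"),
         tto_exclusions = as.list(attr(tto, "exclusions"))),
    res$refine, ovw
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  note_stage("report")
  invisible(res)
}

#' Read a pipeline run configuration from a YAML key-value file
#'
#' Recognized keys: `input`, `out_dir`, `ptmap`, `atcmap`, `synonyms`,
#' `comparator`, `zero_correction`, `roles`.  Paths are resolved relative
#' to the config file's directory.
#'
#' @param path YAML file path.
#' @return Named list of arguments for [run_faers_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (!is.null(p) && !startsWith(p, "/")) file.path(base, p) else p
  args <- list(input = rel(cfg$input), out_dir = rel(cfg$out_dir))
  if (!is.null(cfg$ptmap)) args$pt_map <- read_pt_map(rel(cfg$ptmap))
  if (!is.null(cfg$atcmap)) args$atc_map <- read_atc_map(rel(cfg$atcmap))
  if (!is.null(cfg$synonyms)) args$synonyms <- cfg$synonyms
  if (!is.null(cfg$comparator)) args$comparator <- cfg$comparator
  if (!is.null(cfg$zero_correction)) args$zero_correction <- cfg$zero_correction
  if (!is.null(cfg$roles)) args$roles <- cfg$roles
  args
}
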