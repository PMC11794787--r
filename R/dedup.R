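#' Deduplicate DEMO rows across quarters
#'
#' Spontaneous reports are versioned: one CASEID may appear under several
#' PRIMARYIDs as follow-up information arrives.  Following the FDA-endorsed
#' procedure, for each CASEID the row with the highest FDA_DT is retained;
#' ties on FDA_DT are broken by the highest PRIMARYID.  Rows whose CASEID or
#' PRIMARYID does not parse as a positive integer are excluded and counted.
#' Rows with an unparseable FDA_DT are kept but always lose ties (treated as
#' FDA_DT 0) rather than dropped, so some version of the case survives.
#'
#' The result is deterministic (sorted by CASEID) and independent of input
#' row order.
#'
#' @param demo Tibble of DEMO rows (character columns per [faers_schema]).
#' @return Tibble with exactly one row per valid CASEID, sorted by CASEID.
#'   Attributes: `"n_excluded"` (rows with unparseable key fields) and
#'   `"n_versions_removed"` (rows lost to deduplication).
#' @examples
#' demo <- tibble::tibble(
#'   primaryid = c("1", "2"), caseid = c("7", "7"),
#'   fda_dt = c("20220101", "20220301"), event_dt = "", age = "",
#'   age_cod = "", sex = "", occr_country = "", occp_cod = "")
#' deduplicate_reports(demo)$primaryid  # "2"
#' @export
deduplicate_reports <- function(demo) {
  caseid <- parse_positive_int(demo$caseid)
  primaryid <- parse_positive_int(demo$primaryid)
  fda <- suppressWarnings(as.numeric(demo$fda_dt))
  fda[!is.finite(fda) | !grepl("^[0-9]{8}$", trimws(demo$fda_dt))] <- 0
  valid <- !is.na(caseid) & !is.na(primaryid)
  n_excluded <- sum(!valid)
  if (n_excluded > 0L) {
    message("deduplicate_reports: excluded ", n_excluded,
            " row(s) with unparseable CASEID/PRIMARYID")
  }
  d <- demo[valid, , drop = FALSE]
  ord <- order(caseid[valid], fda[valid], primaryid[valid])
  d <- d[ord, , drop = FALSE]
  cid <- caseid[valid][ord]
  keep <- !duplicated(cid, fromLast = TRUE)
  out <- d[keep, , drop = FALSE]
  attr(out, "n_excluded") <- n_excluded
  attr(out, "n_versions_removed") <- sum(!keep)
  out
}

#' Remove rows whose CASEID appears on a deletion list
#'
#' Applied after deduplication, per the FDA procedure: quarters from 2019Q1
#' onward distribute CASEID rosters of reports to expunge.
#'
#' @param rows Tibble with a character `caseid` column.
#' @param deleted Vector of CASEIDs to remove.
#' @return `rows` without the deleted cases; the removal count is attached
#'   as attribute `"n_deleted"`.
#' @export
apply_deletions <- function(rows, deleted) {
  cid <- parse_positive_int(rows$caseid)
  drop <- !is.na(cid) & cid %in% deleted
  out <- rows[!drop, , drop = FALSE]
  attr(out, "n_deleted") <- sum(drop)
  out
}

#' Deduplicate a bundle and apply its deletion list
#'
#' The composed refinement used by the pipeline: (1) deduplicate DEMO across
#' all rows in the bundle, (2) expunge deletion-listed CASEIDs, (3) filter
#' the child tables (DRUG/REAC/OUTC/THER) to the surviving PRIMARYIDs so
#' reports stay coherent.
#'
#' @param bundle A `faers_bundle` (possibly merged across quarters).
#' @return A `faers_bundle` of surviving rows; attribute `"refine_summary"`
#'   holds the counts `input_rows`, `unique_cases`, `deleted`, `output_rows`.
#' @export
refine_bundle <- function(bundle) {
  demo0 <- bundle$demo
  dd <- deduplicate_reports(demo0)
  dd2 <- apply_deletions(dd, bundle$deleted_caseids)
  keep_ids <- unique(dd2$primaryid)
  trim <- function(tb) tb[tb$primaryid %in% keep_ids, , drop = FALSE]
  out <- structure(
    list(demo = as_tibble(dd2),
         drug = trim(bundle$drug), reac = trim(bundle$reac),
         outc = trim(bundle$outc), ther = trim(bundle$ther),
         deleted_caseids = bundle$deleted_caseids,
         dropped = c(drug = 0L, reac = 0L, outc = 0L, ther = 0L)),
    class = "faers_bundle"
  )
  attr(out, "refine_summary") <- list(
    input_rows = nrow(demo0),
    unique_cases = nrow(dd),
    deleted = attr(dd2, "n_deleted"),
    output_rows = nrow(dd2)
  )
  out
}
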