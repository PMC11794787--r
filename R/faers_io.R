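#' Column schemas for the supported FAERS quarterly tables
#'
#' The quarterly ASCII extracts ship one "$"-delimited file per table.  Only
#' the columns the downstream analysis touches are declared here; extra
#' columns present in real files are ignored by name when reading.  All
#' values are kept as strings at this layer because FAERS ages and dates are
#' dirty; typing happens downstream.
#'
#' @format A named list of character vectors (one per table: DEMO, DRUG,
#'   REAC, OUTC, THER).
#' @export
faers_schema <- list(
  DEMO = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occr_country", "occp_cod"),
  DRUG = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "prod_ai"),
  REAC = c("primaryid", "caseid", "pt"),
  OUTC = c("primaryid", "caseid", "outc_cod"),
  THER = c("primaryid", "caseid", "dsg_drug_seq", "start_dt")
)

# Split "$"-delimited lines preserving trailing empty fields.
split_delim <- function(lines, delim) {
  parts <- strsplit(paste0(lines, delim, "\x01"), delim, fixed = TRUE)
  lapply(parts, function(p) p[-length(p)])
}

#' Read one FAERS-style ASCII table
#'
#' Parses a header-led, delimiter-separated text file into a tibble of
#' character columns following [faers_schema].  Data lines whose field count
#' disagrees with the header are skipped and counted, never fatal.  Header
#' columns not in the schema are dropped; schema columns missing from the
#' header come back as empty strings (with a warning).
#'
#' @param file Path to the file (or a connection readable by `readLines()`).
#' @param table Table name, one of `names(faers_schema)`.
#' @param delim Field delimiter; FAERS convention is `"$"`.
#' @return A tibble with the schema's columns, all character.  The number of
#'   skipped malformed lines is attached as attribute `"skipped"`.
#' @examples
#' tf <- tempfile()
#' writeLines(c("primaryid$caseid$pt", "1001$11$Hypotension"), tf)
#' read_faers_table(tf, "REAC")
#' @export
read_faers_table <- function(file, table, delim = "$") {
  if (!table %in% names(faers_schema)) {
    stop("unknown table name: ", table, call. = FALSE)
  }
  schema <- faers_schema[[table]]
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("empty stream: no header line for table ", table, call. = FALSE)
  }
  header <- tolower(trimws(split_delim(lines[1], delim)[[1]]))
  body <- lines[-1]
  skipped <- 0L
  if (length(body)) {
    parts <- split_delim(body, delim)
    ok <- lengths(parts) == length(header)
    skipped <- sum(!ok)
    if (skipped > 0L) {
      warning(sprintf("%s: skipped %d line(s) with field count != %d",
                      table, skipped, length(header)), call. = FALSE)
    }
    parts <- parts[ok]
  } else {
    parts <- list()
  }
  if (length(parts)) {
    m <- matrix(unlist(parts, use.names = FALSE),
                ncol = length(header), byrow = TRUE)
    df <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE),
                    .name_repair = "minimal")
    names(df) <- header
  } else {
    df <- as_tibble(setNames(rep(list(character(0)), length(header)), header),
                    .name_repair = "minimal")
  }
  missing_cols <- setdiff(schema, header)
  if (length(missing_cols)) {
    warning(sprintf("%s: columns absent from header, filled empty: %s",
                    table, paste(missing_cols, collapse = ", ")),
            call. = FALSE)
    for (mc in missing_cols) df[[mc]] <- rep("", nrow(df))
  }
  out <- df[, schema]
  attr(out, "skipped") <- skipped
  out
}

#' Write one FAERS-style ASCII table
#'
#' Inverse of [read_faers_table()]: emits a header of the schema columns and
#' one delimiter-joined line per row.  Round trips with the reader.
#'
#' @param rows Tibble/data.frame with the table's schema columns.
#' @param file Output path.
#' @param table Table name, one of `names(faers_schema)`.
#' @param delim Field delimiter.
#' @return `file`, invisibly.
#' @export
write_faers_table <- function(rows, file, table, delim = "$") {
  if (!table %in% names(faers_schema)) {
    stop("unknown table name: ", table, call. = FALSE)
  }
  schema <- faers_schema[[table]]
  miss <- setdiff(schema, names(rows))
  if (length(miss)) {
    stop("missing columns for ", table, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cols <- lapply(rows[schema], as.character)
  body <- do.call(paste, c(cols, sep = delim))
  writeLines(c(paste(schema, collapse = delim), body), file)
  invisible(file)
}

#' Read a deletion report log
#'
#' FAERS quarters from 2019Q1 onward ship a list of CASEIDs to be removed
#' after deduplication, one per line.  Blank lines are ignored; non-numeric
#' lines are skipped with a warning.
#'
#' @param file Path or connection.
#' @return Sorted vector of distinct CASEIDs (numeric).
#' @export
read_deletion_list <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  ids <- parse_positive_int(lines)
  bad <- sum(is.na(ids))
  if (bad > 0L) {
    warning(sprintf("deletion list: skipped %d non-numeric line(s)", bad),
            call. = FALSE)
  }
  sort(unique(ids[!is.na(ids)]))
}

#' Assemble per-table rows into a referentially consistent quarter bundle
#'
#' Child-table rows (DRUG/REAC/OUTC/THER) whose PRIMARYID does not appear in
#' DEMO are dropped with a logged count; this mirrors the validation a
#' careful FAERS ingest applies before analysis.
#'
#' @param demo,drug,reac,outc,ther Tibbles as returned by
#'   [read_faers_table()].
#' @param deleted_caseids Vector of CASEIDs slated for deletion (may be
#'   empty).
#' @return A `faers_bundle`: a list with elements `demo`, `drug`, `reac`,
#'   `outc`, `ther`, `deleted_caseids` and a `dropped` count vector.
#' @export
assemble_quarter <- function(demo, drug, reac, outc, ther,
                             deleted_caseids = numeric(0)) {
  keep_ids <- unique(demo$primaryid)
  trim_child <- function(tb) {
    ok <- tb$primaryid %in% keep_ids
    list(rows = tb[ok, , drop = FALSE], dropped = sum(!ok))
  }
  d <- trim_child(drug); r <- trim_child(reac)
  o <- trim_child(outc); t <- trim_child(ther)
  dropped <- c(drug = d$dropped, reac = r$dropped,
               outc = o$dropped, ther = t$dropped)
  if (sum(dropped) > 0L) {
    message("assemble_quarter: dropped orphan child rows: ",
            paste(names(dropped), dropped, sep = "=", collapse = ", "))
  }
  structure(
    list(demo = as_tibble(demo), drug = d$rows, reac = r$rows,
         outc = o$rows, ther = t$rows,
         deleted_caseids = sort(unique(deleted_caseids)),
         dropped = dropped),
    class = "faers_bundle"
  )
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("<faers_bundle>\n")
  for (tb in c("demo", "drug", "reac", "outc", "ther")) {
    cat(sprintf("  %s: %d rows\n", toupper(tb), nrow(x[[tb]])))
  }
  cat(sprintf("  deletion list: %d caseid(s)\n", length(x$deleted_caseids)))
  invisible(x)
}

#' Merge several quarter bundles into one
#'
#' Concatenates the five tables and unions the deletion lists, preserving
#' quarter order.  Used before cross-quarter deduplication.
#'
#' @param bundles List of `faers_bundle` objects.
#' @return One `faers_bundle`.
#' @export
merge_quarters <- function(bundles) {
  stopifnot(length(bundles) >= 1L)
  pick <- function(tb) bind_rows(lapply(bundles, `[[`, tb))
  assemble_quarter(pick("demo"), pick("drug"), pick("reac"),
                   pick("outc"), pick("ther"),
                   deleted_caseids =
                     sort(unique(unlist(lapply(bundles, `[[`,
                                               "deleted_caseids")))))
}

quarter_file <- function(dir, table, quarter) {
  file.path(dir, sprintf("%s%s.txt", table, quarter))
}

#' Read a full quarter from a directory
#'
#' Expects files named `<TABLE><yy>Q<q>.txt` (e.g. `DEMO23Q1.txt`) plus an
#' optional deletion list `DELETED<yy>Q<q>.txt`.
#'
#' @param dir Directory holding the quarter's files.
#' @param quarter Quarter tag such as `"23Q1"`.
#' @param delim Field delimiter.
#' @return A `faers_bundle`.
#' @export
read_quarter <- function(dir, quarter, delim = "$") {
  tabs <- lapply(names(faers_schema), function(tb) {
    read_faers_table(quarter_file(dir, tb, quarter), tb, delim)
  })
  names(tabs) <- tolower(names(faers_schema))
  del_file <- quarter_file(dir, "DELETED", quarter)
  del <- if (file.exists(del_file)) read_deletion_list(del_file) else numeric(0)
  assemble_quarter(tabs$demo, tabs$drug, tabs$reac, tabs$outc, tabs$ther, del)
}

#' Write a quarter bundle to a directory
#'
#' @param bundle A `faers_bundle`.
#' @param dir Output directory (created if absent).
#' @param quarter Quarter tag such as `"23Q1"`.
#' @param delim Field delimiter.
#' @return `dir`, invisibly.
#' @export
write_quarter <- function(bundle, dir, quarter, delim = "$") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in names(faers_schema)) {
    write_faers_table(bundle[[tolower(tb)]],
                      quarter_file(dir, tb, quarter), tb, delim)
  }
  writeLines(as.character(bundle$deleted_caseids),
             quarter_file(dir, "DELETED", quarter))
  invisible(dir)
}
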