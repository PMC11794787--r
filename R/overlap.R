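#' Per-PT CRS overlap and mortality among cohort reports
#'
#' For each preferred term, restricted to cohort reports mentioning it:
#' how many also report cytokine release syndrome, and how many were fatal.
#' PTs with no cohort reports are omitted.
#'
#' @param cohort Labeled cohort tibble (needs `primaryid`, `has_crs`,
#'   `is_fatal`).
#' @param cohort_reac Long tibble `primaryid`, `pt` restricted to (or
#'   filterable by) the cohort.
#' @param pts PTs to tabulate; default: all PTs observed in the cohort.
#' @return Tibble `pt`, `n_pt`, `n_crs_overlap`, `overlap_rate`, `n_fatal`,
#'   `mortality_rate` (rates as fractions in `[0, 1]`).
#' @export
overlap_table <- function(cohort, cohort_reac, pts = NULL) {
  reac <- distinct(tibble(primaryid = cohort_reac$primaryid,
                          pt = trimws(cohort_reac$pt)))
  reac <- reac[reac$primaryid %in% cohort$primaryid, , drop = FALSE]
  if (is.null(pts)) pts <- sort(unique(reac$pt[nzchar(reac$pt)]))
  idx <- match(reac$primaryid, cohort$primaryid)
  reac$has_crs <- cohort$has_crs[idx]
  reac$is_fatal <- cohort$is_fatal[idx]
  rows <- lapply(pts, function(p) {
    sel <- reac[tolower(reac$pt) == tolower(p), , drop = FALSE]
    n <- nrow(sel)
    if (n == 0L) return(NULL)
    tibble(pt = p, n_pt = n,
           n_crs_overlap = sum(sel$has_crs),
           overlap_rate = sum(sel$has_crs) / n,
           n_fatal = sum(sel$is_fatal),
           mortality_rate = sum(sel$is_fatal) / n)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(pt = character(), n_pt = integer(),
                  n_crs_overlap = integer(), overlap_rate = numeric(),
                  n_fatal = integer(), mortality_rate = numeric())
  }
  arrange(out, desc(.data$n_pt), .data$pt)
}

as_2x2 <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0) || any(m != floor(m))) {
    stop("need a 2x2 table of nonnegative integer counts", call. = FALSE)
  }
  m
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities (margins
#' fixed) of all tables at most as probable as the observed one.  A zero
#' margin gives p = 1.
#'
#' @param m 2x2 matrix of counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(3, 0, 0, 3), 2))  # 0.1
#' @export
fisher_exact <- function(m) {
  m <- as_2x2(m)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  fisher.test(m)$p.value
}

#' Pearson chi-square test without continuity correction
#'
#' @param m r x c matrix of counts with nonzero margins.
#' @param yates Apply Yates continuity correction (off by default).
#' @return List `statistic`, `df`, `p`.
#' @examples
#' chi_square(matrix(c(20, 10, 10, 20), 2))  # statistic 20/3
#' @export
chi_square <- function(m, yates = FALSE) {
  m <- as.matrix(m)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate margins", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(m, correct = yates))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Categorical association test with the small-expected-count dispatch rule
#'
#' Literal implementation of the reporting convention: if any expected cell
#' count is below 5 the table goes to Fisher's exact test (2x2 only),
#' otherwise to the Pearson chi-square test without continuity correction.
#'
#' @param m Matrix of counts.
#' @return List `p`, `method` (`"fisher"` or `"chi-square"`), and
#'   `statistic`/`df` when chi-square.
#' @export
assoc_test <- function(m) {
  m <- as.matrix(m)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    list(p = fisher_exact(m), method = "fisher")
  } else {
    ht <- chi_square(m)
    list(p = ht$p, method = "chi-square", statistic = ht$statistic,
         df = ht$df)
  }
}
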