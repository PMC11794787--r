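#' Build the 2x2 contingency table for one drug-event pair
#'
#' In the case/non-case design the table counts reports, with event presence
#' binary per report: `a` = cohort (target-drug) reports mentioning the PT,
#' `b` = cohort reports without it, `c`/`d` analogously on the comparator.
#'
#' @param cohort_reac Long tibble `primaryid`, `pt` of cohort reactions
#'   (distinct per report).
#' @param comparator_reac Same for the comparator population.
#' @param n_cohort,n_comparator Report counts of the two populations.
#' @param pt Preferred term (non-empty string; matched case-insensitively).
#' @return Named list `a`, `b`, `c`, `d`.
#' @export
contingency_table <- function(cohort_reac, comparator_reac,
                              n_cohort, n_comparator, pt) {
  if (!is.character(pt) || length(pt) != 1L || !nzchar(trimws(pt))) {
    stop("pt must be one non-empty string", call. = FALSE)
  }
  key <- tolower(trimws(pt))
  a <- length(unique(cohort_reac$primaryid[
    tolower(trimws(cohort_reac$pt)) == key]))
  c_ <- length(unique(comparator_reac$primaryid[
    tolower(trimws(comparator_reac$pt)) == key]))
  list(a = a, b = n_cohort - a, c = c_, d = n_comparator - c_)
}

#' Reporting odds ratio with a 95% Wald confidence interval
#'
#' ROR = (a d)/(b c); the interval is `exp(log ROR +/- 1.96 * sqrt(1/a +
#' 1/b + 1/c + 1/d))`.  With any zero cell the estimate is undefined
#' (`NA`) unless `zero_correction = TRUE`, in which case 0.5 is added to all
#' four cells (Haldane-Anscombe) and the result is flagged `corrected`.
#' Vectorized over the four cell arguments.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @param zero_correction Apply the +0.5 correction on zero cells?
#' @return Tibble with columns `ror`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' ror_estimate(10, 90, 100, 9900)  # ROR 11, CI about (5.56, 21.77)
#' @export
ror_estimate <- function(a, b, c, d, zero_correction = FALSE) {
  stopifnot(all(c(a, b, c, d) >= 0, na.rm = TRUE))
  zero <- (a == 0 | b == 0 | c == 0 | d == 0)
  corrected <- zero & zero_correction
  shift <- ifelse(corrected, 0.5, 0)
  aa <- a + shift; bb <- b + shift; cc <- c + shift; dd <- d + shift
  ok <- !zero | zero_correction
  ror <- ifelse(ok, (aa * dd) / (bb * cc), NA_real_)
  se <- ifelse(ok, sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd), NA_real_)
  tibble(ror = ror,
         ci_low = exp(log(ror) - 1.96 * se),
         ci_high = exp(log(ror) + 1.96 * se),
         corrected = corrected)
}

#' Screen preferred terms for disproportionality signals
#'
#' Computes one ROR row per PT and applies the signal rule: at least
#' `min_reports` target-drug reports of the PT and a lower 95% confidence
#' limit above 1.  Output is sorted signals-first by descending ROR, then by
#' report count.
#'
#' @param cohort_reac,comparator_reac Long tibbles `primaryid`, `pt`
#'   (distinct per report; see [label_reports()]).
#' @param n_cohort,n_comparator Population sizes (report counts).
#' @param pts PTs to screen; default: every PT observed in the cohort.
#' @param zero_correction Passed to [ror_estimate()].
#' @param min_reports Minimum `a`-cell count for a signal (default 3).
#' @return Tibble: `pt`, `n` (= a), `a`, `b`, `c`, `d`, `ror`, `ci_low`,
#'   `ci_high`, `corrected`, `is_signal`.
#' @export
screen_signals <- function(cohort_reac, comparator_reac,
                           n_cohort, n_comparator, pts = NULL,
                           zero_correction = FALSE, min_reports = 3L) {
  cr <- tibble(primaryid = cohort_reac$primaryid,
               pt = trimws(cohort_reac$pt))
  xr <- tibble(primaryid = comparator_reac$primaryid,
               pt = trimws(comparator_reac$pt))
  if (is.null(pts)) pts <- sort(unique(cr$pt[nzchar(cr$pt)]))
  if (length(pts) == 0L) {
    return(tibble(pt = character(), n = integer(), a = integer(),
                  b = integer(), c = integer(), d = integer(),
                  ror = numeric(), ci_low = numeric(), ci_high = numeric(),
                  corrected = logical(), is_signal = logical()))
  }
  key <- tolower(pts)
  a_tab <- table(factor(tolower(distinct(cr)$pt), levels = key))
  c_tab <- table(factor(tolower(distinct(xr)$pt), levels = key))
  a <- as.integer(a_tab); c_ <- as.integer(c_tab)
  b <- n_cohort - a; d <- n_comparator - c_
  est <- ror_estimate(a, b, c_, d, zero_correction)
  out <- tibble(pt = pts, n = a, a = a, b = b, c = c_, d = d,
                ror = est$ror, ci_low = est$ci_low, ci_high = est$ci_high,
                corrected = est$corrected)
  out$is_signal <- !is.na(out$ci_low) & out$n >= min_reports & out$ci_low > 1
  out <- out[out$a > 0, , drop = FALSE]  # PTs unreported in the cohort carry no row
  ord <- order(-out$is_signal,
               -ifelse(is.na(out$ror), -Inf, out$ror),
               -out$n)
  out[ord, , drop = FALSE]
}

#' PTs mapping to cardiovascular organ classes among cohort reactions
#'
#' Convenience default for [screen_signals()]: the distinct PTs observed in
#' the cohort whose SOC is cardiac or vascular.
#'
#' @param cohort_reac Long tibble `primaryid`, `pt`, `soc` (from
#'   [label_reports()]), already restricted to cohort reports.
#' @return Character vector of PTs.
#' @export
cardiovascular_pts <- function(cohort_reac) {
  sort(unique(cohort_reac$pt[!is.na(cohort_reac$soc) &
                               cohort_reac$soc %in% cardiovascular_socs]))
}
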