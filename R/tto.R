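#' Time to onset per report
#'
#' Days from the earliest therapy start of the target drug (THER.START_DT
#' joined through DSG_DRUG_SEQ to the target DRUG rows) to the event date
#' (DEMO.EVENT_DT).  Both dates must carry full YYYYMMDD precision; partial
#' dates and negative differences yield `NA` and are tallied in the
#' `"exclusions"` attribute rather than imputed.
#'
#' @param bundle A refined `faers_bundle`.
#' @param synonyms Target-drug synonyms.
#' @param roles Optional role codes for target identification.
#' @return Tibble `primaryid`, `days` (integer or NA); attribute
#'   `"exclusions"` counts `missing_event`, `missing_start`, `negative`.
#' @export
compute_tto <- function(bundle, synonyms = target_drug_synonyms,
                        roles = NULL) {
  drug <- bundle$drug
  target <- drug[match_target_drug(drug, synonyms, roles), , drop = FALSE]
  ther <- bundle$ther
  key_t <- paste(target$primaryid, trimws(target$drug_seq), sep = "\r")
  key_h <- paste(ther$primaryid, trimws(ther$dsg_drug_seq), sep = "\r")
  th <- ther[key_h %in% key_t, , drop = FALSE]
  th$start <- parse_faers_date(th$start_dt)
  th <- th[!is.na(th$start), , drop = FALSE]
  starts <- summarise(group_by(th, .data$primaryid),
                      start = min(.data$start), .groups = "drop")
  demo <- bundle$demo
  ev <- parse_faers_date(demo$event_dt)
  idx <- match(demo$primaryid, starts$primaryid)
  start <- starts$start[idx]
  days <- as.integer(ev - start)
  excl <- c(missing_event = sum(is.na(ev)),
            missing_start = sum(!is.na(ev) & is.na(start)),
            negative = sum(!is.na(days) & days < 0))
  days[!is.na(days) & days < 0] <- NA_integer_
  out <- tibble(primaryid = demo$primaryid, days = days)
  attr(out, "exclusions") <- excl
  out
}

#' Median and interquartile summary of onset times
#'
#' Linear-interpolation (type 7) quantiles on the sorted values.
#'
#' @param days Nonempty numeric vector of onset days (NAs dropped).
#' @return Tibble `n`, `median`, `q1`, `q3`.
#' @export
tto_summary <- function(days) {
  days <- days[!is.na(days)]
  if (length(days) == 0L) stop("no onset times to summarize", call. = FALSE)
  q <- quantile(days, c(.25, .5, .75), type = 7, names = FALSE)
  tibble(n = length(days), median = q[2], q1 = q[1], q3 = q[3])
}

#' Wilcoxon two-sample (rank-sum) comparison
#'
#' Two-sided test of a location shift between two groups of onset times.
#' With `n_x + n_y <= 20` and no ties the p-value is exact (enumeration of
#' rank assignments); otherwise a normal approximation with tie-corrected
#' variance and 0.5 continuity correction is used.  Degenerate input (all
#' values identical across both samples) returns p = 1.
#'
#' @param x,y Nonempty numeric vectors.
#' @return List `W` (rank-sum statistic of `x`, Mann-Whitney form),
#'   `p` (two-sided), `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_two_sample(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
wilcoxon_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  ties <- any(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1L) {
    return(list(W = length(x) * length(y) / 2, p = 1, method = "degenerate"))
  }
  exact <- (length(x) + length(y) <= 20L) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, conf.int = FALSE)
  )
  list(W = unname(ht$statistic), p = min(1, ht$p.value),
       method = if (exact) "exact" else "normal")
}

#' Group-wise onset comparison
#'
#' Convenience wrapper: summarizes onset per group and tests the two groups
#' with [wilcoxon_two_sample()].
#'
#' @param days Numeric vector of onset days (NA = unusable, excluded).
#' @param group Logical or two-level vector aligned with `days`.
#' @param labels Length-2 character names for the `TRUE`/first and
#'   `FALSE`/second group.
#' @return List `summary` (tibble with a `group` column) and `test`.
#' @export
tto_compare <- function(days, group, labels = c("group1", "group2")) {
  ok <- !is.na(days)
  days <- days[ok]; group <- group[ok]
  g <- if (is.logical(group)) group else group == group[1]
  x <- days[g]; y <- days[!g]
  s1 <- cbind(tibble(group = labels[1]), tto_summary(x))
  s2 <- cbind(tibble(group = labels[2]), tto_summary(y))
  list(summary = as_tibble(rbind(s1, s2)), test = wilcoxon_two_sample(x, y))
}
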