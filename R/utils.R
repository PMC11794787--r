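#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join distinct n bind_rows rename
#'   row_number desc across all_of if_else count
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile median glm binomial coef vcov pchisq pnorm rbinom
#'   runif rlnorm plogis qlogis t.test wilcox.test fisher.test chisq.test
#'   glm.control rnorm setNames
#' @importFrom utils head
NULL

# Integer parse that never warns: non-numeric or non-positive -> NA
parse_positive_int <- function(x) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  out[!is.finite(out) | out <= 0 | out != floor(out)] <- NA_real_
  out
}

# FAERS dates are YYYYMMDD integers; partial dates (YYYY or YYYYMM) and
# garbage come back NA.  Returns a Date vector.
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out <- rep(as.Date(NA), length(x))
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    out[full] <- d
  }
  out
}

# TRUE where the string is a structurally valid 8-digit date
is_full_date <- function(x) {
  !is.na(parse_faers_date(x))
}

vlog <- function(verbose, ...) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}
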