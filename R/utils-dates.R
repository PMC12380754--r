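# Partial dates travel as character strings in FAERS numeric form:
# "YYYYMMDD" (complete), "YYYYMM" (year-month), "YYYY" (year only),
# NA / "" (missing). Arithmetic is only defined for complete dates.

#' Test whether a partial date is complete (day-level)
#'
#' @param x character vector of dates in FAERS numeric form (`YYYYMMDD`,
#'   `YYYYMM`, `YYYY`, or `NA`).
#' @return logical vector: `TRUE` where the value has day-level resolution.
#' @examples
#' pd_complete(c("20230105", "202301", "2023", NA))
#' @export
pd_complete <- function(x) {
  x <- as.character(x)
  !is.na(x) & nchar(x) == 8L & grepl("^[0-9]{8}$", x)
}

#' Parse partial dates to `Date`
#'
#' Complete (`YYYYMMDD`) values parse to `Date`; partial or missing values
#' give `NA`. A complete value naming an impossible calendar day (for
#' example `20231345`) also gives `NA` and can be told apart from a partial
#' date via [pd_complete()].
#'
#' @inheritParams pd_complete
#' @return `Date` vector with `NA` for partial, missing or invalid values.
#' @export
pd_parse <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  ok <- pd_complete(x)
  if (any(ok)) out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

# Sortable numeric key: partial dates are right-padded with zeros so a
# year-only date sorts before any complete date in that year. NA -> NA.
pd_sort_key <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  n <- nchar(x)
  pad <- ifelse(is.na(x), NA_character_,
                paste0(x, strrep("0", pmax(0L, 8L - n))))
  suppressWarnings(as.numeric(pad))
}

# Format a Date as FAERS numeric-form character.
pd_format <- function(d) format(d, "%Y%m%d")

# Derive a child seed from the user seed, staying inside 32-bit range.
pv_seed <- function(seed, k = 0L) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647)
}

# Shared input check helpers ------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single number in [0, 1], got %s", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != trunc(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}
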