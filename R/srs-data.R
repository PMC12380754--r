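#' Relational container for raw spontaneous-report data
#'
#' An `srs_data` object mirrors the relational layout of a FAERS quarterly
#' extract: one demographics row per report version plus child tables for
#' drugs, reactions, therapy dates, outcomes and indications, all keyed by
#' `primaryid` (the report-version identifier). `caseid` groups versions of
#' the same case for deduplication.
#'
#' Dates are carried as character strings in FAERS numeric form
#' (`YYYYMMDD`, with `YYYYMM` / `YYYY` for partial dates); see
#' [pd_complete()].
#'
#' @param demo data frame with columns `primaryid`, `caseid`, `fda_dt`
#'   (receipt date), `event_dt`, `sex`, `age`, `age_cod`, `wt`, `wt_cod`,
#'   `reporter_country`, `occp_cod`. Missing columns are added as `NA`.
#' @param drug data frame with columns `primaryid`, `drug_seq`, `role_cod`
#'   (`PS`/`SS`/`C`/`I` or FAERS numeric codes), `drugname`.
#' @param reac data frame with columns `primaryid`, `pt`.
#' @param ther optional data frame with columns `primaryid`, `drug_seq`,
#'   `start_dt`.
#' @param outc optional data frame with columns `primaryid`, `outc_cod`.
#' @param indi optional data frame with columns `primaryid`, `indi_pt`.
#' @return an object of class `srs_data` (a named list of data frames).
#' @export
srs_data <- function(demo, drug, reac, ther = NULL, outc = NULL,
                     indi = NULL) {
  demo <- coerce_cols(demo, c("primaryid", "caseid", "fda_dt", "event_dt",
                              "sex", "age", "age_cod", "wt", "wt_cod",
                              "reporter_country", "occp_cod"),
                      num = c("age", "wt"))
  drug <- coerce_cols(drug, c("primaryid", "drug_seq", "role_cod",
                              "drugname"), num = "drug_seq")
  reac <- coerce_cols(reac, c("primaryid", "pt"))
  ther <- coerce_cols(empty_if_null(ther), c("primaryid", "drug_seq",
                                             "start_dt"), num = "drug_seq")
  outc <- coerce_cols(empty_if_null(outc), c("primaryid", "outc_cod"))
  indi <- coerce_cols(empty_if_null(indi), c("primaryid", "indi_pt"))
  if (anyDuplicated(demo$primaryid))
    stopf("duplicate primaryid in DEMO: %s",
          paste(head(demo$primaryid[duplicated(demo$primaryid)], 3),
                collapse = ", "))
  if (any(is.na(demo$caseid) | demo$caseid == ""))
    stopf("caseid must be non-empty for every report")
  structure(list(demo = demo, drug = drug, reac = reac, ther = ther,
                 outc = outc, indi = indi),
            class = "srs_data")
}

empty_if_null <- function(x) {
  if (is.null(x)) data.frame() else x
}

# Ensure the listed columns exist with canonical types (character except
# the named numeric columns); extra columns are preserved.
coerce_cols <- function(df, cols, num = character()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0L && length(df) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                 cols), stringsAsFactors = FALSE)
  }
  for (cl in cols) if (!cl %in% names(df)) df[[cl]] <- rep(NA, nrow(df))
  for (cl in cols) {
    if (cl %in% num) {
      df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
    } else {
      v <- as.character(df[[cl]])
      v[!is.na(v) & v == ""] <- NA_character_
      df[[cl]] <- v
    }
  }
  rownames(df) <- NULL
  df[cols]
}

#' @export
print.srs_data <- function(x, ...) {
  cat(sprintf(
    "<srs_data> %d report versions (%d cases), %d drug rows, %d reactions\n",
    nrow(x$demo), length(unique(x$demo$caseid)), nrow(x$drug),
    nrow(x$reac)))
  invisible(x)
}

#' Number of report versions in an `srs_data` object
#' @param x an `srs_data` object.
#' @return integer count of demographics rows.
#' @export
n_reports <- function(x) nrow(x$demo)
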