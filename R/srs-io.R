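# Table name <-> file naming for the two supported dialects.
FAERS_TABLES <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
                  ther = "THER", outc = "OUTC", indi = "INDI")

#' Write a spontaneous-report database to disk
#'
#' The `faers_ascii` dialect emits one `$`-delimited table per file
#' (`DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`, `OUTC.txt`,
#' `INDI.txt`) with a header row, matching the layout of FAERS quarterly
#' ASCII extracts. The `generic_csv` dialect emits one RFC-4180 CSV per
#' table (`demo.csv`, ...) keyed by a report-identifier column.
#' Reading the files back with [read_faers_quarter()] or
#' [read_generic_csv()] reproduces the input field for field.
#'
#' @param x an [srs_data()] object or a `synthetic_cohort`.
#' @param dir output directory, created if absent.
#' @param dialect `"faers_ascii"` or `"generic_csv"`.
#' @param key_column key column name used by the generic dialect.
#' @return invisibly, the named character vector of written file paths.
#' @export
write_srs <- function(x, dir, dialect = c("faers_ascii", "generic_csv"),
                      key_column = "report_id") {
  if (inherits(x, "synthetic_cohort")) x <- x$data
  stopifnot(inherits(x, "srs_data"))
  dialect <- match.arg(dialect)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", dir)
  paths <- character(0)
  for (tb in names(FAERS_TABLES)) {
    df <- x[[tb]]
    if (dialect == "faers_ascii") {
      path <- file.path(dir, paste0(FAERS_TABLES[[tb]], ".txt"))
      con <- file(path, "w")
      writeLines(paste(names(df), collapse = "$"), con)
      if (nrow(df)) {
        cells <- vapply(df, function(v) {
          v <- as.character(v); v[is.na(v)] <- ""; v
        }, character(nrow(df)))
        cells <- matrix(cells, nrow = nrow(df))
        writeLines(apply(cells, 1, paste, collapse = "$"), con)
      }
      close(con)
    } else {
      path <- file.path(dir, paste0(tb, ".csv"))
      names(df)[names(df) == "primaryid"] <- key_column
      utils::write.csv(df, path, row.names = FALSE, na = "")
    }
    paths[[tb]] <- path
  }
  invisible(paths)
}

#' Read a FAERS-style quarterly ASCII file set
#'
#' Parses `$`-delimited tables with a header row. `DEMO`, `DRUG` and
#' `REAC` are mandatory; `THER`, `OUTC` and `INDI` are optional. Data
#' lines whose field count disagrees with the header are skipped and
#' counted, not fatal; the per-table skip counts are attached as attribute
#' `"skipped"`.
#'
#' @param dir directory containing the files, or a named character vector
#'   of paths (names among `demo`, `drug`, `reac`, `ther`, `outc`,
#'   `indi`).
#' @return an [srs_data()] object with attribute `skipped` (named integer
#'   vector of malformed-row counts per table).
#' @export
read_faers_quarter <- function(dir) {
  paths <- locate_tables(dir, faers = TRUE)
  for (tb in c("demo", "drug", "reac")) {
    if (is.na(paths[[tb]]))
      stopf("mandatory table %s not found in '%s'", FAERS_TABLES[[tb]],
            paste(dir, collapse = ", "))
  }
  skipped <- integer(0)
  tabs <- list()
  for (tb in names(FAERS_TABLES)) {
    if (is.na(paths[[tb]])) next
    parsed <- parse_dollar_file(paths[[tb]])
    tabs[[tb]] <- parsed$df
    skipped[[tb]] <- parsed$skipped
  }
  out <- srs_data(tabs$demo, tabs$drug, tabs$reac, tabs$ther, tabs$outc,
                  tabs$indi)
  attr(out, "skipped") <- skipped
  out
}

parse_dollar_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stopf("empty table file '%s'", path)
  header <- strsplit(lines[[1]], "$", fixed = TRUE)[[1]]
  if (length(header) < 1L || any(header == ""))
    stopf("malformed header in '%s': '%s'", path, lines[[1]])
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "$", fixed = TRUE)
  # the field count is separator count + 1 ($ cannot occur inside a
  # field in this dialect); strsplit drops trailing empties, so pad
  nf <- nchar(body) - nchar(gsub("$", "", body, fixed = TRUE)) + 1L
  ok <- nf == length(header)
  cols <- lapply(seq_along(header), function(j) {
    vapply(fields[ok], function(f) {
      if (j <= length(f)) f[[j]] else ""
    }, character(1))
  })
  df <- as.data.frame(setNames(cols, header), stringsAsFactors = FALSE,
                      check.names = FALSE)
  list(df = df, skipped = sum(!ok))
}

#' Read a generic one-row-per-record CSV file set
#'
#' Reads per-table CSVs (demographics, drugs, reactions, optional therapy,
#' outcome and indication tables), drops exact-duplicate rows within each
#' table before joining, and assembles the tables on the shared report
#' key. The resulting case set is the union of keys across tables;
#' demographics rows absent for a key are filled with `NA`.
#'
#' @param dir directory containing `demo.csv`, `drug.csv`, `reac.csv` and
#'   optionally `ther.csv`, `outc.csv`, `indi.csv`, or a named character
#'   vector of paths.
#' @param key_column name of the report-identifier column present in every
#'   file.
#' @return an [srs_data()] object.
#' @export
read_generic_csv <- function(dir, key_column = "report_id") {
  paths <- locate_tables(dir, faers = FALSE)
  for (tb in c("demo", "drug", "reac")) {
    if (is.na(paths[[tb]]))
      stopf("mandatory table %s.csv not found in '%s'", tb,
            paste(dir, collapse = ", "))
  }
  tabs <- list()
  for (tb in names(FAERS_TABLES)) {
    if (is.na(paths[[tb]])) next
    df <- utils::read.csv(paths[[tb]], colClasses = "character",
                          check.names = FALSE)
    if (!key_column %in% names(df))
      stopf("key column '%s' missing from '%s'", key_column, paths[[tb]])
    df <- df[!duplicated(df), , drop = FALSE]
    names(df)[names(df) == key_column] <- "primaryid"
    tabs[[tb]] <- df
  }
  keys <- unique(unlist(lapply(tabs, `[[`, "primaryid")))
  missing_demo <- setdiff(keys, tabs$demo$primaryid)
  if (length(missing_demo)) {
    extra <- data.frame(primaryid = missing_demo)
    extra$caseid <- missing_demo
    tabs$demo <- merge(tabs$demo, extra, all = TRUE, sort = FALSE)
  }
  if (!"caseid" %in% names(tabs$demo) ||
      all(is.na(tabs$demo$caseid)))
    tabs$demo$caseid <- tabs$demo$primaryid
  tabs$demo$caseid[is.na(tabs$demo$caseid)] <-
    tabs$demo$primaryid[is.na(tabs$demo$caseid)]
  srs_data(tabs$demo, tabs$drug, tabs$reac, tabs$ther, tabs$outc,
           tabs$indi)
}

locate_tables <- function(dir, faers) {
  out <- setNames(rep(NA_character_, length(FAERS_TABLES)),
                  names(FAERS_TABLES))
  if (length(dir) == 1L && dir.exists(dir)) {
    files <- list.files(dir, full.names = TRUE)
    for (tb in names(FAERS_TABLES)) {
      pat <- paste0("^", if (faers) FAERS_TABLES[[tb]] else tb,
                    "[^/]*\\.(txt|csv)$")
      hit <- files[grepl(pat, basename(files), ignore.case = TRUE)]
      if (length(hit)) out[[tb]] <- hit[[1]]
    }
  } else {
    if (is.null(names(dir)))
      stopf("'%s' is not a directory; pass a named vector of paths", dir)
    for (tb in intersect(names(dir), names(out))) out[[tb]] <- dir[[tb]]
  }
  out
}

#' Deduplicate report versions to one record per case
#'
#' Applies the published FDA guidance for FAERS case deduplication: among
#' versions sharing a `caseid`, keep the one with the latest receipt date
#' (`fda_dt`); ties are broken by the numerically larger `primaryid`.
#' The removed versions are reported in the attached log.
#'
#' @param x an [srs_data()] object.
#' @return the deduplicated `srs_data`, with attributes `n_removed`
#'   (count) and `dedup_log` (data frame of removed `primaryid` /
#'   `caseid`). Idempotent.
#' @export
deduplicate <- function(x) {
  stopifnot(inherits(x, "srs_data"))
  demo <- x$demo
  if (nrow(demo) == 0L) {
    attr(x, "n_removed") <- 0L
    return(x)
  }
  key_date <- pd_sort_key(demo$fda_dt)
  key_date[is.na(key_date)] <- -Inf
  key_id <- suppressWarnings(as.numeric(demo$primaryid))
  key_id[is.na(key_id)] <- -Inf
  ord <- order(demo$caseid, -key_date, -key_id)
  keep_first <- !duplicated(demo$caseid[ord])
  keep_ids <- demo$primaryid[ord][keep_first]
  removed <- demo[!demo$primaryid %in% keep_ids, c("primaryid", "caseid")]
  out <- subset_srs(x, keep_ids)
  attr(out, "n_removed") <- nrow(removed)
  attr(out, "dedup_log") <- removed
  out
}

subset_srs <- function(x, primaryids) {
  for (tb in names(FAERS_TABLES)) {
    x[[tb]] <- x[[tb]][x[[tb]]$primaryid %in% primaryids, , drop = FALSE]
    rownames(x[[tb]]) <- NULL
  }
  x
}
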