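#' Build 2x2 contingency tables for drug-event pairs
#'
#' For every distinct event label (preferred term or system organ class)
#' with at least one co-report with the target drug, builds the standard
#' 2x2 table against the rest of the database: `a` reports with target
#' drug and the event, `b` target drug and other events, `c` other drugs
#' and the event, `d` neither. Under the default report-level counting a
#' report contributes at most once per label and once to the drug margin,
#' so `a + b + c + d = N` (the number of reports in the database view).
#' With `counting = "pairs"` the counting unit is the report x label pair
#' (a report with three PTs contributes three times), in which case the
#' margins count pairs rather than reports.
#'
#' @param clean a `clean_reports` object covering the *whole* database
#'   view (target and comparator reports); for SOC level, annotate first
#'   with [map_pt_to_soc()].
#' @param drug_names character vector of target drug names.
#' @param level `"PT"` or `"SOC"`.
#' @param role_values drug roles defining the target margin (default
#'   primary suspect); `NULL` accepts any role.
#' @param counting `"reports"` (default) or `"pairs"`.
#' @return data frame with columns `level`, `label`, `a`, `b`, `c`, `d`,
#'   `N`, sorted by decreasing `a`; only labels with `a >= 1` appear.
#' @export
build_tables <- function(clean, drug_names, level = c("PT", "SOC"),
                         role_values = "PS",
                         counting = c("reports", "pairs")) {
  stopifnot(inherits(clean, "clean_reports"))
  level <- match.arg(level)
  counting <- match.arg(counting)
  if (nrow(clean$reports) == 0L) stopf("empty database")
  lab <- label_rows(clean, level, counting)
  targets <- target_report_ids(clean, drug_names, role_values)
  if (counting == "reports") {
    N <- nrow(clean$reports)
    n_drug <- sum(clean$reports$report_id %in% targets)
  } else {
    N <- nrow(lab)
    n_drug <- sum(lab$report_id %in% targets)
  }
  is_target <- lab$report_id %in% targets
  a_tab <- table(lab$label[is_target])
  evt_tab <- table(lab$label)
  labels <- names(a_tab)[a_tab >= 1]
  a <- as.numeric(a_tab[labels])
  evt <- as.numeric(evt_tab[labels])
  out <- data.frame(level = level, label = labels, a = a,
                    b = n_drug - a, c = evt - a,
                    d = N - n_drug - (evt - a), N = N)
  out <- out[order(-out$a, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# One row per counting unit: (report, label) pairs, deduplicated per
# report under report-level counting.
label_rows <- function(clean, level, counting = "reports") {
  re <- clean$reactions
  if (level == "SOC") {
    if (is.null(re$soc))
      stopf("SOC level requires map_pt_to_soc() annotation")
    lab <- data.frame(report_id = re$report_id, label = re$soc)
  } else {
    lab <- data.frame(report_id = re$report_id, label = re$pt)
  }
  if (counting == "reports") lab <- unique(lab)
  lab
}

#' Event report counts by label
#'
#' Number of reports (or report x label pairs) mentioning each event
#' label, in descending order — the "reported cases" ranking used when
#' presenting organ-class distributions.
#'
#' @inheritParams build_tables
#' @return named numeric vector, descending.
#' @export
event_counts <- function(clean, level = c("PT", "SOC"),
                         counting = c("reports", "pairs")) {
  stopifnot(inherits(clean, "clean_reports"))
  level <- match.arg(level)
  counting <- match.arg(counting)
  if (nrow(clean$reactions) == 0L) return(setNames(numeric(0),
                                                   character(0)))
  lab <- label_rows(clean, level, counting)
  tab <- sort(table(lab$label), decreasing = TRUE)
  setNames(as.numeric(tab), names(tab))
}
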