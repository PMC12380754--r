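#' Compute time to onset per report with date hygiene
#'
#' Time to onset (TTO) is the number of calendar days from the start of
#' therapy with the target drug to the event date. The therapy start is
#' the earliest complete start date among the report's matching
#' suspect-drug entries. Reports with incomplete dates (year-only,
#' year-month or missing), events dated before therapy start, or
#' unparseable dates are excluded with a reason; every input report is
#' accounted for as either a record or an exclusion.
#'
#' @param clean a `clean_reports` object.
#' @param drug_names optional target drug names restricting which drug
#'   entries provide the start date; `NULL` uses all suspect entries.
#' @param role_values drug roles providing start dates (default `PS`).
#' @return list with `records` (data frame `report_id`, `days`) and
#'   `exclusions` (data frame `report_id`, `reason` in
#'   `incomplete_date`, `event_before_start`, `unparseable`).
#' @export
compute_tto <- function(clean, drug_names = NULL, role_values = "PS") {
  stopifnot(inherits(clean, "clean_reports"))
  d <- clean$drugs
  keep <- rep(TRUE, nrow(d))
  if (!is.null(drug_names)) keep <- match_drug_names(d$name, drug_names)
  if (!is.null(role_values)) keep <- keep & d$role %in% role_values
  d <- d[keep, , drop = FALSE]

  ids <- clean$reports$report_id
  ev_raw <- clean$reports$event_date
  start_raw <- rep(NA_character_, length(ids))
  if (nrow(d)) {
    complete <- pd_complete(d$start_date)
    dc <- d[complete, , drop = FALSE]
    if (nrow(dc)) {
      key <- pd_sort_key(dc$start_date)
      best <- tapply(seq_len(nrow(dc)), dc$report_id,
                     function(i) i[which.min(key[i])])
      start_raw[match(names(best), ids)] <- dc$start_date[unlist(best)]
    }
  }

  reason <- rep(NA_character_, length(ids))
  ev_ok <- pd_complete(ev_raw)
  st_ok <- pd_complete(start_raw)
  reason[!ev_ok | !st_ok] <- "incomplete_date"
  ev <- pd_parse(ev_raw)
  st <- pd_parse(start_raw)
  bad_parse <- is.na(reason) & (is.na(ev) | is.na(st))
  reason[bad_parse] <- "unparseable"
  days <- as.numeric(ev - st)
  reason[is.na(reason) & days < 0] <- "event_before_start"

  ok <- is.na(reason)
  list(records = data.frame(report_id = ids[ok], days = days[ok]),
       exclusions = data.frame(report_id = ids[!ok],
                               reason = reason[!ok]))
}

#' Attach organ classes to TTO records
#'
#' Expands TTO records to one row per distinct (report, SOC) combination,
#' for organ-class-level onset comparisons.
#'
#' @param tto result of [compute_tto()].
#' @param clean the `clean_reports` object annotated with
#'   [map_pt_to_soc()].
#' @return data frame with columns `report_id`, `soc`, `days`.
#' @export
tto_by_soc <- function(tto, clean) {
  if (is.null(clean$reactions$soc))
    stopf("annotate with map_pt_to_soc() before tto_by_soc()")
  socs <- unique(clean$reactions[c("report_id", "soc")])
  out <- merge(tto$records, socs, by = "report_id")
  out[order(out$soc, out$report_id), c("report_id", "soc", "days")]
}

#' Quantile summary of onset times
#'
#' Median, quartiles (linear interpolation, quantile type 7),
#' interquartile range and extremes.
#'
#' @param days numeric vector of onset times (>= 1 value).
#' @return named list: `median`, `q1`, `q3`, `iqr`, `min`, `max`, `n`.
#' @export
summarize_tto <- function(days) {
  days <- days[!is.na(days)]
  if (length(days) == 0L) stopf("no onset records to summarize")
  q <- stats::quantile(days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
       min = min(days), max = max(days), n = length(days))
}

#' Monthly binning of onset times
#'
#' Bins onset days into `[0, m]`, `(m, 2m]`, ... with `m = month_days`
#' (30 by default, a convention for "within the first month"), reporting
#' counts and percentages of all valid records.
#'
#' @param days numeric vector of onset times.
#' @param month_days bin width in days.
#' @return data frame with columns `bin`, `lower`, `upper`, `n`, `pct`.
#' @export
bin_monthly <- function(days, month_days = 30) {
  days <- days[!is.na(days)]
  if (length(days) == 0L)
    return(data.frame(bin = character(0), lower = numeric(0),
                      upper = numeric(0), n = numeric(0),
                      pct = numeric(0)))
  n_bins <- max(1L, ceiling(max(days) / month_days))
  breaks <- seq(0, n_bins * month_days, by = month_days)
  cuts <- cut(days, breaks = breaks, include.lowest = TRUE)
  tab <- table(cuts)
  data.frame(bin = names(tab),
             lower = breaks[-length(breaks)], upper = breaks[-1],
             n = as.numeric(tab),
             pct = 100 * as.numeric(tab) / length(days))
}

#' Kruskal-Wallis rank test across onset-time groups
#'
#' Tie-corrected rank statistic `H` with `k - 1` degrees of freedom and
#' chi-squared upper-tail p-value. The degenerate case where every
#' observation is identical returns `H = 0`, `p = 1`.
#'
#' @param groups named list of numeric vectors (>= 2 nonempty groups).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stopf("need at least two groups")
  if (any(lengths(groups) == 0L)) stopf("every group must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Kaplan-Meier cumulative incidence of onset
#'
#' Product-limit estimate of the cumulative incidence `1 - S(t)`. In the
#' usual TTO design every record is an event (no censoring), in which
#' case the curve coincides with the empirical distribution function;
#' right-censoring is supported for reuse via `status`.
#'
#' @param days event or censoring times (>= 0).
#' @param status event indicator (1 = event, 0 = censored); default all
#'   events.
#' @return data frame with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `cuminc`, starting from an implicit
#'   `time = 0` row with `cuminc = 0`.
#' @export
km_cumulative_incidence <- function(days, status = NULL) {
  days <- as.numeric(days)
  if (length(days) == 0L) stopf("no records")
  if (any(is.na(days) | days < 0)) stopf("times must be nonnegative")
  if (is.null(status)) status <- rep(1, length(days))
  sf <- survival::survfit(survival::Surv(days, status) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    survival = sf$surv, cuminc = 1 - sf$surv)
  if (nrow(out) == 0L || out$time[1] > 0) {
    out <- rbind(data.frame(time = 0, n_risk = length(days), n_event = 0,
                            n_censor = 0, survival = 1, cuminc = 0),
                 out)
  }
  rownames(out) <- NULL
  out
}
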