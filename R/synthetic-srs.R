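#' Configuration for the synthetic spontaneous-report generator
#'
#' Defines the generative regime for a synthetic reporting-system database:
#' a uniform background multinomial over drugs, a Dirichlet-drawn event
#' multinomial, designated drug-event pairs with elevated relative risk,
#' Weibull onset times, and nuisance processes (duplicate case versions,
#' corrupted dates, demographic missingness).
#'
#' Defaults emulate the reporting regime seen in echinocandin
#' pharmacovigilance extracts: one suspect drug per report, one to three
#' preferred terms per report (FAERS averages roughly 2.5), onset times
#' with Weibull shape 0.8 and scale 10 days (median about 6 days, an
#' early-failure hazard), weight missing for about 70% of reports, age for
#' about 20% and sex for about 12%.
#'
#' @param n_reports number of reports to generate.
#' @param n_drugs number of distinct drugs; reports draw a drug uniformly.
#' @param n_events number of distinct event preferred terms.
#' @param signal_pairs `NULL` or a data frame with columns `drug`, `event`
#'   (1-based indices) and `rr` (relative-risk multiplier, >= 0). For each
#'   designated pair, the event's probability conditional on the drug is
#'   multiplied by `rr` and the row renormalized, so the realized marginal
#'   relative risk is slightly below `rr`.
#' @param events_per_report integer range `c(min, max)` of distinct events
#'   drawn per report.
#' @param onset_shape,onset_scale Weibull shape (dimensionless) and scale
#'   (days) of the time from therapy start to event.
#' @param p_duplicate fraction of cases that receive extra report versions
#'   when [inject_duplicates()] is applied.
#' @param p_bad_date fraction of reports whose dates are corrupted when
#'   [corrupt_dates()] is applied.
#' @param missingness named list of per-field missingness fractions; fields
#'   `sex`, `age`, `wt`, `country`, `outcome`, `indication`.
#' @param seed integer seed; identical config and seed give identical
#'   output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_reports, n_drugs = 10, n_events = 100,
                       signal_pairs = NULL,
                       events_per_report = c(1L, 3L),
                       onset_shape = 0.8, onset_scale = 10,
                       p_duplicate = 0, p_bad_date = 0,
                       missingness = list(sex = 0.12, age = 0.20,
                                          wt = 0.70, country = 0.05,
                                          outcome = 0.12,
                                          indication = 0.30),
                       seed = 1L) {
  n_reports <- check_count(n_reports, "n_reports")
  n_drugs <- check_count(n_drugs, "n_drugs", min = 1L)
  n_events <- check_count(n_events, "n_events", min = 1L)
  if (!is.null(signal_pairs)) {
    signal_pairs <- as.data.frame(signal_pairs)
    need <- c("drug", "event", "rr")
    if (!all(need %in% names(signal_pairs)))
      stopf("signal_pairs needs columns %s", paste(need, collapse = ", "))
    if (any(signal_pairs$drug < 1 | signal_pairs$drug > n_drugs))
      stopf("signal_pairs$drug out of range [1, %d]", n_drugs)
    if (any(signal_pairs$event < 1 | signal_pairs$event > n_events))
      stopf("signal_pairs$event out of range [1, %d]", n_events)
    if (any(signal_pairs$rr < 0)) stopf("signal_pairs$rr must be >= 0")
  }
  if (length(events_per_report) == 1L)
    events_per_report <- rep(events_per_report, 2L)
  events_per_report <- as.integer(events_per_report)
  if (events_per_report[1] < 1L ||
      events_per_report[2] < events_per_report[1] ||
      events_per_report[2] > n_events)
    stopf("events_per_report must satisfy 1 <= min <= max <= n_events")
  if (onset_shape <= 0 || onset_scale <= 0)
    stopf("onset_shape and onset_scale must be positive")
  check_fraction(p_duplicate, "p_duplicate")
  check_fraction(p_bad_date, "p_bad_date")
  default_miss <- list(sex = 0.12, age = 0.20, wt = 0.70, country = 0.05,
                       outcome = 0.12, indication = 0.30)
  missingness <- utils::modifyList(default_miss, as.list(missingness))
  for (f in names(missingness)) check_fraction(missingness[[f]],
                                               paste0("missingness$", f))
  structure(list(n_reports = n_reports, n_drugs = n_drugs,
                 n_events = n_events, signal_pairs = signal_pairs,
                 events_per_report = events_per_report,
                 onset_shape = onset_shape, onset_scale = onset_scale,
                 p_duplicate = p_duplicate, p_bad_date = p_bad_date,
                 missingness = missingness, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic spontaneous-report cohort
#'
#' Each report draws one drug from a uniform multinomial and 1-k distinct
#' events from an event multinomial whose probabilities for designated
#' (drug, event) pairs are multiplied by the pair's relative-risk factor
#' and renormalized. Event background probabilities are drawn once per
#' config from a symmetric Dirichlet(1) so that event margins vary across
#' labels. Therapy start dates, Weibull onset times, receipt dates,
#' demographics and outcomes are attached, with per-field missingness.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `data` (an [srs_data()] object, pre-deduplication) and `truth`
#'   (ground-truth metadata: the config, background event probabilities,
#'   planted pairs, onset parameters and per-report assignments). The
#'   distributional choices are synthetic stand-ins for a reporting
#'   system, recorded as such in `truth$notes`.
#' @examples
#' cfg <- sim_config(n_reports = 200, n_drugs = 5, n_events = 20, seed = 7)
#' coh <- generate_reports(cfg)
#' coh$data
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_reports
  if (n == 0L) {
    return(new_cohort(srs_data(data.frame(), data.frame(), data.frame()),
                      config, event_base_probs = numeric(0)))
  }
  withr::with_seed(config$seed, {
    base_p <- stats::rgamma(config$n_events, 1, 1)
    base_p <- base_p / sum(base_p)
    rows <- plant_rows(base_p, config)

    drug_idx <- sample.int(config$n_drugs, n, replace = TRUE)
    ks <- seq.int(config$events_per_report[1], config$events_per_report[2])
    k <- ks[sample.int(length(ks), n, replace = TRUE)]
    events <- vector("list", n)
    for (i in seq_len(n)) {
      p <- rows$get(drug_idx[i])
      events[[i]] <- sample.int(config$n_events, k[i], prob = p)
    }

    start <- as.Date("2004-01-01") +
      (sample.int(7400L, n, replace = TRUE) - 1L)
    onset <- stats::rweibull(n, config$onset_shape, config$onset_scale)
    event_date <- start + round(onset)
    fda <- event_date + (sample.int(91L, n, replace = TRUE) - 1L)

    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.40, 0.60))
    ageband <- sample.int(3L, n, replace = TRUE, prob = c(0.14, 0.56, 0.30))
    age <- round(c(stats::runif(n, 0, 17), stats::runif(n, 18, 65),
                   stats::runif(n, 66, 90))[(ageband - 1L) * n +
                                            seq_len(n)])
    wt <- round(pmin(pmax(stats::rnorm(n, 70, 15), 30), 140))
    country <- sample(c("FR", "US", "JP", "CN", "DE", "GB", "IT"), n,
                      replace = TRUE,
                      prob = c(0.20, 0.20, 0.15, 0.10, 0.10, 0.15, 0.10))
    occp <- sample(c("MD", "PH", "CN", "OT"), n, replace = TRUE,
                   prob = c(0.50, 0.20, 0.15, 0.15))
    outc_cod <- sample(c("DE", "HO", "LT", "DS", "RI", "OT"), n,
                       replace = TRUE,
                       prob = c(0.33, 0.25, 0.06, 0.01, 0.005, 0.345))
    indi_pt <- sample(c("FUNGAL INFECTION", "SYSTEMIC CANDIDA",
                        "BRONCHOPULMONARY ASPERGILLOSIS",
                        "CANDIDA INFECTION", "ANTIFUNGAL PROPHYLAXIS",
                        "FEBRILE NEUTROPENIA"), n, replace = TRUE,
                      prob = c(0.25, 0.20, 0.15, 0.15, 0.15, 0.10))

    m <- config$missingness
    mask <- function(x, p) {
      x[stats::runif(length(x)) < p] <- NA
      x
    }
    sex <- mask(sex, m$sex); age <- mask(age, m$age)
    wt <- mask(wt, m$wt); country <- mask(country, m$country)
    keep_outc <- stats::runif(n) >= m$outcome
    keep_indi <- stats::runif(n) >= m$indication

    primaryid <- as.character(100000000 + seq_len(n))
    caseid <- as.character(50000000 + seq_len(n))
    drug_names <- sprintf("DRUG_%03d", seq_len(config$n_drugs))
    pt_labels <- sprintf("EVENT_%04d", seq_len(config$n_events))

    demo <- data.frame(primaryid = primaryid, caseid = caseid,
                       fda_dt = pd_format(fda),
                       event_dt = pd_format(event_date),
                       sex = sex, age = age,
                       age_cod = ifelse(is.na(age), NA, "YR"),
                       wt = wt, wt_cod = ifelse(is.na(wt), NA, "KG"),
                       reporter_country = country, occp_cod = occp)
    drug <- data.frame(primaryid = primaryid, drug_seq = 1,
                       role_cod = "PS", drugname = drug_names[drug_idx])
    reac <- data.frame(primaryid = rep(primaryid, lengths(events)),
                       pt = pt_labels[unlist(events)])
    ther <- data.frame(primaryid = primaryid, drug_seq = 1,
                       start_dt = pd_format(start))
    outc <- data.frame(primaryid = primaryid[keep_outc],
                       outc_cod = outc_cod[keep_outc])
    indi <- data.frame(primaryid = primaryid[keep_indi],
                       indi_pt = indi_pt[keep_indi])

    new_cohort(srs_data(demo, drug, reac, ther, outc, indi), config,
               event_base_probs = base_p, drug_of_report = drug_idx,
               onset_days = onset, drug_names = drug_names,
               pt_labels = pt_labels)
  })
}

# Per-drug event probability rows: drugs without planted pairs share the
# Dirichlet background row; planted rows are boosted and renormalized.
plant_rows <- function(base_p, config) {
  special <- list()
  sp <- config$signal_pairs
  if (!is.null(sp) && nrow(sp) > 0) {
    for (d in unique(sp$drug)) {
      p <- base_p
      sub <- sp[sp$drug == d, , drop = FALSE]
      p[sub$event] <- p[sub$event] * sub$rr
      special[[as.character(d)]] <- p / sum(p)
    }
  }
  list(get = function(d) {
    s <- special[[as.character(d)]]
    if (is.null(s)) base_p else s
  })
}

new_cohort <- function(data, config, event_base_probs, ...) {
  truth <- c(list(config = config, n_cases = nrow(data$demo),
                  signal_pairs = config$signal_pairs,
                  onset = list(shape = config$onset_shape,
                               scale = config$onset_scale),
                  event_base_probs = event_base_probs,
                  duplicate_cases = character(0),
                  bad_dates = data.frame(primaryid = character(0),
                                         type = character(0)),
                  notes = paste("synthetic stand-in distributions;",
                                "not fit to any real database")),
             list(...))
  structure(list(data = data, truth = truth), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  np <- if (is.null(x$truth$signal_pairs)) 0 else nrow(x$truth$signal_pairs)
  cat(sprintf(paste0("<synthetic_cohort> %d report versions, %d true",
                     " cases, %d planted signal pair(s)\n"),
              nrow(x$data$demo), x$truth$n_cases, np))
  invisible(x)
}

#' Draw synthetic onset times
#'
#' Strictly positive Weibull draws in days, using the onset shape and scale
#' of the configuration. Deterministic under the config seed (an
#' independent substream from [generate_reports()]).
#'
#' @param config a [sim_config()].
#' @param n number of draws.
#' @return numeric vector of `n` onset times in days, all > 0.
#' @export
generate_onsets <- function(config, n) {
  stopifnot(inherits(config, "sim_config"))
  n <- check_count(n, "n")
  if (n == 0L) return(numeric(0))
  withr::with_seed(pv_seed(config$seed, 17L), {
    x <- stats::rweibull(n, config$onset_shape, config$onset_scale)
    # guard against an underflow-to-zero draw; support is t > 0
    x[x <= 0] <- .Machine$double.eps
    x
  })
}

#' Inject duplicate case versions into a synthetic cohort
#'
#' A fraction `p_duplicate` of cases gain one or two extra report versions
#' that share the `caseid` but carry new `primaryid`s, strictly later
#' receipt dates and a possibly perturbed reaction list. Ground truth keeps
#' the original case count, so write/read/deduplicate round trips can be
#' verified exactly.
#'
#' @param cohort a `synthetic_cohort`.
#' @param p_duplicate optional override of the config fraction.
#' @return the cohort with extra report versions and
#'   `truth$duplicate_cases` filled in.
#' @export
inject_duplicates <- function(cohort, p_duplicate = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$truth$config
  p <- if (is.null(p_duplicate)) cfg$p_duplicate else p_duplicate
  check_fraction(p, "p_duplicate")
  n <- nrow(cohort$data$demo)
  n_dup <- round(p * n)
  if (n_dup == 0L) return(cohort)
  if (n == 0L) stopf("cannot inject duplicates into an empty cohort")
  withr::with_seed(pv_seed(cfg$seed, 29L), {
    x <- cohort$data
    pick <- sample(x$demo$caseid, n_dup)
    next_id <- max(as.numeric(x$demo$primaryid)) + 1
    all_pts <- unique(x$reac$pt)
    demo_add <- list(); child_add <- list(drug = list(), ther = list(),
                                          outc = list(), indi = list(),
                                          reac = list())
    for (cid in pick) {
      orig <- x$demo[x$demo$caseid == cid, , drop = FALSE][1, ]
      n_extra <- sample(1:2, 1)
      fda <- pd_parse(orig$fda_dt)
      for (j in seq_len(n_extra)) {
        fda <- fda + sample(1:60, 1)
        ver <- orig
        ver$primaryid <- as.character(next_id)
        ver$fda_dt <- pd_format(fda)
        demo_add[[length(demo_add) + 1L]] <- ver
        pts <- x$reac$pt[x$reac$primaryid == orig$primaryid]
        if (stats::runif(1) < 0.5) {
          if (length(pts) > 1 && stats::runif(1) < 0.5) {
            pts <- pts[-sample.int(length(pts), 1)]
          } else {
            pts <- unique(c(pts, sample(all_pts, 1)))
          }
        }
        child_add$reac[[length(child_add$reac) + 1L]] <-
          data.frame(primaryid = ver$primaryid, pt = pts)
        for (tb in c("drug", "ther", "outc", "indi")) {
          rows <- x[[tb]][x[[tb]]$primaryid == orig$primaryid, ,
                          drop = FALSE]
          if (nrow(rows)) {
            rows$primaryid <- ver$primaryid
            child_add[[tb]][[length(child_add[[tb]]) + 1L]] <- rows
          }
        }
        next_id <- next_id + 1
      }
    }
    x$demo <- rbind(x$demo, do.call(rbind, demo_add))
    for (tb in c("drug", "ther", "outc", "indi", "reac")) {
      if (length(child_add[[tb]]))
        x[[tb]] <- rbind(x[[tb]], do.call(rbind, child_add[[tb]]))
    }
    rownames(x$demo) <- NULL
    cohort$data <- srs_data(x$demo, x$drug, x$reac, x$ther, x$outc,
                            x$indi)
    cohort$truth$duplicate_cases <- pick
    cohort
  })
}

#' Corrupt report dates in a synthetic cohort
#'
#' A fraction `p_bad_date` of reports receive a partial (year-only or
#' year-month), missing, or inverted (event before therapy start) event
#' date. The corrupted report identifiers and corruption types are
#' recorded in `truth$bad_dates`, so downstream date-hygiene filters can be
#' checked exactly.
#'
#' @param cohort a `synthetic_cohort`.
#' @param p_bad_date optional override of the config fraction.
#' @return the cohort with corrupted dates and `truth$bad_dates` filled in.
#' @export
corrupt_dates <- function(cohort, p_bad_date = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$truth$config
  p <- if (is.null(p_bad_date)) cfg$p_bad_date else p_bad_date
  check_fraction(p, "p_bad_date")
  n <- nrow(cohort$data$demo)
  n_bad <- round(p * n)
  if (n_bad == 0L) return(cohort)
  withr::with_seed(pv_seed(cfg$seed, 31L), {
    x <- cohort$data
    idx <- sample.int(n, n_bad)
    type <- sample(c("year_only", "year_month", "missing", "inverted"),
                   n_bad, replace = TRUE)
    ev <- x$demo$event_dt
    for (j in seq_along(idx)) {
      i <- idx[j]
      ev[i] <- switch(type[j],
        year_only = substr(ev[i], 1, 4),
        year_month = substr(ev[i], 1, 6),
        missing = NA_character_,
        inverted = {
          st <- x$ther$start_dt[match(x$demo$primaryid[i],
                                      x$ther$primaryid)]
          pd_format(pd_parse(st) - sample(3:60, 1))
        })
    }
    x$demo$event_dt <- ev
    cohort$data <- x
    cohort$truth$bad_dates <- data.frame(
      primaryid = x$demo$primaryid[idx], type = type)
    cohort
  })
}

#' Synthetic preferred-term to system-organ-class map
#'
#' Assigns the generator's event labels to `n_socs` synthetic organ-class
#' labels in contiguous blocks, mimicking the many-to-one primary-SOC
#' convention of a MedDRA-like hierarchy.
#'
#' @param config a [sim_config()].
#' @param n_socs number of synthetic organ classes.
#' @return data frame with columns `pt` and `soc`.
#' @export
synthetic_term_map <- function(config, n_socs = 10L) {
  stopifnot(inherits(config, "sim_config"))
  n_socs <- check_count(n_socs, "n_socs", min = 1L)
  pt <- sprintf("EVENT_%04d", seq_len(config$n_events))
  soc <- sprintf("SOC_%02d",
                 ((seq_len(config$n_events) - 1L) %% n_socs) + 1L)
  data.frame(pt = pt, soc = soc)
}
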