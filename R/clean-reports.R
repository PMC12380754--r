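#' Match drug names against verbatim drug-name fields
#'
#' Case-insensitive substring matching of any target name against the
#' verbatim name, the convention used when querying a reporting system by
#' generic and trade name (e.g. `"CASPOFUNGIN"`, `"CANCIDAS"`). No
#' normalization beyond case folding is applied.
#'
#' @param drugnames character vector of verbatim drug-name fields.
#' @param names nonempty character vector of target names.
#' @return logical vector, one element per entry of `drugnames`.
#' @examples
#' match_drug_names("Cancidas 50 mg vial", c("CASPOFUNGIN", "CANCIDAS"))
#' @export
match_drug_names <- function(drugnames, names) {
  if (length(names) == 0L) stopf("`names` must be nonempty")
  x <- toupper(as.character(drugnames))
  hit <- rep(FALSE, length(x))
  for (nm in toupper(names)) {
    hit <- hit | grepl(nm, x, fixed = TRUE)
  }
  hit & !is.na(x)
}

# FAERS role codes and their generic-dialect spellings.
normalize_role <- function(role) {
  r <- toupper(trimws(as.character(role)))
  map <- c("1" = "PS", "PS" = "PS", "PRIMARY SUSPECT" = "PS",
           "SUSPECTED DRUG" = "PS",
           "2" = "SS", "SS" = "SS", "3" = "C", "C" = "C",
           "CONCOMITANT" = "C", "4" = "I", "I" = "I", "INTERACTING" = "I")
  out <- unname(map[r])
  out[is.na(out)] <- r[is.na(out)]
  out
}

#' Harmonize raw report data into clean per-report records
#'
#' Normalizes sex codes, converts ages to years (FAERS unit codes `YR`,
#' `MON`, `WK`, `DY`; `HR` and `DEC` give unknown), converts weights to
#' kilograms (`KG`, `LBS`), uppercases and deduplicates reaction preferred
#' terms within each report, and joins the earliest therapy start date to
#' each drug entry. Deduplicate with [deduplicate()] first.
#'
#' @param x an [srs_data()] object.
#' @return an object of class `clean_reports`: a list of data frames
#'   `reports` (one row per report: `report_id`, `case_id`, `sex`,
#'   `age_years`, `weight_kg`, `country`, `reporter`, `event_date`,
#'   `receipt_date`), `drugs` (`report_id`, `drug_seq`, `name`, `role`,
#'   `start_date`), `reactions` (`report_id`, `pt`), `outcomes`
#'   (`report_id`, `outcome`) and `indications` (`report_id`,
#'   `indication`).
#' @export
as_clean_reports <- function(x) {
  stopifnot(inherits(x, "srs_data"))
  demo <- x$demo
  sex <- toupper(demo$sex)
  sex <- ifelse(is.na(sex), "unknown",
                ifelse(sex %in% c("F", "FEMALE"), "female",
                       ifelse(sex %in% c("M", "MALE"), "male", "unknown")))
  unit <- toupper(ifelse(is.na(demo$age_cod), "YR", demo$age_cod))
  factor_map <- c(YR = 1, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365.25)
  fac <- unname(factor_map[unit])
  age_years <- demo$age * fac
  age_years[!is.na(age_years) & age_years < 0] <- NA
  wunit <- toupper(ifelse(is.na(demo$wt_cod), "KG", demo$wt_cod))
  wfac <- unname(c(KG = 1, KGS = 1, LBS = 0.45359237,
                   LB = 0.45359237)[wunit])
  weight_kg <- demo$wt * wfac
  weight_kg[!is.na(weight_kg) & weight_kg < 0] <- NA

  reports <- data.frame(report_id = demo$primaryid,
                        case_id = demo$caseid, sex = sex,
                        age_years = age_years, weight_kg = weight_kg,
                        country = demo$reporter_country,
                        reporter = demo$occp_cod,
                        event_date = demo$event_dt,
                        receipt_date = demo$fda_dt)

  drugs <- x$drug
  start <- x$ther
  if (nrow(start)) {
    key <- paste(start$primaryid, start$drug_seq)
    skey <- pd_sort_key(start$start_dt)
    best <- tapply(seq_len(nrow(start)), key, function(i) {
      i[which.min(replace(skey[i], is.na(skey[i]), Inf))]
    })
    start <- start[unlist(best), , drop = FALSE]
    drugs$start_date <- start$start_dt[match(
      paste(drugs$primaryid, drugs$drug_seq),
      paste(start$primaryid, start$drug_seq))]
  } else {
    drugs$start_date <- rep(NA_character_, nrow(drugs))
  }
  drugs <- data.frame(report_id = drugs$primaryid,
                      drug_seq = drugs$drug_seq,
                      name = drugs$drugname,
                      role = normalize_role(drugs$role_cod),
                      start_date = drugs$start_date)

  reac <- x$reac
  reactions <- unique(data.frame(report_id = reac$primaryid,
                                 pt = toupper(reac$pt)))
  reactions <- reactions[!is.na(reactions$pt), , drop = FALSE]
  rownames(reactions) <- NULL

  outcomes <- data.frame(report_id = x$outc$primaryid,
                         outcome = toupper(x$outc$outc_cod))
  indications <- data.frame(report_id = x$indi$primaryid,
                            indication = toupper(x$indi$indi_pt))
  structure(list(reports = reports, drugs = drugs, reactions = reactions,
                 outcomes = outcomes, indications = indications),
            class = "clean_reports")
}

#' @export
print.clean_reports <- function(x, ...) {
  cat(sprintf("<clean_reports> %d reports, %d drug entries, %d reaction PTs\n",
              nrow(x$reports), nrow(x$drugs), nrow(x$reactions)))
  invisible(x)
}

# Report ids whose drug entries match the target names with a given role.
target_report_ids <- function(clean, drug_names,
                              role_values = "PS") {
  d <- clean$drugs
  hit <- match_drug_names(d$name, drug_names)
  if (!is.null(role_values)) hit <- hit & d$role %in% role_values
  unique(d$report_id[hit])
}

#' Restrict to reports with the target drug as primary suspect
#'
#' Keeps reports having at least one drug entry that matches a target name
#' (see [match_drug_names()]) with a primary-suspect role. For the generic
#' dialect, role spellings such as `"suspected drug"` are normalized to
#' `PS`; other role values can be supplied via `role_values`.
#'
#' @param x an [srs_data()] or `clean_reports` object (deduplicated).
#' @param drug_names character vector of target drug names.
#' @param role_values roles accepted as "suspect"; `NULL` accepts any role.
#' @return a `clean_reports` object restricted to the matching reports.
#' @export
filter_primary_suspect <- function(x, drug_names, role_values = "PS") {
  clean <- if (inherits(x, "clean_reports")) x else as_clean_reports(x)
  ids <- target_report_ids(clean, drug_names, role_values)
  subset_clean(clean, ids)
}

subset_clean <- function(clean, ids) {
  clean$reports <- clean$reports[clean$reports$report_id %in% ids, ,
                                 drop = FALSE]
  for (tb in c("drugs", "reactions", "outcomes", "indications")) {
    clean[[tb]] <- clean[[tb]][clean[[tb]]$report_id %in% ids, ,
                               drop = FALSE]
    rownames(clean[[tb]]) <- NULL
  }
  rownames(clean$reports) <- NULL
  clean
}

#' Load a preferred-term to organ-class map
#'
#' @param path CSV with two columns, preferred term and system organ
#'   class (header optional but recommended: `pt,soc`).
#' @return data frame with columns `pt` and `soc`.
#' @export
load_term_map <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (ncol(df) < 2L) stopf("term map '%s' needs two columns (pt, soc)", path)
  names(df)[1:2] <- c("pt", "soc")
  df[1:2]
}

#' Annotate reaction terms with their system organ class
#'
#' Every preferred term is annotated with its primary SOC from the map;
#' terms absent from the map are annotated `"UNMAPPED"` and counted in the
#' attached attribute.
#'
#' @param clean a `clean_reports` object.
#' @param term_map data frame with columns `pt`, `soc` (many-to-one; a PT
#'   appearing with two different SOCs is a configuration error).
#' @return `clean` with a `soc` column added to `reactions` and attribute
#'   `n_unmapped` set.
#' @export
map_pt_to_soc <- function(clean, term_map) {
  stopifnot(inherits(clean, "clean_reports"))
  term_map <- as.data.frame(term_map)
  if (nrow(term_map) == 0L) stopf("term map is empty")
  if (!all(c("pt", "soc") %in% names(term_map)))
    stopf("term map needs columns `pt` and `soc`")
  tm <- unique(data.frame(pt = toupper(term_map$pt),
                          soc = term_map$soc))
  if (anyDuplicated(tm$pt))
    stopf("term map is not many-to-one: PT(s) %s map to multiple SOCs",
          paste(unique(tm$pt[duplicated(tm$pt)]), collapse = ", "))
  soc <- tm$soc[match(clean$reactions$pt, tm$pt)]
  n_unmapped <- sum(is.na(soc))
  soc[is.na(soc)] <- "UNMAPPED"
  clean$reactions$soc <- soc
  attr(clean, "n_unmapped") <- n_unmapped
  clean
}

#' Demographic summary table
#'
#' Counts and percentages by sex, age band, weight band, outcome code,
#' reporter type, top-k countries and top-k indications. Percentages use
#' the total number of tally rows for that characteristic as denominator;
#' for multi-valued characteristics (e.g. multiple outcome codes per
#' report in some dialects) this exceeds the report count, matching the
#' convention of published SRS summary tables.
#'
#' @param clean a `clean_reports` object.
#' @param age_breaks two cut points for the age bands (years); defaults to
#'   `c(18, 65)` giving `<18`, `18-65`, `>65`.
#' @param weight_breaks two cut points for weight bands (kg).
#' @param top_k number of countries / indications to list.
#' @return data frame with columns `characteristic`, `category`, `n`,
#'   `pct` (percentage of that characteristic's tally total, in 0-100).
#' @export
summarize_demographics <- function(clean, age_breaks = c(18, 65),
                                   weight_breaks = c(50, 100),
                                   top_k = 5L) {
  stopifnot(inherits(clean, "clean_reports"))
  r <- clean$reports
  tally <- function(characteristic, categories) {
    n <- as.numeric(categories)
    data.frame(characteristic = characteristic,
               category = names(categories), n = n,
               pct = if (sum(n) > 0) 100 * n / sum(n) else 0 * n)
  }
  band <- function(x, breaks, unit) {
    lab <- ifelse(is.na(x), "unknown",
           ifelse(x < breaks[1], sprintf("<%g", breaks[1]),
           ifelse(x <= breaks[2], sprintf("%g-%g", breaks[1], breaks[2]),
                  sprintf(">%g", breaks[2]))))
    levs <- c(sprintf("<%g", breaks[1]),
              sprintf("%g-%g", breaks[1], breaks[2]),
              sprintf(">%g", breaks[2]), "unknown")
    table(factor(lab, levels = levs))
  }
  out <- list(
    tally("sex", table(factor(r$sex,
                              levels = c("female", "male", "unknown")))),
    tally("age_years", band(r$age_years, age_breaks)),
    tally("weight_kg", band(r$weight_kg, weight_breaks)))

  oc <- clean$outcomes$outcome
  n_no_outcome <- sum(!r$report_id %in% clean$outcomes$report_id)
  oc_tab <- c(table(oc), unknown = n_no_outcome)
  out <- c(out, list(tally("outcome", oc_tab)))

  rep_tab <- table(ifelse(is.na(r$reporter), "unknown", r$reporter))
  out <- c(out, list(tally("reporter", rep_tab)))

  ct <- table(r$country[!is.na(r$country)])
  ct <- sort(ct, decreasing = TRUE)
  topc <- head(ct, top_k)
  if (length(topc)) {
    df <- data.frame(characteristic = "country",
                     category = names(topc), n = as.numeric(topc),
                     pct = 100 * as.numeric(topc) / nrow(r))
    out <- c(out, list(df))
  }
  it <- sort(table(clean$indications$indication), decreasing = TRUE)
  topi <- head(it, top_k)
  if (length(topi)) {
    df <- data.frame(characteristic = "indication",
                     category = names(topi), n = as.numeric(topi),
                     pct = 100 * as.numeric(topi) / nrow(r))
    out <- c(out, list(df))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
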