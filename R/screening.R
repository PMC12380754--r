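#' Positivity threshold policy for the four algorithms
#'
#' The standard published criteria: ROR positive when `a >= 3` and the
#' lower 95% CI bound exceeds 1; PRR positive when `PRR >= 2`,
#' `chi-squared >= 4` and `a >= 3`; BCPNN positive when `IC025 > 0`; MGPS
#' positive when `EBGM05 >= 2`. At the preferred-term level a Bonferroni
#' gate on the chi-squared p-value can additionally be required for the
#' "significant" consensus call.
#'
#' @param ror_a_min,ror_ci_low ROR criteria: minimum count and exclusive
#'   lower bound for the CI low end.
#' @param prr_min,chi2_min,prr_a_min PRR criteria.
#' @param ic025_min exclusive lower bound for IC025.
#' @param ebgm05_min inclusive threshold for EBGM05.
#' @param use_bonferroni require `p_adj < alpha` at PT level.
#' @param alpha significance level for the Bonferroni gate.
#' @return an object of class `threshold_policy`.
#' @export
threshold_policy <- function(ror_a_min = 3, ror_ci_low = 1,
                             prr_min = 2, chi2_min = 4, prr_a_min = 3,
                             ic025_min = 0, ebgm05_min = 2,
                             use_bonferroni = TRUE, alpha = 0.05) {
  vals <- c(ror_a_min = ror_a_min, ror_ci_low = ror_ci_low,
            prr_min = prr_min, chi2_min = chi2_min,
            prr_a_min = prr_a_min, ic025_min = ic025_min,
            ebgm05_min = ebgm05_min, alpha = alpha)
  if (any(!is.finite(vals))) stopf("all policy bounds must be finite")
  if (ror_a_min < 1 || prr_a_min < 1) stopf("a_min thresholds must be >= 1")
  structure(as.list(c(vals, use_bonferroni = use_bonferroni)),
            class = "threshold_policy")
}

#' Classify signal statistics against the consensus rule
#'
#' Applies the per-algorithm positivity thresholds and the consensus rule:
#' at SOC level, `significant` when all four algorithms flag, `positive`
#' when at least one does, `negative` otherwise; at PT level only the
#' all-four consensus (optionally gated on the Bonferroni-adjusted
#' p-value) yields `significant`, everything else is `negative`.
#'
#' @param stats data frame from [compute_signals()].
#' @param policy a [threshold_policy()].
#' @param level `"PT"` or `"SOC"`; defaults to the `level` column of
#'   `stats`.
#' @return data frame of verdicts: `label`, `level`, `a`, per-algorithm
#'   logical flags (`flag_ror`, `flag_prr`, `flag_bcpnn`, `flag_mgps`),
#'   `n_positive_algorithms`, `classification`, `excluded`,
#'   `exclusion_reason`.
#' @export
classify_signals <- function(stats, policy = threshold_policy(),
                             level = NULL) {
  stopifnot(inherits(policy, "threshold_policy"))
  if (is.null(level)) {
    level <- as.character(stats$level)
  } else {
    level <- rep_len(as.character(level), nrow(stats))
  }
  if (!all(level %in% c("PT", "SOC")))
    stopf("level must be PT or SOC for every row")
  fr <- function(x) !is.na(x) & x  # NA (undefined statistic) never flags
  flag_ror <- fr(stats$a >= policy$ror_a_min &
                 stats$ror_low > policy$ror_ci_low)
  flag_prr <- fr(stats$prr >= policy$prr_min &
                 stats$chi2 >= policy$chi2_min &
                 stats$a >= policy$prr_a_min)
  flag_bcpnn <- fr(stats$ic025 > policy$ic025_min)
  flag_mgps <- fr(stats$ebgm05 >= policy$ebgm05_min)
  n_pos <- flag_ror + flag_prr + flag_bcpnn + flag_mgps
  all4 <- n_pos == 4L
  bonf_ok <- if (policy$use_bonferroni) {
    !is.na(stats$p_adj) & stats$p_adj < policy$alpha
  } else {
    rep(TRUE, nrow(stats))
  }
  classification <- ifelse(level == "SOC",
    ifelse(all4, "significant", ifelse(n_pos >= 1, "positive",
                                       "negative")),
    ifelse(all4 & bonf_ok, "significant", "negative"))
  data.frame(label = stats$label, level = level, a = stats$a,
             flag_ror = flag_ror, flag_prr = flag_prr,
             flag_bcpnn = flag_bcpnn, flag_mgps = flag_mgps,
             n_positive_algorithms = n_pos,
             classification = classification,
             excluded = FALSE, exclusion_reason = NA_character_)
}

#' Mark verdicts matching an exclusion blocklist
#'
#' Signals unrelated to drug therapy, driven by the underlying disease or
#' representing indications are screened with a user-supplied blocklist of
#' case-insensitive glob patterns. Matching labels are marked excluded
#' with the pattern's reason tag; rows are never deleted.
#'
#' @param verdicts data frame from [classify_signals()].
#' @param blocklist data frame with columns `pattern` (glob) and `reason`,
#'   or a character vector of patterns (reason `"blocklist"`).
#' @return `verdicts` with `excluded` / `exclusion_reason` filled in; the
#'   row count is unchanged.
#' @examples
#' v <- data.frame(label = c("FUNGAL INFECTION", "HEPATOTOXICITY"),
#'                 excluded = FALSE, exclusion_reason = NA)
#' apply_exclusions(v, data.frame(pattern = "FUNGAL*",
#'                                reason = "indication"))
#' @export
apply_exclusions <- function(verdicts, blocklist) {
  if (is.character(blocklist)) {
    blocklist <- data.frame(pattern = blocklist, reason = "blocklist")
  }
  blocklist <- as.data.frame(blocklist)
  if (nrow(blocklist) == 0L) return(verdicts)
  if (!all(c("pattern", "reason") %in% names(blocklist)))
    stopf("blocklist needs columns `pattern` and `reason`")
  if (any(is.na(blocklist$pattern) | blocklist$pattern == ""))
    stopf("blocklist contains an empty pattern")
  for (i in seq_len(nrow(blocklist))) {
    rx <- tryCatch(utils::glob2rx(blocklist$pattern[i]),
                   error = function(e)
                     stopf("malformed blocklist pattern '%s'",
                           blocklist$pattern[i]))
    hit <- grepl(rx, verdicts$label, ignore.case = TRUE)
    newhit <- hit & !verdicts$excluded
    verdicts$excluded[newhit] <- TRUE
    verdicts$exclusion_reason[newhit] <- blocklist$reason[i]
  }
  verdicts
}

#' Exclusive-region overlap of named label sets
#'
#' For every nonempty subset of the named sets, lists the labels exclusive
#' to exactly that subset — the regions of a Venn diagram. The exclusive
#' region sizes sum to the size of the union.
#'
#' @param sets named list (length >= 2) of character vectors.
#' @return list with `regions` (data frame: `sets` — names joined by
#'   `&` —, `k`, `n`, and list-column `labels`) and `union_size`.
#' @examples
#' overlap_sets(list(A = letters[1:5], B = letters[4:8], C = c("e", "i")))
#' @export
overlap_sets <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "") ||
      length(sets) < 2L)
    stopf("`sets` must be a named list of at least two label sets")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  nm <- names(sets)
  k <- length(sets)
  rows <- list()
  for (mask in 1:(2^k - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    region <- Reduce(intersect, sets[inset])
    if (any(!inset) && length(region))
      region <- setdiff(region, Reduce(union, sets[!inset]))
    rows[[length(rows) + 1L]] <- data.frame(
      sets = paste(nm[inset], collapse = "&"), k = sum(inset),
      n = length(region))
    rows[[length(rows)]]$labels <- I(list(sort(region)))
  }
  regions <- do.call(rbind, rows)
  list(regions = regions,
       union_size = length(Reduce(union, sets)))
}
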