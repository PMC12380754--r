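# The four disproportionality algorithms operate on the 2x2 report table
#
#                target event   other events
#   target drug       a              b
#   other drugs       c              d
#
# ROR and PRR follow the standard frequentist forms (Rothman CI for the
# odds ratio, Evans' PRR with the one-degree-of-freedom chi-squared); the
# BCPNN information component uses the Bate closed-form posterior moments,
# and EBGM the DuMouchel gamma-Poisson mixture (see mgps.R).

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a d)/(b c)` with Wald interval
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero and `haldane = TRUE`, the Haldane-Anscombe correction adds 0.5 to
#' all four cells; with the correction disabled, zero-cell tables are
#' flagged undefined rather than raising an error.
#'
#' @param a,b,c,d numeric vectors of cell counts (recycled to a common
#'   length).
#' @param haldane apply the +0.5 correction to zero-cell tables.
#' @return data frame with columns `ror`, `ror_low`, `ror_high`,
#'   `ror_corrected` (logical), `ror_undefined` (logical; `NA` estimates).
#' @examples
#' ror_stat(20, 80, 100, 9800)
#' @export
ror_stat <- function(a, b, c, d, haldane = TRUE) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  corrected <- haldane & zero
  undefined <- zero & !haldane
  off <- 0.5 * corrected
  aa <- a + off; bb <- b + off; cc <- c + off; dd <- d + off
  est <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  low <- exp(log(est) - 1.96 * se)
  high <- exp(log(est) + 1.96 * se)
  est[undefined] <- low[undefined] <- high[undefined] <- NA_real_
  data.frame(ror = est, ror_low = low, ror_high = high,
             ror_corrected = corrected, ror_undefined = undefined)
}

#' Proportional reporting ratio with chi-squared test
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` and the one-degree-of-freedom
#' chi-squared `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]` computed on the
#' raw (uncorrected) counts, with the upper-tail p-value. The Yates
#' continuity correction is available by flag. When `c = 0` the PRR is
#' undefined; with `haldane = TRUE` the +0.5 correction is applied to the
#' PRR (never to the chi-squared) instead.
#'
#' @inheritParams ror_stat
#' @param yates apply the Yates continuity correction to the chi-squared.
#' @return data frame with columns `prr`, `chi2`, `p_chi2`,
#'   `prr_corrected`, `prr_undefined`.
#' @examples
#' prr_stat(20, 80, 100, 9800)
#' @export
prr_stat <- function(a, b, c, d, haldane = TRUE, yates = FALSE) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  corrected <- haldane & zero
  # the ratio itself only degenerates when c = 0 (or an empty drug margin)
  undefined <- (c == 0 | a + b == 0) & !haldane
  off <- 0.5 * corrected
  aa <- a + off; bb <- b + off; cc <- c + off; dd <- d + off
  prr <- (aa / (aa + bb)) / (cc / (cc + dd))
  prr[undefined] <- NA_real_

  N <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(num - N / 2, 0)
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(den > 0, N * num^2 / den, NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(prr = prr, chi2 = chi2, p_chi2 = p,
             prr_corrected = corrected, prr_undefined = undefined)
}

#' BCPNN information component (closed form)
#'
#' Posterior moments of the information component
#' `IC = log2 P(drug, event) / (P(drug) P(event))` under the Bayesian
#' confidence propagation neural network model with the standard prior
#' constants (`alpha1 = beta1 = 1`, `alpha = beta = 2`, `gamma11 = 1`;
#' `gamma` scaled so the prior IC expectation is 0). `IC025 = E(IC) - 2
#' sqrt(V(IC))` approximates the 2.5th percentile of the posterior.
#'
#' @inheritParams ror_stat
#' @param priors named list overriding the prior constants `alpha1`,
#'   `beta1`, `alpha`, `beta`, `gamma11`.
#' @return data frame with columns `e_ic`, `v_ic`, `ic025` (bits).
#' @examples
#' bcpnn_ic(25, 75, 150, 9750)
#' @export
bcpnn_ic <- function(a, b, c, d, priors = list()) {
  pr <- utils::modifyList(list(alpha1 = 1, beta1 = 1, alpha = 2,
                               beta = 2, gamma11 = 1), priors)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  N <- a + b + c + d
  a1 <- pr$alpha1; b1 <- pr$beta1; al <- pr$alpha; be <- pr$beta
  g11 <- pr$gamma11
  gam <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  e_ic <- log2((a + g11) * (N + al) * (N + be) /
               ((N + gam) * (a + b + a1) * (a + c + b1)))
  v_ic <- ((N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
           (N - a - b + al - a1) / ((a + b + a1) * (1 + N + al)) +
           (N - a - c + be - b1) / ((a + c + b1) * (1 + N + be))) /
          log(2)^2
  data.frame(e_ic = e_ic, v_ic = v_ic, ic025 = e_ic - 2 * sqrt(v_ic))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m p)` with family size `m`, the number of labels tested
#' at that level in that database.
#'
#' @param p numeric vector of p-values.
#' @param m family size; must be at least `length(p)`.
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0)
    stopf("family size `m` must be a positive number")
  if (m < length(p))
    stopf("family size m = %g is smaller than the number of tests (%d)",
          m, length(p))
  pmin(1, m * p)
}

#' Compute all four disproportionality statistics for a table set
#'
#' Runs [ror_stat()], [prr_stat()], [bcpnn_ic()] and (after fitting or
#' reusing a gamma-mixture prior, see [fit_mgps_prior()]) [ebgm_stat()]
#' on every 2x2 table, and Bonferroni-adjusts the chi-squared p-values
#' with family size equal to the number of labels tested.
#'
#' @param tables data frame from [build_tables()] (columns `label`,
#'   `level`, `a`, `b`, `c`, `d`, `N`).
#' @param prior a fitted `gamma_mixture_prior`, or `NULL` to fit one from
#'   `tables`.
#' @param haldane,yates zero-cell and continuity-correction flags passed
#'   to the frequentist statistics; the Bayesian statistics always use raw
#'   counts.
#' @param bcpnn_priors prior constants for [bcpnn_ic()].
#' @return data frame with one row per label carrying the table counts,
#'   the expected count `e_expected = (a+b)(a+c)/N`, all statistic
#'   columns and `p_adj`; the fitted prior and family size are attached
#'   as attributes `prior` and `m_tests`.
#' @export
compute_signals <- function(tables, prior = NULL, haldane = TRUE,
                            yates = FALSE, bcpnn_priors = list()) {
  need <- c("label", "a", "b", "c", "d", "N")
  if (!all(need %in% names(tables)))
    stopf("`tables` must have columns %s", paste(need, collapse = ", "))
  if (!"level" %in% names(tables)) tables$level <- NA_character_
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  N <- tables$N
  E <- (a + b) * (a + c) / N
  if (is.null(prior)) prior <- fit_mgps_prior(a, E)
  out <- cbind(tables[c("level", "label", "a", "b", "c", "d", "N")],
               e_expected = E,
               ror_stat(a, b, c, d, haldane = haldane),
               prr_stat(a, b, c, d, haldane = haldane, yates = yates),
               bcpnn_ic(a, b, c, d, priors = bcpnn_priors),
               ebgm_stat(a, E, prior))
  m <- nrow(out)
  out$p_adj <- bonferroni(out$p_chi2, m)
  attr(out, "prior") <- prior
  attr(out, "m_tests") <- m
  out
}
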