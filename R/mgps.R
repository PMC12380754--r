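# DuMouchel's multi-item gamma-Poisson shrinker. The observed count a_i of
# each drug-event pair is modelled as Poisson(lambda_i * E_i), where E_i =
# (a+b)(a+c)/N is the count expected under independence and the relative
# reporting rate lambda follows a two-component gamma mixture prior
#   lambda ~ w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2)   (rate
# parameterization). Marginally a_i is then a mixture of negative
# binomials, which is what the prior is fitted to; the posterior for each
# pair is again a two-component gamma mixture.

#' Fit the gamma-mixture prior of the multi-item gamma-Poisson shrinker
#'
#' Maximizes the negative-binomial mixture marginal likelihood over the
#' five hyperparameters by quasi-Newton search on the unconstrained scale
#' (log shapes/rates, logit weight), starting from DuMouchel's published
#' starting point (0.2, 0.1, 2, 4, 1/3). On non-convergence the search is
#' restarted from jittered starts.
#'
#' @param a observed counts, one per drug-event pair.
#' @param E expected counts under independence, same length.
#' @param start numeric vector `(alpha1, beta1, alpha2, beta2, w)`.
#' @param n_restarts maximum number of jittered restarts.
#' @return an object of class `gamma_mixture_prior`: list with elements
#'   `alpha1`, `beta1`, `alpha2`, `beta2`, `w`, `loglik`, `convergence`.
#' @references DuMouchel W (1999) Bayesian data mining in large frequency
#'   tables, with an application to the FDA spontaneous reporting system.
#'   The American Statistician 53:177-190.
#' @export
fit_mgps_prior <- function(a, E, start = c(0.2, 0.1, 2, 4, 1 / 3),
                           n_restarts = 5L) {
  if (length(a) != length(E)) stopf("`a` and `E` lengths differ")
  keep <- is.finite(a) & is.finite(E) & E > 0
  a <- a[keep]; E <- E[keep]
  if (length(a) == 0L) stopf("no usable (a, E) pairs")
  if (all(a == 0)) stopf("degenerate input: all observed counts are zero")
  if (length(a) < 20L)
    warning("fewer than 20 tables; hyperparameter estimates will be unstable")

  nll <- function(th) {
    a1 <- exp(th[1]); b1 <- exp(th[2])
    a2 <- exp(th[3]); b2 <- exp(th[4])
    w <- stats::plogis(th[5])
    if (any(!is.finite(c(a1, b1, a2, b2)))) return(1e10)
    l1 <- suppressWarnings(
      stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE))
    l2 <- suppressWarnings(
      stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE))
    if (any(is.nan(l1) | is.nan(l2))) return(1e10)
    m <- pmax(l1 + log(w), l2 + log1p(-w))
    ll <- m + log(exp(l1 + log(w) - m) + exp(l2 + log1p(-w) - m))
    v <- -sum(ll)
    if (!is.finite(v)) 1e10 else v
  }

  # the mixture likelihood is multimodal (label switching, and a
  # degenerate mode that parks one component at zero weight); search from
  # a fixed battery of starts and keep the best converged optimum
  starts <- list(start,
                 c(start[3], start[4], start[1], start[2],
                   1 - start[5]),
                 c(10, 10, 0.5, 0.1, 0.9),
                 c(1, 1, 1, 0.1, 0.5))
  best <- NULL
  for (s in starts) {
    th_try <- c(log(s[1:4]), stats::qlogis(s[5]))
    fit <- tryCatch(stats::optim(th_try, nll, method = "BFGS",
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        fit$convergence == 0 &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    th0 <- c(log(start[1:4]), stats::qlogis(start[5]))
    for (r in seq_len(n_restarts)) {
      th_try <- th0 + stats::rnorm(5, sd = 0.5)
      fit <- tryCatch(stats::optim(th_try, nll, method = "BFGS",
                                   control = list(maxit = 500)),
                      error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) &&
          (is.null(best) || fit$value < best$value)) best <- fit
      if (!is.null(best) && best$convergence == 0) break
    }
  }
  if (is.null(best)) stopf("MGPS prior fit failed after restarts")
  th <- best$par
  out <- structure(list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
                        alpha2 = exp(th[3]), beta2 = exp(th[4]),
                        w = stats::plogis(th[5]),
                        loglik = -best$value,
                        convergence = best$convergence),
                   class = "gamma_mixture_prior")
  if (best$convergence != 0) {
    cond <- simpleError("MGPS optimizer did not converge after restarts")
    cond$prior <- out
    stop(cond)
  }
  out
}

#' @export
print.gamma_mixture_prior <- function(x, ...) {
  cat(sprintf(paste0("<gamma_mixture_prior> w=%.3f, ",
                     "Gamma(%.3f, %.3f) / Gamma(%.3f, %.3f), ",
                     "logLik=%.2f\n"),
              x$w, x$alpha1, x$beta1, x$alpha2, x$beta2, x$loglik))
  invisible(x)
}

# Prior mean relative reporting rate implied by the mixture.
prior_mean <- function(prior) {
  prior$w * prior$alpha1 / prior$beta1 +
    (1 - prior$w) * prior$alpha2 / prior$beta2
}

#' Empirical-Bayes geometric mean and its 5th percentile
#'
#' Under the gamma-mixture prior, the posterior of the relative reporting
#' rate given `a` is a two-component gamma mixture with components
#' `Gamma(alpha_j + a, beta_j + E)` and weights proportional to the prior
#' weights times the component negative-binomial marginals. `EBGM =
#' 2^{E[log2 lambda | a]}` via the digamma expectation of a log-gamma
#' variate; `EBGM05` is the posterior 5th percentile obtained by monotone
#' root-finding on the mixture distribution function.
#'
#' @param a observed counts.
#' @param E expected counts under independence (> 0).
#' @param prior a `gamma_mixture_prior` from [fit_mgps_prior()].
#' @return data frame with columns `ebgm` and `ebgm05`.
#' @export
ebgm_stat <- function(a, E, prior) {
  stopifnot(inherits(prior, "gamma_mixture_prior"))
  if (length(a) != length(E)) stopf("`a` and `E` lengths differ")
  if (any(!is.finite(E) | E <= 0)) stopf("all expected counts must be > 0")
  a1 <- prior$alpha1; b1 <- prior$beta1
  a2 <- prior$alpha2; b2 <- prior$beta2; w <- prior$w
  l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE) +
    log(w)
  l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE) +
    log1p(-w)
  m <- pmax(l1, l2)
  q1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  elog <- q1 * (digamma(a1 + a) - log(b1 + E)) +
    (1 - q1) * (digamma(a2 + a) - log(b2 + E))
  ebgm <- 2^(elog / log(2))

  ebgm05 <- vapply(seq_along(a), function(i) {
    cdf <- function(q) {
      q1[i] * stats::pgamma(q, shape = a1 + a[i], rate = b1 + E[i]) +
        (1 - q1[i]) * stats::pgamma(q, shape = a2 + a[i],
                                    rate = b2 + E[i])
    }
    lo <- 1e-12
    hi <- max(stats::qgamma(0.999, shape = a1 + a[i], rate = b1 + E[i]),
              stats::qgamma(0.999, shape = a2 + a[i], rate = b2 + E[i]))
    tries <- 0L
    while (cdf(hi) < 0.05 && tries < 60L) {
      hi <- hi * 2
      tries <- tries + 1L
    }
    if (cdf(hi) < 0.05 || cdf(lo) > 0.05)
      stopf("EBGM05 root not bracketed (a=%g, E=%g, CDF(%g)=%g)",
            a[i], E[i], hi, cdf(hi))
    stats::uniroot(function(q) cdf(q) - 0.05, c(lo, hi),
                   tol = 1e-10)$root
  }, numeric(1))
  data.frame(ebgm = ebgm, ebgm05 = ebgm05)
}
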