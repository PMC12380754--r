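make_tto_clean <- function(event_dt, start_dt, role = "PS",
                           name = "CASPOFUNGIN") {
  n <- length(event_dt)
  ids <- as.character(seq_len(n))
  demo <- data.frame(primaryid = ids, caseid = ids, fda_dt = "20230601",
                     event_dt = event_dt)
  drug <- data.frame(primaryid = ids, drug_seq = 1,
                     role_cod = rep_len(role, n),
                     drugname = rep_len(name, n))
  reac <- data.frame(primaryid = ids, pt = "EVENT")
  ther <- data.frame(primaryid = ids, drug_seq = 1, start_dt = start_dt)
  as_clean_reports(srs_data(demo, drug, reac, ther))
}

test_that("onset days are calendar differences with full date hygiene", {
  clean <- make_tto_clean(
    event_dt = c("20230111", "20230105", "20230101", "202301", NA,
                 "20230230"),
    start_dt = c("20230105", "20230105", "20230301", "20230101",
                 "20230101", "20230101"))
  tto <- compute_tto(clean)
  expect_equal(tto$records$days[tto$records$report_id == "1"], 6)
  expect_equal(tto$records$days[tto$records$report_id == "2"], 0)
  ex <- setNames(tto$exclusions$reason, tto$exclusions$report_id)
  expect_equal(ex[["3"]], "event_before_start")
  expect_equal(ex[["4"]], "incomplete_date")
  expect_equal(ex[["5"]], "incomplete_date")
  expect_equal(ex[["6"]], "unparseable")  # 30 February
  expect_equal(nrow(tto$records) + nrow(tto$exclusions), 6L)
})

test_that("the earliest complete start among matching suspect entries is
           used", {
  ids <- "1"
  demo <- data.frame(primaryid = ids, caseid = ids, fda_dt = "20230601",
                     event_dt = "20230110")
  drug <- data.frame(primaryid = rep(ids, 3), drug_seq = 1:3,
                     role_cod = c("PS", "PS", "C"),
                     drugname = c("CASPOFUNGIN", "CASPOFUNGIN IV",
                                  "OTHER"))
  reac <- data.frame(primaryid = ids, pt = "EVENT")
  ther <- data.frame(primaryid = rep(ids, 3), drug_seq = 1:3,
                     start_dt = c("20230105", "20230102", "20230101"))
  clean <- as_clean_reports(srs_data(demo, drug, reac, ther))
  tto <- compute_tto(clean, drug_names = "CASPOFUNGIN")
  # concomitant entry's earlier start is ignored; PS earliest = Jan 2
  expect_equal(tto$records$days, 8)
})

test_that("quantile summaries use type-7 interpolation", {
  s <- summarize_tto(1:10)
  expect_equal(s$median, 5.5)
  expect_equal(s$q1, 3.25)
  expect_equal(s$q3, 7.75)
  # independent interpolation oracle: q1 at position 1 + 0.25 * 9
  expect_equal(s$q1, 3 + 0.25)
  s1 <- summarize_tto(7)
  expect_equal(s1$median, 7); expect_equal(s1$iqr, 0)
  # quartile arithmetic: Q1 = 3, Q3 = 16 gives IQR 13, median 6
  s2 <- summarize_tto(c(3, 3, 6, 16, 16))
  expect_equal(s2$median, 6)
  expect_equal(s2$q1, 3); expect_equal(s2$q3, 16)
  expect_equal(s2$iqr, 13)
  expect_error(summarize_tto(numeric(0)), "no onset")
})

test_that("monthly bins report counts and percentages of valid records", {
  days <- rep(c(6, 45, 70), times = c(591, 49, 17))  # 657 records
  b <- bin_monthly(days)
  expect_equal(b$n[1], 591)
  expect_equal(round(b$pct[1], 2), 89.95)
  expect_equal(round(sum(b$pct[1:2]), 2), 97.41)
  expect_equal(sum(b$pct), 100, tolerance = 1e-12)
  expect_equal(sum(b$n), 657)
  # boundary: day 30 falls in the first bin, day 31 in the second
  b2 <- bin_monthly(c(30, 31))
  expect_equal(b2$n, c(1, 1))
  expect_equal(nrow(bin_monthly(numeric(0))), 0L)
})

test_that("the Weibull fit matches a grid-search likelihood oracle and
           covers the truth", {
  cfg <- sim_config(100, onset_shape = 0.7, onset_scale = 9, seed = 71)
  t <- generate_onsets(cfg, 2000)
  fit <- weibull_fit(t)
  grid <- weibull_grid_mle(t)
  expect_equal(fit$shape, unname(grid["shape"]), tolerance = 5e-3)
  expect_equal(fit$scale, unname(grid["scale"]), tolerance = 5e-3)
  expect_true(fit$shape_ci[1] < 0.7 && 0.7 < fit$shape_ci[2])
  expect_true(fit$scale_ci[1] < 9 && 9 < fit$scale_ci[2])
  expect_equal(fit$pattern, "early_failure")
  # an established fitter agrees with the Newton solution
  if (requireNamespace("fitdistrplus", quietly = TRUE)) {
    ref <- fitdistrplus::fitdist(t, "weibull")
    expect_equal(fit$shape, unname(ref$estimate["shape"]),
                 tolerance = 2e-3)
    expect_equal(fit$scale, unname(ref$estimate["scale"]),
                 tolerance = 2e-3)
  }
})

test_that("shape CIs achieve near-nominal coverage at the exponential
           null", {
  withr::with_seed(202, {
    covered <- vapply(1:200, function(i) {
      t <- rweibull(2000, 1, 10)
      ci <- weibull_fit(t)$shape_ci
      ci[1] < 1 && 1 < ci[2]
    }, logical(1))
  })
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("hazard-pattern classification follows the shape CI", {
  # upper bound below 1 (e.g. 0.79) is the early-failure pattern
  cfg <- sim_config(100, onset_shape = 0.65, onset_scale = 8, seed = 3)
  fit <- weibull_fit(generate_onsets(cfg, 3000))
  expect_lt(fit$shape_ci[2], 1)
  expect_equal(fit$pattern, "early_failure")
  cfg2 <- sim_config(100, onset_shape = 1.8, onset_scale = 8, seed = 4)
  expect_equal(weibull_fit(generate_onsets(cfg2, 3000))$pattern,
               "wear_out")
  cfg3 <- sim_config(100, onset_shape = 1, onset_scale = 8, seed = 5)
  expect_equal(weibull_fit(generate_onsets(cfg3, 3000))$pattern,
               "random")
})

test_that("weibull_fit guards its preconditions and handles zeros", {
  expect_error(weibull_fit(rep(5, 100)), "equal")
  expect_error(weibull_fit(1:5), "at least 10")
  t <- c(rep(0, 5), rweibull(100, 0.8, 10))
  fit <- weibull_fit(t)  # zeros replaced by 0.5 inside the likelihood
  expect_true(fit$shape > 0 && fit$scale > 0)
})

test_that("Kruskal-Wallis matches the direct rank-formula oracle", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskal_wallis(g)
  # tie-free direct formula: H = 12/(N(N+1)) sum n_i (rbar_i - rbar)^2
  N <- 9
  rbar <- c(mean(1:3), mean(4:6), mean(7:9))
  H <- 12 / (N * (N + 1)) * sum(3 * (rbar - (N + 1) / 2)^2)
  expect_equal(kw$H, H)
  expect_equal(kw$df, 2)
  expect_equal(kw$p, pchisq(H, 2, lower.tail = FALSE))
  # complete ties
  kw0 <- kruskal_wallis(list(x = c(5, 5, 5), y = c(5, 5, 5),
                             z = c(5, 5, 5)))
  expect_equal(kw0$H, 0); expect_equal(kw0$p, 1)
  # two-group H equals the squared standardized Wilcoxon statistic
  x <- c(1.2, 3.4, 5.1, 7.9); y <- c(2.2, 4.4, 6.1)
  kw2 <- kruskal_wallis(list(x = x, y = y))
  r <- rank(c(x, y)); n1 <- 4; n2 <- 3; N2 <- 7
  W <- sum(r[1:4])
  z <- (W - n1 * (N2 + 1) / 2) / sqrt(n1 * n2 * (N2 + 1) / 12)
  expect_equal(kw2$H, z^2)
  expect_error(kruskal_wallis(list(a = 1)), "two groups")
  expect_error(kruskal_wallis(list(a = 1, b = numeric(0))), "nonempty")
})

test_that("per-SOC onset groups assemble from annotated reports", {
  clean <- make_tto_clean(
    event_dt = c("20230105", "20230110", "20230120"),
    start_dt = "20230101")
  clean$reactions <- data.frame(
    report_id = c("1", "1", "2", "3"),
    pt = c("A", "B", "A", "C"))
  clean <- map_pt_to_soc(clean, data.frame(pt = c("A", "B", "C"),
                                           soc = c("S1", "S2", "S2")))
  tto <- compute_tto(clean)
  by_soc <- tto_by_soc(tto, clean)
  expect_equal(nrow(by_soc), 4L)  # report 1 contributes to S1 and S2
  expect_setequal(by_soc$days[by_soc$soc == "S2"], c(4, 19))
})

test_that("Kaplan-Meier cumulative incidence equals the empirical CDF
           without censoring", {
  km <- km_cumulative_incidence(c(1, 2, 2, 5))
  expect_equal(km$time, c(0, 1, 2, 5))
  expect_equal(km$cuminc, c(0, 0.25, 0.75, 1.0))
  # hand product-limit: 1 - (1 - 1/4), 1 - (3/4)(1 - 2/3), ...
  expect_equal(km$survival, c(1, 3 / 4, 3 / 4 * 1 / 3, 0))
  t <- rweibull(300, 0.8, 10)
  km2 <- km_cumulative_incidence(t)
  F_emp <- ecdf(t)
  expect_equal(km2$cuminc[-1], unname(F_emp(km2$time[-1])))
  expect_true(all(diff(km2$cuminc) >= 0))
  expect_equal(km2$cuminc[1], 0)
  expect_equal(km2$cuminc[nrow(km2)], 1)
  expect_error(km_cumulative_incidence(numeric(0)), "no records")
})

test_that("right-censored records reduce the cumulative incidence", {
  km <- km_cumulative_incidence(c(1, 2, 2, 5), status = c(1, 1, 1, 0))
  expect_lt(max(km$cuminc), 1)
  expect_equal(km$n_censor[km$time == 5], 1)
})
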