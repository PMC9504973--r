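onePair <- function(onset, starts, drug = "d", pt = "e") {
  df <- data.frame(case_id = "A", drug_name = drug, pt = pt,
                   involvement = "suspect", onset_date = onset,
                   outcome = "unclear", stringsAsFactors = FALSE)
  df$start_dates <- list(starts)
  new("PairTable", pairs = df, suspectOnly = TRUE, nCases = 1L)
}

test_that("onset days follow the half-day convention and the cap", {
  # same-day onset -> 0.5 d
  od <- onsetDays(onePair("20200101", "20200101"))
  expect_equal(od$observations$days, 0.5)
  # nine days later -> 9.5 d
  od <- onsetDays(onePair("20200110", "20200101"))
  expect_equal(od$observations$days, 9.5)
  # beyond two years -> excluded with the cap reason
  od <- onsetDays(onePair("20200601", "20180101"))
  expect_equal(nrow(od$observations), 0)
  expect_equal(od$exclusions$reason, "exceeds_cap")
  # exactly at the cap boundary: 730-day difference gives 730.5 -> out
  od <- onsetDays(onePair("20200101", as.character(20200101 - 10000 * 2)))
  expect_equal(od$exclusions$reason, "exceeds_cap")
  # 729 days -> 729.5, retained
  d0 <- as.Date("2020-01-01") - 729
  od <- onsetDays(onePair("20200101", format(d0, "%Y%m%d")))
  expect_equal(od$observations$days, 729.5)
})

test_that("multi-dose cases use the earliest start on or before onset", {
  starts <- c("20200101", "20200301")
  od <- onsetDays(onePair("20200305", starts))
  expect_equal(od$observations$days, 64.5)   # from 2020-01-01
  od <- onsetDays(onePair("20200305", starts), startRule = "latest")
  expect_equal(od$observations$days, 4.5)    # from 2020-03-01
  # starts after the onset cannot be chosen
  od <- onsetDays(onePair("20191231", starts))
  expect_equal(od$exclusions$reason, "no_start_on_or_before_onset")
})

test_that("reduced-precision dates are excluded with a reason", {
  od <- onsetDays(onePair("202001", "20200101"))
  expect_equal(od$exclusions$reason, "onset_not_day_precision")
  od <- onsetDays(onePair("20200110", "202001"))
  expect_equal(od$exclusions$reason, "no_day_precision_start")
  # a month-precision start is skipped, a day-precision one used
  od <- onsetDays(onePair("20200110", c("202001", "20200105")))
  expect_equal(od$observations$days, 5.5)
})

test_that("observations plus exclusions account for every pair", {
  g <- generateSrs(generatorConfig(
    nCases = 3000, missingDateRate = 0.3,
    planted = list(plantedAssociation("drug_a", "event_common",
                                      targetRor = 4)),
    seed = 5))
  pairs <- buildPairs(g$db)
  od <- onsetDays(pairs, drug = "drug_a", pt = "event_common")
  nPairs <- sum(pairData(pairs)$drug_name == "drug_a" &
                  pairData(pairs)$pt == "event_common")
  expect_equal(nrow(od$observations) + nrow(od$exclusions), nPairs)
  expect_true(all(od$observations$days >= 0.5 &
                    od$observations$days <= 730))
})

test_that("median and IQR match a sort-based quantile oracle", {
  expect_equal(summarizeTto(0.5),
               list(median = 0.5, q1 = 0.5, q3 = 0.5, n = 1L))
  s <- summarizeTto(c(0.5, 1.5, 7.5))
  expect_equal(s$median, 1.5)
  # oracle: type-7 quantile by hand on sorted values
  set.seed(3)
  x <- round(rweibull(200, 1.3, 50)) + 0.5
  s <- summarizeTto(x)
  xs <- sort(x)
  manual <- function(p) {
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(s$median, manual(0.5))
  expect_equal(s$q1, manual(0.25))
  expect_equal(s$q3, manual(0.75))
  expect_error(summarizeTto(numeric()), class = "pv_estimate_error")
})

test_that("Weibull MLE is scale-equivariant and handles special cases", {
  set.seed(9)
  t <- rweibull(150, shape = 1.4, scale = 40)
  f1 <- weibullParams(weibullFit(t))
  f2 <- weibullParams(weibullFit(t * 3))
  expect_equal(f2$alpha, 3 * f1$alpha, tolerance = 1e-5)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-5)

  # exponential data: shape CI contains 1
  set.seed(10)
  fe <- weibullParams(weibullFit(rexp(500, 1 / 30)))
  expect_lt(fe$betaCi[1], 1)
  expect_gt(fe$betaCi[2], 1)
  expect_equal(fe$beta, 1, tolerance = 0.15)

  # agreement with an independent MLE implementation
  skip_if_not_installed("fitdistrplus")
  fd <- fitdistrplus::fitdist(t, "weibull")
  expect_equal(f1$beta, unname(fd$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f1$alpha, unname(fd$estimate["scale"]), tolerance = 1e-3)
  # and our optimum is at least as good in log-likelihood
  expect_gte(f1$logLik, fd$loglik - 1e-6)

  # degenerate sample: shape driven to the documented bound, CIs
  # unavailable, classification neutral
  fdeg <- weibullParams(weibullFit(rep(10, 20)))
  expect_equal(fdeg$beta, 50, tolerance = 1e-3)
  expect_true(all(is.na(fdeg$betaCi)))
  expect_equal(fdeg$failureType, "random")

  expect_error(weibullFit(c(1, 2)), class = "pv_insufficient_data")
  expect_error(weibullFit(c(0, 1, 2)), class = "pv_estimate_error")
})

test_that("fitted median agrees with the empirical median at scale", {
  set.seed(12)
  t <- rweibull(4000, shape = 1.3, scale = 50)
  f <- weibullParams(weibullFit(t))
  fittedMedian <- f$alpha * log(2)^(1 / f$beta)
  expect_equal(fittedMedian, median(t), tolerance = 0.05)
})

test_that("failure types follow the shape-parameter CI rule", {
  expect_equal(classifyFailureType(c(0.41, 0.70)), "early_failure")
  expect_equal(classifyFailureType(c(1.21, 1.73)), "wear_out")
  expect_equal(classifyFailureType(c(0.88, 1.88)), "random")
  # boundary: a CI touching 1 shows no demonstrated trend
  expect_equal(classifyFailureType(c(1.0, 1.5)), "random")
  # a fitted object classifies through its own CI
  set.seed(13)
  f <- weibullFit(rweibull(400, shape = 0.5, scale = 10))
  expect_equal(classifyFailureType(f), "early_failure")
})
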