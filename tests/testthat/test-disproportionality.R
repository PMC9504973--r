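# independent evaluation of the Woolf formulas, written in log space so
# the test does not share code paths with the implementation
oracleRor <- function(a, b, c, d, level = 0.05) {
  lro <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - level / 2)
  c(ror = exp(lro), lo = exp(lro - z * se), hi = exp(lro + z * se))
}

test_that("contingency cells partition the pair table", {
  pairs <- buildPairs(tinyDb())
  ct <- contingencyTable(pairs, "olaparib", "Anaemia")
  expect_equal(ct@a, 2)
  expect_equal(ct@a + ct@b + ct@c + ct@d, nrow(pairData(pairs)))
  # a drug with no reports: a = b = 0
  ct0 <- contingencyTable(pairs, "no_such_drug", "Anaemia")
  expect_equal(ct0@a + ct0@b, 0)
  expect_equal(ct0@c + ct0@d, nrow(pairData(pairs)))
})

test_that("ROR point estimate and Woolf CI match frozen hand values", {
  # balanced table: ROR 1, CI symmetric about 1 on the log scale
  ctEq <- new("ContingencyTable", drug = "D", pt = "E",
              a = 10, b = 10, c = 10, d = 10)
  est <- rorEstimate(ctEq)
  expect_equal(est$ror, 1)
  expect_equal(est$ciLow * est$ciHigh, 1, tolerance = 1e-12)

  # a=20 b=80 c=100 d=900: ROR 2.25, CI (1.322026, 3.829351)
  ct <- new("ContingencyTable", drug = "D", pt = "E",
            a = 20, b = 80, c = 100, d = 900)
  est <- rorEstimate(ct)
  expect_equal(est$ror, 2.25, tolerance = 1e-12)
  expect_equal(est$ciLow, 1.3220262, tolerance = 1e-6)
  expect_equal(est$ciHigh, 3.8293513, tolerance = 1e-6)
})

test_that("zero cells engage the continuity correction", {
  ct <- new("ContingencyTable", drug = "D", pt = "E",
            a = 1, b = 0, c = 0, d = 0)
  est <- rorEstimate(ct)
  expect_true(is.finite(est$ror) && est$ror > 0)
  expect_true(is.finite(est$ciLow) && is.finite(est$ciHigh))
  # matches the oracle on the corrected cells
  o <- oracleRor(1.5, 0.5, 0.5, 0.5)
  expect_equal(est$ror, unname(o["ror"]), tolerance = 1e-12)
  # an all-zero table is undefined
  ct0 <- new("ContingencyTable", drug = "D", pt = "E",
             a = 0, b = 0, c = 0, d = 0)
  expect_error(rorEstimate(ct0), class = "pv_estimate_error")
})

test_that("ROR is transpose-invariant and monotone in the cells", {
  set.seed(20)
  for (i in 1:50) {
    cells <- sample(1:200, 4, replace = TRUE)
    mk <- function(a, b, c, d) new("ContingencyTable", drug = "D",
                                   pt = "E", a = a, b = b, c = c, d = d)
    base <- rorEstimate(mk(cells[1], cells[2], cells[3], cells[4]))$ror
    swapped <- rorEstimate(mk(cells[1], cells[3], cells[2],
                              cells[4]))$ror
    expect_equal(base, swapped, tolerance = 1e-12)
    expect_gt(rorEstimate(mk(cells[1] + 1, cells[2], cells[3],
                             cells[4]))$ror, base)
    expect_lt(rorEstimate(mk(cells[1], cells[2] + 1, cells[3],
                             cells[4]))$ror, base)
    expect_lt(rorEstimate(mk(cells[1], cells[2], cells[3] + 1,
                             cells[4]))$ror, base)
    expect_gt(rorEstimate(mk(cells[1], cells[2], cells[3],
                             cells[4] + 1))$ror, base)
  }
})

test_that("signal detection screens rare terms and sorts by ROR", {
  # hand-built pair table: event_x is hugely disproportional for
  # drug_t but has only 9 cases -> screened out, never a signal
  mkPairs <- function(n, drug, pt) data.frame(
    case_id = sprintf("%s_%s_%03d", drug, pt, seq_len(n)),
    drug_name = drug, pt = pt, involvement = "suspect",
    onset_date = "", outcome = "unclear", stringsAsFactors = FALSE)
  df <- rbind(mkPairs(9, "drug_t", "event_x"),
              mkPairs(40, "drug_t", "event_y"),
              mkPairs(5, "drug_o", "event_x"),
              mkPairs(2000, "drug_o", "event_y"),
              mkPairs(1500, "drug_o", "event_z"))
  df$start_dates <- rep(list(character()), nrow(df))
  pairs <- new("PairTable", pairs = df, suspectOnly = TRUE,
               nCases = nrow(df))
  res <- detectSignals(pairs, "drug_t", minCases = 10)
  xRow <- res[res$pt == "event_x", ]
  expect_true(xRow$screened_out)
  expect_false(xRow$is_signal)
  expect_gt(xRow$ror, 10)          # large ROR, still not a signal
  expect_equal(res$pt[1], "event_x")  # sorted by descending ROR
  yRow <- res[res$pt == "event_y", ]
  expect_false(yRow$screened_out)
  # signal flag consistent with the CI rule
  expect_equal(yRow$is_signal, yRow$ci_low > 1)
  # cells: a + b = drug reports
  expect_equal(xRow$cases + xRow$non_cases, 49)
})
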