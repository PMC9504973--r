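#' Published PARP-inhibitor signal table (verbatim transcription)
#'
#' The published disproportionality table for olaparib (22 preferred
#' terms) and niraparib (11 terms): reported cases, non-cases, reporting
#' rate, ROR and 95% CI exactly as printed. Used to validate the
#' report arithmetic (rate = 100 a / (a+b)) and the signal rule (lower
#' CI bound > 1) against an external reference, since the underlying
#' case-level database is not redistributable.
#'
#' @return data.frame with columns \code{drug}, \code{pt},
#'   \code{cases}, \code{non_cases}, \code{rate_pct} (character, as
#'   printed, trailing zeros trimmed), \code{ror}, \code{ci_low},
#'   \code{ci_high}.
#' @export
table1Fixture <- function() {
  ola <- data.frame(
    drug = "olaparib",
    pt = c("Malignant neoplasm progression", "Anaemia",
           "Myelodysplastic syndrome", "Fatigue",
           "Acute myeloid leukaemia", "Ileus", "Myelosuppression",
           "Nausea", "Neutrophil count decreased",
           "Interstitial lung disease", "Malaise", "Pancytopenia",
           "Death", "Platelet count decreased", "Vomiting",
           "Neutropenia", "Haemoglobin decreased", "Renal impairment",
           "Decreased appetite", "Pyrexia", "Febrile neutropenia",
           "White blood cell count decreased"),
    cases = c(242, 496, 30, 10, 12, 14, 33, 34, 63, 90, 15, 20, 14, 49,
              15, 24, 11, 17, 11, 17, 12, 14),
    non_cases = c(1310, 1056, 1522, 1542, 1540, 1538, 1519, 1518, 1489,
                  1462, 1537, 1532, 1538, 1503, 1537, 1528, 1541, 1535,
                  1541, 1535, 1540, 1538),
    rate_pct = c("15.59", "31.96", "1.93", "0.64", "0.77", "0.9",
                 "2.13", "2.19", "4.06", "5.8", "0.97", "1.29", "0.9",
                 "3.16", "0.97", "1.55", "0.71", "1.1", "0.71", "1.1",
                 "0.77", "0.9"),
    ror = c(73.50, 40.50, 11.71, 6.46, 6.33, 5.24, 3.83, 3.47, 2.85,
            2.19, 2.03, 2.02, 1.87, 1.83, 1.77, 1.38, 1.35, 1.02, 0.93,
            0.79, 0.74, 0.67),
    ci_low = c(63.90, 36.37, 8.15, 3.47, 3.58, 3.09, 2.71, 2.47, 2.21,
               1.77, 1.22, 1.30, 1.10, 1.38, 1.06, 0.92, 0.75, 0.63,
               0.51, 0.49, 0.42, 0.40),
    ci_high = c(84.55, 45.09, 16.84, 12.06, 11.18, 8.88, 5.40, 4.88,
                3.67, 2.71, 3.38, 3.14, 3.17, 2.43, 2.95, 2.06, 2.44,
                1.65, 1.68, 1.27, 1.31, 1.14),
    stringsAsFactors = FALSE)
  nir <- data.frame(
    drug = "niraparib",
    pt = c("Ovarian cancer recurrent", "Ovarian cancer",
           "Disease progression", "Thrombocytopenia", "Ileus",
           "Condition aggravated", "Platelet count decreased",
           "Renal impairment", "Anaemia", "Myelosuppression",
           "Neutrophil count decreased"),
    cases = c(26, 35, 57, 44, 11, 10, 75, 41, 39, 15, 25),
    non_cases = c(523, 514, 492, 505, 538, 539, 474, 508, 510, 534, 524),
    rate_pct = c("4.74", "6.38", "10.38", "8.01", "2", "1.82", "13.66",
                 "7.47", "7.1", "2.73", "4.55"),
    ror = c(1917.13, 500.61, 101.85, 13.60, 11.99, 10.11, 8.90, 7.45,
            6.46, 4.94, 3.21),
    ci_low = c(1182.47, 348.02, 77.17, 9.99, 6.60, 5.40, 6.98, 5.42,
               4.66, 2.96, 2.15),
    ci_high = c(3108.217, 720.11, 134.42, 18.52, 21.80, 18.91, 11.35,
                10.24, 8.95, 8.26, 4.80),
    stringsAsFactors = FALSE)
  rbind(ola, nir)
}

#' Published post-event outcome tables (verbatim transcription)
#'
#' Outcome counts and printed percentages for the signalled terms of
#' both drugs. One row per (drug, term, category) with the count and
#' the percentage as printed; used to validate the package's
#' percentage arithmetic and rounding against an external reference.
#' A handful of printed cells are internally inconsistent (apparent
#' truncation or transcription slips in the source); the arithmetic
#' reproduction test documents and tolerates them.
#'
#' @return data.frame with columns \code{drug}, \code{pt}, \code{n},
#'   \code{category}, \code{count}, \code{printed_pct}.
#' @export
outcomeFixture <- function() {
  cats <- c("recovered", "remission", "not_recovered", "with_sequelae",
            "death", "unclear")
  row <- function(drug, pt, n, counts, pcts) {
    data.frame(drug = drug, pt = pt, n = n, category = cats,
               count = counts, printed_pct = pcts,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    row("olaparib", "Anaemia", 496, c(223, 93, 46, 0, 1, 133),
        c(45.0, 18.8, 9.2, 0, 0.2, 26.8)),
    row("olaparib", "Myelodysplastic syndrome", 30, c(0, 1, 14, 0, 8, 7),
        c(0, 3.3, 46.7, 0, 26.7, 23.3)),
    row("olaparib", "Acute myeloid leukaemia", 12, c(0, 0, 3, 0, 6, 3),
        c(0, 0, 25.0, 0, 50.0, 25.0)),
    row("olaparib", "Myelosuppression", 33, c(12, 2, 2, 0, 0, 17),
        c(36.3, 6.1, 6.1, 0, 0, 51.5)),
    row("olaparib", "Neutrophil count decreased", 63, c(23, 8, 3, 0, 0, 29),
        c(36.5, 12.7, 4.8, 0, 0, 46.0)),
    row("olaparib", "Platelet count decreased", 49, c(26, 8, 3, 0, 2, 10),
        c(53.1, 16.3, 6.1, 0, 4.1, 20.4)),
    row("olaparib", "Pancytopenia", 20, c(8, 4, 1, 0, 0, 7),
        c(40.0, 20.0, 5.0, 0, 0, 35.0)),
    row("olaparib", "Ileus", 14, c(2, 1, 1, 0, 0, 10),
        c(14.3, 7.1, 7.1, 0, 0, 71.5)),
    row("olaparib", "Nausea", 34, c(14, 6, 7, 0, 0, 7),
        c(41.2, 17.6, 20.6, 0, 0, 20.6)),
    row("olaparib", "Vomiting", 15, c(6, 4, 2, 0, 0, 3),
        c(40.0, 26.7, 13.3, 0, 0, 20.0)),
    row("olaparib", "Malignant neoplasm progression", 242,
        c(0, 0, 1, 0, 32, 209), c(0, 0, 0.4, 0, 13.2, 86.4)),
    row("olaparib", "Fatigue", 5, c(4, 0, 1, 0, 0, 0),
        c(80.0, 0, 20.0, 0, 0, 0)),
    row("olaparib", "Interstitial lung disease", 90,
        c(37, 31, 2, 2, 0, 18), c(41.1, 34.5, 2.2, 2.2, 0, 20.0)),
    row("olaparib", "Malaise", 15, c(7, 3, 2, 0, 0, 3),
        c(46.7, 20.0, 13.3, 0, 0, 20.0)),
    row("olaparib", "Death", 14, c(0, 0, 0, 0, 14, 0),
        c(0, 0, 0, 0, 100.0, 0)),
    row("niraparib", "Thrombocytopenia", 44, c(20, 7, 8, 0, 0, 9),
        c(45.4, 15.9, 18.2, 0, 0, 20.5)),
    row("niraparib", "Platelet count decreased", 75,
        c(36, 13, 17, 0, 0, 9), c(48.0, 17.3, 22.7, 0, 0, 12.0)),
    row("niraparib", "Anaemia", 39, c(14, 10, 8, 0, 0, 7),
        c(35.9, 25.6, 20.5, 0, 0, 18.0)),
    row("niraparib", "Myelosuppression", 15, c(2, 1, 2, 0, 0, 10),
        c(13.3, 6.7, 13.3, 0, 0, 66.7)),
    row("niraparib", "Neutrophil count decreased", 25,
        c(12, 5, 6, 0, 0, 2), c(48.0, 20.0, 24.0, 0, 0, 8.0)),
    row("niraparib", "Ileus", 11, c(3, 1, 4, 0, 0, 3),
        c(27.3, 9.1, 36.3, 0, 0, 27.3)),
    row("niraparib", "Ovarian cancer recurrent", 26,
        c(1, 1, 7, 0, 2, 15), c(3.8, 3.8, 27.0, 0, 7.7, 57.7)),
    row("niraparib", "Ovarian cancer", 35, c(1, 1, 15, 0, 3, 15),
        c(2.8, 2.8, 42.9, 0, 8.6, 42.9)),
    row("niraparib", "Disease progression", 57, c(2, 3, 21, 0, 4, 28),
        c(3.5, 3.5, 36.8, 0, 7.0, 49.2)),
    row("niraparib", "Condition aggravated", 10, c(0, 0, 4, 0, 2, 4),
        c(0, 0, 40.0, 0, 20.0, 40.0)),
    row("niraparib", "Renal impairment", 41, c(8, 3, 13, 0, 0, 17),
        c(19.5, 7.3, 31.7, 0, 0, 41.5))))
}

#' Published Weibull time-to-onset parameters (verbatim transcription)
#'
#' Scale and shape estimates with 95% CIs for the signalled terms of
#' both drugs. The shape CIs drive the failure-type classification
#' tests; the case-level onset data behind the fits are not published,
#' so the estimates themselves serve as reference context, not as
#' reproduction targets.
#'
#' @return data.frame with columns \code{drug}, \code{pt}, \code{n},
#'   \code{alpha}, \code{alpha_low}, \code{alpha_high}, \code{beta},
#'   \code{beta_low}, \code{beta_high}.
#' @export
weibullFixture <- function() {
  ola <- data.frame(
    drug = "olaparib",
    pt = c("Anaemia", "Myelodysplastic syndrome",
           "Acute myeloid leukaemia", "Myelosuppression",
           "Neutrophil count decreased", "Platelet count decreased",
           "Pancytopenia", "Ileus", "Nausea", "Vomiting",
           "Malignant neoplasm progression", "Fatigue",
           "Interstitial lung disease", "Malaise", "Death"),
    n = c(327, 18, 4, 15, 31, 41, 14, 5, 27, 14, 24, 8, 67, 13, 2),
    alpha = c(84.54, 361.28, 363.24, 74.67, 55.16, 60.93, 118.11,
              65.97, 9.60, 6.68, 187.71, 34.74, 151.25, 35.78, 397.34),
    alpha_low = c(76.42, 241.26, 181.38, 40.29, 33.81, 40.87, 68.90,
                  21.34, 4.39, 2.04, 134.30, 14.52, 126.37, 13.60,
                  210.89),
    alpha_high = c(93.39, 527.09, 708.13, 134.06, 88.03, 89.39, 196.54,
                   193.61, 20.21, 20.49, 257.64, 79.09, 179.90, 88.19,
                   772.73),
    beta = c(1.15, 1.33, 2.06, 0.96, 0.80, 0.85, 1.13, 1.08, 0.54,
             0.51, 1.35, 0.98, 1.46, 0.67, 4.17),
    beta_low = c(1.06, 0.88, 0.77, 0.60, 0.60, 0.67, 0.74, 0.45, 0.41,
                 0.34, 0.97, 0.53, 1.21, 0.41, 0.91),
    beta_high = c(1.24, 1.88, 4.21, 1.40, 1.03, 1.04, 1.59, 2.09, 0.70,
                  0.72, 1.81, 1.57, 1.73, 1.01, 11.26),
    stringsAsFactors = FALSE)
  nir <- data.frame(
    drug = "niraparib",
    pt = c("Thrombocytopenia", "Platelet count decreased", "Anaemia",
           "Myelosuppression", "Neutrophil count decreased", "Ileus",
           "Ovarian cancer recurrent", "Ovarian cancer",
           "Disease progression", "Condition aggravated",
           "Renal impairment"),
    n = c(34, 65, 30, 8, 23, 10, 20, 28, 43, 8, 32),
    alpha = c(46.55, 53.20, 49.45, 57.31, 47.37, 53.39, 41.94, 67.74,
              55.77, 50.81, 46.34),
    alpha_low = c(32.96, 43.52, 35.05, 30.39, 32.47, 36.08, 30.03,
                  47.49, 42.50, 29.50, 31.42),
    alpha_high = c(64.74, 64.62, 68.73, 103.86, 66.99, 77.07, 57.51,
                   95.05, 72.42, 84.69, 67.17),
    beta = c(1.08, 1.31, 1.16, 1.34, 1.24, 1.90, 1.50, 1.17, 1.21,
             1.56, 0.99),
    beta_low = c(0.82, 1.07, 0.86, 0.74, 0.87, 1.12, 1.05, 0.85, 0.95,
                 0.87, 0.75),
    beta_high = c(1.37, 1.57, 1.50, 2.11, 1.67, 2.88, 2.01, 1.53, 1.49,
                  2.44, 1.27),
    stringsAsFactors = FALSE)
  rbind(ola, nir)
}
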