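#' @include AllClasses.R
NULL

#' Build the 2x2 contingency table for one drug-event pair
#'
#' Cells are counted on the report (case-PT pair) unit: \code{a} =
#' pairs with the target drug and target event, \code{b} = pairs with
#' the target drug and any other event, \code{c} = pairs with the
#' target event under any other drug, \code{d} = all remaining pairs.
#' The four cells always sum to the size of the pair table, and
#' \code{a + b} is the total number of adverse-event reports for the
#' target drug.
#'
#' @param pairs a [PairTable-class].
#' @param drug target drug name.
#' @param pt target preferred term.
#' @return a [ContingencyTable-class].
#' @export
contingencyTable <- function(pairs, drug, pt) {
  df <- pairData(pairs)
  isDrug <- df$drug_name == drug
  isPt <- df$pt == pt
  new("ContingencyTable", drug = drug, pt = pt,
      a = sum(isDrug & isPt), b = sum(isDrug & !isPt),
      c = sum(!isDrug & isPt), d = sum(!isDrug & !isPt))
}

# vectorised core shared by rorEstimate and detectSignals.
# Returns ror and Woolf CI; with the Haldane-Anscombe policy, 0.5 is
# added to every cell (of a table containing a zero) before both the
# point estimate and the interval.
.rorWoolf <- function(a, b, c, d, alphaLevel = 0.05,
                      zeroCellPolicy = c("haldane", "none")) {
  zeroCellPolicy <- match.arg(zeroCellPolicy)
  if (any(a + b + c + d == 0))
    pvStop("pv_estimate_error",
           "all four contingency cells are zero; ROR undefined")
  if (zeroCellPolicy == "haldane") {
    z0 <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * z0; b <- b + 0.5 * z0
    c <- c + 0.5 * z0; d <- d + 0.5 * z0
  }
  z <- stats::qnorm(1 - alphaLevel / 2)
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror,
       ciLow = exp(log(ror) - z * se),
       ciHigh = exp(log(ror) + z * se))
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' Computes the ROR \eqn{(a d)/(b c)} and its Woolf (log-normal)
#' interval \eqn{\exp(\ln ROR \pm z_{1-\alpha/2}
#' \sqrt{1/a + 1/b + 1/c + 1/d})}. When any cell is zero and the
#' Haldane-Anscombe policy is active (the default), 0.5 is added to all
#' four cells before both formulas, keeping the estimate finite.
#'
#' @param x a [ContingencyTable-class].
#' @param alphaLevel two-sided significance level (default 0.05 for a
#'   95% interval).
#' @param zeroCellPolicy \code{"haldane"} (add 0.5 to every cell when
#'   any cell is zero) or \code{"none"}.
#' @return list with elements \code{ror}, \code{ciLow}, \code{ciHigh}.
#' @examples
#' ct <- new("ContingencyTable", drug = "D", pt = "E",
#'           a = 20, b = 80, c = 100, d = 900)
#' rorEstimate(ct)  # ror 2.25, CI about (1.32, 3.83)
#' @export
rorEstimate <- function(x, alphaLevel = 0.05,
                        zeroCellPolicy = c("haldane", "none")) {
  .rorWoolf(x@a, x@b, x@c, x@d, alphaLevel, zeroCellPolicy)
}

#' Detect disproportionality signals for one drug
#'
#' Evaluates every preferred term reported with the drug: builds the
#' 2x2 table, computes the ROR and Woolf 95% CI, and flags a signal
#' when the lower confidence bound exceeds 1. Terms with fewer than
#' \code{minCases} reports are screened out: they are listed with
#' \code{screened_out = TRUE} and can never be signals, mirroring the
#' usual practice of only interpreting RORs with a minimum case count.
#'
#' @param pairs a [PairTable-class].
#' @param drug target drug name.
#' @param minCases minimum number of reported cases for signal
#'   eligibility (default 10).
#' @param alphaLevel significance level for the CI (default 0.05).
#' @param zeroCellPolicy passed to the ROR computation.
#' @return data.frame sorted by decreasing ROR with columns
#'   \code{drug}, \code{pt}, \code{cases} (= a), \code{non_cases}
#'   (= b), \code{rate_pct} (100 a / (a+b)), \code{ror},
#'   \code{ci_low}, \code{ci_high}, \code{is_signal},
#'   \code{screened_out}.
#' @export
detectSignals <- function(pairs, drug, minCases = 10, alphaLevel = 0.05,
                          zeroCellPolicy = c("haldane", "none")) {
  df <- pairData(pairs)
  out0 <- data.frame(drug = character(), pt = character(),
                     cases = integer(), non_cases = integer(),
                     rate_pct = numeric(), ror = numeric(),
                     ci_low = numeric(), ci_high = numeric(),
                     is_signal = logical(), screened_out = logical(),
                     stringsAsFactors = FALSE)
  isDrug <- df$drug_name == drug
  if (!any(isDrug)) return(out0)
  nTotal <- nrow(df)
  nDrug <- sum(isDrug)
  aTab <- table(df$pt[isDrug])
  ptAll <- table(df$pt)
  pts <- names(aTab)
  a <- as.numeric(aTab)
  b <- nDrug - a
  c <- as.numeric(ptAll[pts]) - a
  d <- nTotal - nDrug - c
  est <- .rorWoolf(a, b, c, d, alphaLevel, zeroCellPolicy)
  screened <- a < minCases
  res <- data.frame(drug = drug, pt = pts,
                    cases = as.integer(a), non_cases = as.integer(b),
                    rate_pct = 100 * a / (a + b),
                    ror = est$ror, ci_low = est$ciLow,
                    ci_high = est$ciHigh,
                    is_signal = est$ciLow > 1 & !screened,
                    screened_out = screened,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$ror, res$pt, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a signal report as TSV (and optionally JSON)
#'
#' Columns mirror the conventional report layout: cases, non-cases,
#' rate in percent, ROR with CI bounds, signal flag. ROR/CI and rate
#' are rounded half-up to 2 decimals for display; underlying values
#' keep full precision in the JSON output.
#'
#' @param signals data.frame from [detectSignals()].
#' @param path output TSV path.
#' @param json optional path for a full-precision JSON copy.
#' @return invisibly, \code{path}.
#' @export
writeSignals <- function(signals, path, json = NULL) {
  disp <- signals
  for (cc in c("rate_pct", "ror", "ci_low", "ci_high"))
    disp[[cc]] <- sprintf("%.2f", roundHalfUp(disp[[cc]], 2))
  utils::write.table(disp, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(json))
    jsonlite::write_json(signals, json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
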