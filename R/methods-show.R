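setMethod("demoTable", "SrsDatabase", function(x) x@demo)
setMethod("drugTable", "SrsDatabase", function(x) x@drug)
setMethod("reacTable", "SrsDatabase", function(x) x@reac)
setMethod("histTable", "SrsDatabase", function(x) x@hist)

setMethod("pairData", "PairTable", function(x) x@pairs)

setMethod("show", "SrsDatabase", function(object) {
  cat("SrsDatabase with", nrow(object@demo), "cases\n")
  cat("  DEMO:", nrow(object@demo), "rows | DRUG:", nrow(object@drug),
      "rows | REAC:", nrow(object@reac), "rows | HIST:",
      nrow(object@hist), "rows\n")
  nd <- length(unique(object@drug$drug_name))
  np <- length(unique(object@reac$pt))
  cat("  ", nd, "distinct drugs,", np, "distinct preferred terms\n")
})

setMethod("show", "PairTable", function(object) {
  cat("PairTable:", nrow(object@pairs), "(case, drug, PT) pairs from",
      object@nCases, "cases",
      if (object@suspectOnly) "[suspect drugs only]\n" else "\n")
})

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("2x2 contingency table for drug '%s' x event '%s'\n",
              object@drug, object@pt))
  m <- matrix(c(object@a, object@c, object@b, object@d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
})

setMethod("show", "WeibullFit", function(object) {
  cat(sprintf("Weibull time-to-onset fit (n = %d)\n", object@n))
  cat(sprintf("  scale alpha: %.2f days (%.0f%% CI %.2f-%.2f)\n",
              object@alpha, 100 * object@level,
              object@alphaCi[1], object@alphaCi[2]))
  cat(sprintf("  shape beta:  %.2f      (%.0f%% CI %.2f-%.2f)\n",
              object@beta, 100 * object@level,
              object@betaCi[1], object@betaCi[2]))
  cat(sprintf("  failure type: %s\n", object@failureType))
  cat(sprintf("  raw days: median %.1f (IQR %.1f-%.1f)\n",
              object@medianDays, object@iqrDays[1], object@iqrDays[2]))
})

#' @describeIn classifyFailureType classify from a numeric (low, high)
#'   shape-parameter confidence interval.
#' @export
setMethod("classifyFailureType", "numeric", function(x) {
  stopifnot(length(x) == 2)
  if (anyNA(x)) return("random")
  if (x[2] < 1) "early_failure"
  else if (x[1] > 1) "wear_out"
  else "random"
})

#' @describeIn classifyFailureType classify a fitted model.
#' @export
setMethod("classifyFailureType", "WeibullFit", function(x)
  classifyFailureType(x@betaCi))
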