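#' @rdname SrsDatabase-class
#' @param x an object.
#' @export
setGeneric("demoTable", function(x) standardGeneric("demoTable"))
#' @rdname SrsDatabase-class
#' @export
setGeneric("drugTable", function(x) standardGeneric("drugTable"))
#' @rdname SrsDatabase-class
#' @export
setGeneric("reacTable", function(x) standardGeneric("reacTable"))
#' @rdname SrsDatabase-class
#' @export
setGeneric("histTable", function(x) standardGeneric("histTable"))

#' @rdname PairTable-class
#' @param x an object.
#' @export
setGeneric("pairData", function(x) standardGeneric("pairData"))

#' Build the (case, drug, event) pair table
#'
#' @param x an [SrsDatabase-class] or the case list from [linkCases()].
#' @param suspectOnly if TRUE (default) only drug records coded as
#'   suspect contribute pairs, matching the convention of conditioning
#'   disproportionality on the suspect drug.
#' @return a [PairTable-class].
#' @export
setGeneric("buildPairs", function(x, suspectOnly = TRUE)
  standardGeneric("buildPairs"))

#' Classify a Weibull fit by its hazard trend
#'
#' The shape parameter governs how the hazard of onset changes with time
#' on drug: shape < 1 means a decreasing hazard (events cluster early;
#' "early failure"), shape > 1 an increasing hazard ("wear-out"), and
#' shape = 1 a constant hazard. Classification is based on the 95%
#' confidence interval of the shape: early failure when the upper bound
#' is below 1, wear-out when the lower bound exceeds 1, and random
#' (no demonstrated trend) otherwise.
#'
#' @param x a [WeibullFit-class], or a numeric vector of length 2 giving
#'   the (lower, upper) confidence bounds of the shape parameter.
#' @return one of \code{"early_failure"}, \code{"random"},
#'   \code{"wear_out"}.
#' @examples
#' classifyFailureType(c(0.41, 0.70))  # early_failure
#' classifyFailureType(c(1.21, 1.73))  # wear_out
#' classifyFailureType(c(0.88, 1.88))  # random
#' @export
setGeneric("classifyFailureType", function(x)
  standardGeneric("classifyFailureType"))
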