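#' @import methods
NULL

.demoCols <- c("case_id", "sex", "age_band", "report_period")
.drugCols <- c("case_id", "drug_name", "involvement", "start_date",
               "end_date", "route")
.reacCols <- c("case_id", "pt", "onset_date", "outcome")
.histCols <- c("case_id", "disease")

#' SrsDatabase: a four-table spontaneous reporting system database
#'
#' Container for the four linked tables of a JADER-schema database --
#' DEMO (patient demographics), DRUG (drug administrations), REAC
#' (adverse events) and HIST (primary disease) -- after column names,
#' involvement codes, outcome labels and dates have been normalised to
#' the package's canonical vocabulary. Rows in DRUG/REAC/HIST whose case
#' id does not appear in DEMO are retained (they are reported as orphans
#' by [linkCases()], never silently dropped).
#'
#' @slot demo data.frame with columns case_id, sex, age_band, report_period.
#' @slot drug data.frame with columns case_id, drug_name, involvement,
#'   start_date, end_date, route.
#' @slot reac data.frame with columns case_id, pt, onset_date, outcome.
#' @slot hist data.frame with columns case_id, disease.
#' @slot dialect the dialect list the tables were read with (see
#'   [srsDialect()]).
#' @export
setClass("SrsDatabase",
  representation(demo = "data.frame", drug = "data.frame",
                 reac = "data.frame", hist = "data.frame",
                 dialect = "list"))

setValidity("SrsDatabase", function(object) {
  msgs <- character()
  chk <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      sprintf("%s table lacks column(s): %s", name,
              paste(miss, collapse = ", "))
    else character()
  }
  msgs <- c(msgs,
            chk(object@demo, .demoCols, "DEMO"),
            chk(object@drug, .drugCols, "DRUG"),
            chk(object@reac, .reacCols, "REAC"),
            chk(object@hist, .histCols, "HIST"))
  if (anyDuplicated(object@demo$case_id))
    msgs <- c(msgs, "DEMO has duplicated case_id values")
  if (nrow(object@demo) && any(!nzchar(object@demo$case_id)))
    msgs <- c(msgs, "DEMO has empty case_id values")
  if (nrow(object@reac) && any(!nzchar(object@reac$pt)))
    msgs <- c(msgs, "REAC has empty preferred-term values")
  bad <- setdiff(unique(object@reac$outcome), .outcomeLevels)
  if (length(bad))
    msgs <- c(msgs, sprintf("REAC has unknown outcome label(s): %s",
                            paste(bad, collapse = ", ")))
  bad <- setdiff(unique(object@drug$involvement), .involvementLevels)
  if (length(bad))
    msgs <- c(msgs, sprintf("DRUG has unknown involvement code(s): %s",
                            paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' PairTable: the (case, drug, event) unit-of-analysis table
#'
#' One row per distinct (case id, drug, preferred term) combination; the
#' counting unit for every downstream statistic. A case contributes at
#' most one row to a given (drug, PT) cell no matter how often the drug
#' or the term repeats within the report.
#'
#' @slot pairs data.frame with columns case_id, drug_name, pt,
#'   involvement, onset_date, outcome, and the list-column start_dates
#'   (all start dates recorded for that drug in that case, ascending).
#' @slot suspectOnly logical; whether only suspect-drug records
#'   contributed pairs.
#' @slot nCases number of cases in the source database.
#' @export
setClass("PairTable",
  representation(pairs = "data.frame", suspectOnly = "logical",
                 nCases = "integer"))

setValidity("PairTable", function(object) {
  need <- c("case_id", "drug_name", "pt", "involvement", "onset_date",
            "outcome", "start_dates")
  miss <- setdiff(need, names(object@pairs))
  if (length(miss))
    return(sprintf("pair table lacks column(s): %s",
                   paste(miss, collapse = ", ")))
  key <- paste(object@pairs$case_id, object@pairs$drug_name,
               object@pairs$pt, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate (case_id, drug_name, pt) rows in pair table")
  TRUE
})

#' ContingencyTable: 2x2 cells for one drug-event pair
#'
#' Cells follow the report-based unit: \code{a} = reports of the target
#' event with the target drug, \code{b} = other events with the target
#' drug, \code{c} = the target event with other drugs, \code{d} =
#' everything else; \code{a+b+c+d} equals the size of the pair table.
#'
#' @slot drug,pt the target drug and preferred term.
#' @slot a,b,c,d the four cell counts.
#' @export
setClass("ContingencyTable",
  representation(drug = "character", pt = "character",
                 a = "numeric", b = "numeric", c = "numeric", d = "numeric"))

setValidity("ContingencyTable", function(object) {
  cells <- c(object@a, object@b, object@c, object@d)
  if (any(cells < 0)) "cells must be non-negative" else TRUE
})

#' WeibullFit: maximum-likelihood Weibull fit to time-to-onset data
#'
#' Holds the scale (alpha, days) and shape (beta, dimensionless)
#' estimates with Wald 95% confidence intervals computed on the log
#' scale, the failure-type classification derived from the shape CI,
#' and the empirical median/IQR of the raw onset days.
#'
#' @slot alpha,beta point estimates (scale in days; shape dimensionless).
#' @slot alphaCi,betaCi numeric(2) confidence bounds (low, high).
#' @slot n number of observations fitted.
#' @slot failureType one of "early_failure", "random", "wear_out".
#' @slot medianDays empirical median of the onset days.
#' @slot iqrDays numeric(2): first and third quartile of the onset days.
#' @slot logLik maximised log-likelihood.
#' @slot level confidence level used for the intervals.
#' @export
setClass("WeibullFit",
  representation(alpha = "numeric", beta = "numeric",
                 alphaCi = "numeric", betaCi = "numeric",
                 n = "integer", failureType = "character",
                 medianDays = "numeric", iqrDays = "numeric",
                 logLik = "numeric", level = "numeric"))

setValidity("WeibullFit", function(object) {
  if (object@alpha <= 0 || object@beta <= 0)
    return("alpha and beta must be positive")
  if (!object@failureType %in% c("early_failure", "random", "wear_out"))
    return("invalid failureType")
  TRUE
})
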