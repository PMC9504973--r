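#' End-to-end analysis configuration
#'
#' @param paths named list/vector of the four input CSVs (demo, drug,
#'   reac, hist).
#' @param dialect an [srsDialect()] object or the path to a YAML
#'   dialect file.
#' @param drugs character vector of drugs to analyse.
#' @param minCases minimum case count for signal eligibility.
#' @param alphaLevel significance level for all confidence intervals.
#' @param capDays time-to-onset cap in days.
#' @param suspectOnly restrict pairs to suspect-drug records.
#' @param startRule start-date choice for multi-dose cases (see
#'   [onsetDays()]).
#' @param outDir output directory for the report bundle.
#' @return a list of class \code{"pv_run_config"}.
#' @export
runConfig <- function(paths, dialect = srsDialect(), drugs,
                      minCases = 10, alphaLevel = 0.05, capDays = 730,
                      suspectOnly = TRUE,
                      startRule = c("earliest", "latest"),
                      outDir = NULL) {
  stopifnot(minCases >= 1, capDays > 0)
  if (is.character(dialect)) dialect <- readDialect(dialect)
  structure(list(paths = paths, dialect = dialect, drugs = drugs,
                 minCases = minCases, alphaLevel = alphaLevel,
                 capDays = capDays, suspectOnly = suspectOnly,
                 startRule = match.arg(startRule), outDir = outDir),
            class = "pv_run_config")
}

#' Run the full signal-detection and time-to-onset pipeline
#'
#' Sequences the whole analysis: read and link the four tables, build
#' the pair table, detect ROR signals per requested drug, fit Weibull
#' time-to-onset models for every signalled term with at least three
#' usable onset observations, and tabulate post-event outcomes for the
#' signalled terms. Every excluded onset observation appears once in
#' the exclusion log with its reason, so the report is fully
#' accountable. When \code{outDir} is set, writes \code{signals.tsv},
#' \code{tto.tsv}, \code{outcomes.tsv}, \code{exclusions.tsv} and
#' \code{run.json} (configuration echo and per-stage row counts);
#' outputs are deterministic given the inputs.
#'
#' @param config a [runConfig()] object, or an [SrsDatabase-class]
#'   together with the remaining arguments supplied through
#'   \code{...} -- convenience for in-memory use.
#' @param ... when \code{config} is a database: arguments passed to
#'   [runConfig()] (except \code{paths}/\code{dialect}).
#' @return invisibly, a list with \code{signals}, \code{tto} (one row
#'   per fitted drug-event), \code{outcomes}, \code{exclusions} and
#'   \code{log} (per-stage counts).
#' @export
runPipeline <- function(config, ...) {
  if (is(config, "SrsDatabase")) {
    db <- config
    config <- runConfig(paths = NULL, ...)
  } else {
    stopifnot(inherits(config, "pv_run_config"))
    db <- readSrsTables(config$paths, config$dialect)
  }

  linked <- linkCases(db)
  pairs <- buildPairs(db, suspectOnly = config$suspectOnly)
  log <- list(cases = nrow(demoTable(db)),
              drug_rows = nrow(drugTable(db)),
              reac_rows = nrow(reacTable(db)),
              orphan_rows = sum(vapply(linked$orphans, nrow, 0L)),
              pairs = nrow(pairData(pairs)))

  signals <- do.call(rbind, lapply(config$drugs, function(d)
    detectSignals(pairs, d, minCases = config$minCases,
                  alphaLevel = config$alphaLevel)))
  if (is.null(signals))
    signals <- detectSignals(pairs, "", config$minCases)[0, ]

  sig <- signals[signals$is_signal, , drop = FALSE]
  ttoRows <- list()
  exclusions <- list()
  outcomes <- list()
  for (d in unique(sig$drug)) {
    ptsSig <- sig$pt[sig$drug == d]
    outcomes[[d]] <- tabulateOutcomes(pairs, d, ptsSig)
    for (p in ptsSig) {
      od <- onsetDays(pairs, drug = d, pt = p, capDays = config$capDays,
                      startRule = config$startRule)
      exclusions[[paste(d, p)]] <- od$exclusions
      if (nrow(od$observations) >= 3) {
        fit <- tryCatch(weibullFit(od$observations$days,
                                   alphaLevel = config$alphaLevel),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          w <- weibullParams(fit)
          ttoRows[[paste(d, p)]] <- data.frame(
            drug = d, pt = p, n = w$n,
            alpha = w$alpha, alpha_low = w$alphaCi[1],
            alpha_high = w$alphaCi[2],
            beta = w$beta, beta_low = w$betaCi[1],
            beta_high = w$betaCi[2],
            failure_type = w$failureType,
            median_days = w$medianDays,
            q1_days = w$iqrDays[1], q3_days = w$iqrDays[2],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  bind <- function(lst, proto) {
    out <- do.call(rbind, unname(lst))
    if (is.null(out)) proto else { rownames(out) <- NULL; out }
  }
  tto <- bind(ttoRows, data.frame(drug = character(), pt = character(),
                                  n = integer(), alpha = numeric(),
                                  alpha_low = numeric(),
                                  alpha_high = numeric(),
                                  beta = numeric(), beta_low = numeric(),
                                  beta_high = numeric(),
                                  failure_type = character(),
                                  median_days = numeric(),
                                  q1_days = numeric(),
                                  q3_days = numeric()))
  excl <- bind(exclusions, data.frame(case_id = character(),
                                      drug = character(),
                                      pt = character(),
                                      reason = character()))
  outc <- bind(outcomes, tabulateOutcomes(pairs, "", character())[0, ])
  log$signals <- sum(signals$is_signal)
  log$tto_fits <- nrow(tto)
  log$tto_exclusions <- nrow(excl)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeSignals(signals, file.path(config$outDir, "signals.tsv"))
    utils::write.table(tto, file.path(config$outDir, "tto.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
    writeOutcomes(outc, file.path(config$outDir, "outcomes.tsv"))
    utils::write.table(excl, file.path(config$outDir, "exclusions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
    meta <- list(drugs = config$drugs, min_cases = config$minCases,
                 alpha_level = config$alphaLevel,
                 cap_days = config$capDays,
                 suspect_only = config$suspectOnly,
                 start_rule = config$startRule, log = log)
    jsonlite::write_json(meta, file.path(config$outDir, "run.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(signals = signals, tto = tto, outcomes = outc,
                 exclusions = excl, log = log))
}
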