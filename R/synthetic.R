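#' @include AllClasses.R
NULL

#' Declare a planted drug-event association
#'
#' A planted association makes one (drug, PT) pair carry a known
#' reporting odds ratio and a known Weibull onset-delay distribution,
#' so the detection and time-to-onset stages can be validated against
#' ground truth.
#'
#' @param drug,pt names of a drug and preferred term declared in the
#'   generator config.
#' @param targetRor target reporting odds ratio (> 0; 1 plants a null
#'   association).
#' @param weibullAlpha,weibullBeta scale (days) and shape of the onset
#'   delay distribution for this pair.
#' @param outcomeProbs optional named probability vector over the seven
#'   outcome categories overriding the config default for this pair.
#' @return a list of class \code{"planted_association"}.
#' @export
plantedAssociation <- function(drug, pt, targetRor = 1,
                               weibullAlpha = 60, weibullBeta = 1,
                               outcomeProbs = NULL) {
  stopifnot(targetRor > 0, weibullAlpha > 0, weibullBeta > 0)
  structure(list(drug = drug, pt = pt, targetRor = targetRor,
                 weibullAlpha = weibullAlpha, weibullBeta = weibullBeta,
                 outcomeProbs = outcomeProbs),
            class = "planted_association")
}

.defaultOutcomeProbs <- c(recovered = 0.35, remission = 0.15,
                          not_recovered = 0.15, with_sequelae = 0.01,
                          death = 0.04, unclear = 0.20, missing = 0.10)

#' Configuration for the synthetic SRS database generator
#'
#' Describes a small synthetic world: each case gets one suspect drug
#' (multinomial over \code{drugs}), possibly a concomitant drug,
#' adverse events drawn per preferred term at its background
#' probability (tilted for planted pairs), onset dates placed a
#' Weibull-distributed number of days after the treatment start, and a
#' multinomial outcome. A fraction of dates is degraded to month
#' precision or removed to exercise the partial-date path, and a
#' fraction of cases receives a second, later start date for the same
#' drug (re-administration).
#'
#' The default world mimics the shape of real spontaneous-report data
#' at a testable scale: a target drug holding a few percent of reports,
#' one moderately common adverse event (2% background reporting
#' probability) and a tail of rarer ones, background onset delays with
#' a roughly constant hazard, and around 5% missing or degraded dates.
#'
#' @param nCases number of cases to generate.
#' @param drugs data.frame with columns \code{name}, \code{prob}:
#'   suspect-drug assignment probabilities (normalised internally).
#' @param pts data.frame with columns \code{name}, \code{prob}:
#'   background per-case event probabilities.
#' @param planted list of [plantedAssociation()] objects.
#' @param outcomeProbs named probability vector over the seven outcome
#'   categories (must sum to 1).
#' @param missingDateRate probability that a date field is degraded
#'   (half of the degraded dates keep year-month precision, half are
#'   removed entirely).
#' @param multiDoseRate probability that a case receives a second start
#'   date for its suspect drug.
#' @param concomitantRate probability that a case also lists a random
#'   other drug as concomitant.
#' @param dateWindow character(2), first and last treatment start date.
#' @param backgroundAlpha,backgroundBeta Weibull scale/shape of onset
#'   delays for non-planted pairs (default exponential-like, scale 60
#'   days).
#' @param seed integer RNG seed; identical seed and config give a
#'   byte-identical database.
#' @return a list of class \code{"srs_generator_config"}.
#' @export
generatorConfig <- function(nCases = 5000,
                            drugs = data.frame(
                              name = c("drug_a", "drug_b", "drug_x"),
                              prob = c(0.05, 0.15, 0.80)),
                            pts = data.frame(
                              name = c("event_common", "event_b",
                                       "event_c", "event_d", "event_e"),
                              prob = c(0.02, 0.010, 0.005, 0.002, 0.001)),
                            planted = list(),
                            outcomeProbs = .defaultOutcomeProbs,
                            missingDateRate = 0.05,
                            multiDoseRate = 0.10,
                            concomitantRate = 0.30,
                            dateWindow = c("2018-01-01", "2021-12-31"),
                            backgroundAlpha = 60,
                            backgroundBeta = 1,
                            seed = 1L) {
  stopifnot(nCases >= 1,
            all(c("name", "prob") %in% names(drugs)),
            all(c("name", "prob") %in% names(pts)),
            abs(sum(outcomeProbs) - 1) < 1e-8,
            missingDateRate >= 0, missingDateRate <= 1)
  for (pl in planted) {
    if (!pl$drug %in% drugs$name || !pl$pt %in% pts$name)
      pvStop("pv_config_error",
             "planted association (%s, %s) references an undeclared drug or term",
             pl$drug, pl$pt)
    q <- pts$prob[pts$name == pl$pt]
    # closed-form tilt (see generateSrs): tilted probability = targetRor * q
    if (pl$targetRor * q >= 1)
      pvStop("pv_config_error",
             "infeasible tilt for (%s, %s): targetRor * background = %.3f >= 1",
             pl$drug, pl$pt, pl$targetRor * q)
  }
  structure(list(nCases = as.integer(nCases), drugs = drugs, pts = pts,
                 planted = planted, outcomeProbs = outcomeProbs,
                 missingDateRate = missingDateRate,
                 multiDoseRate = multiDoseRate,
                 concomitantRate = concomitantRate,
                 dateWindow = as.Date(dateWindow),
                 backgroundAlpha = backgroundAlpha,
                 backgroundBeta = backgroundBeta,
                 seed = as.integer(seed)),
            class = "srs_generator_config")
}

# degrade a vector of Date values to partial-date strings: with
# probability `rate`, a date loses day precision (half the time) or is
# removed entirely (the other half)
.degradeDates <- function(dates, rate) {
  out <- format(dates, "%Y%m%d")
  n <- length(out)
  if (n == 0 || rate <= 0) return(out)
  hit <- stats::runif(n) < rate
  toMonth <- hit & stats::runif(n) < 0.5
  toMissing <- hit & !toMonth
  out[toMonth] <- substr(out[toMonth], 1, 6)
  out[toMissing] <- ""
  out
}

#' Generate a synthetic four-table SRS database
#'
#' Draws a database under the world described by the config (see
#' [generatorConfig()]) and returns it together with a ledger of
#' ground truth. The event probability of a planted (drug, PT) pair is
#' tilted in closed form so that the expected reporting odds ratio on
#' the report-based 2x2 table equals the target: because the off-event
#' cells (b, d) count *other* events, whose rates are untouched by the
#' tilt, the expected ROR reduces to the ratio of event probabilities
#' under exposure vs non-exposure, so the tilted probability is simply
#' \code{targetRor * background}. Onset dates are the start date plus a
#' Weibull draw rounded to whole days (real databases resolve dates to
#' the day).
#'
#' @param config an [generatorConfig()] object.
#' @return list with \code{db} (an [SrsDatabase-class]) and
#'   \code{ledger}: the realized 2x2 cells and sample ROR per planted
#'   association, per-(drug, PT) pair counts, the total pair count, and
#'   the planted parameters.
#' @export
generateSrs <- function(config) {
  stopifnot(inherits(config, "srs_generator_config"))
  withSeed(config$seed, .generateSrsImpl(config))
}

.generateSrsImpl <- function(cfg) {
  n <- cfg$nCases
  ids <- sprintf("C%06d", seq_len(n))
  drugNames <- as.character(cfg$drugs$name)
  ptNames <- as.character(cfg$pts$name)
  q <- cfg$pts$prob

  ## DEMO
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.7, 0.3))
  ageBand <- sample(c("30-39", "40-49", "50-59", "60-69", "70-79", "80-89"),
                    n, replace = TRUE,
                    prob = c(0.05, 0.15, 0.25, 0.30, 0.20, 0.05))
  windowDays <- as.numeric(cfg$dateWindow[2] - cfg$dateWindow[1])
  startDate <- cfg$dateWindow[1] + floor(stats::runif(n) * (windowDays + 1))
  reportPeriod <- paste0(format(startDate, "%Y"), "-Q",
                         (as.integer(format(startDate, "%m")) - 1) %/% 3 + 1)
  demo <- data.frame(case_id = ids, sex = sex, age_band = ageBand,
                     report_period = reportPeriod, stringsAsFactors = FALSE)

  ## suspect drug per case (multinomial), optional concomitant
  suspect <- sample(drugNames, n, replace = TRUE,
                    prob = cfg$drugs$prob / sum(cfg$drugs$prob))

  ## event matrix: n x J Bernoulli with planted tilt
  pmat <- matrix(rep(q, each = n), nrow = n)
  for (pl in cfg$planted) {
    j <- match(pl$pt, ptNames)
    rows <- suspect == pl$drug
    pmat[rows, j] <- pl$targetRor * q[j]
  }
  events <- matrix(stats::runif(n * length(ptNames)), nrow = n) < pmat

  evCase <- row(events)[events]
  evPt <- col(events)[events]
  nEv <- length(evCase)

  ## onset delays: Weibull per (suspect drug, pt), planted pairs use
  ## their own parameters
  shape <- rep(cfg$backgroundBeta, nEv)
  scale <- rep(cfg$backgroundAlpha, nEv)
  for (pl in cfg$planted) {
    j <- match(pl$pt, ptNames)
    hit <- suspect[evCase] == pl$drug & evPt == j
    shape[hit] <- pl$weibullBeta
    scale[hit] <- pl$weibullAlpha
  }
  delay <- round(stats::rweibull(nEv, shape = shape, scale = scale))
  onsetDate <- startDate[evCase] + delay

  ## outcomes: default multinomial, per-association override
  outcome <- sample(names(cfg$outcomeProbs), nEv, replace = TRUE,
                    prob = cfg$outcomeProbs)
  for (pl in cfg$planted) {
    if (is.null(pl$outcomeProbs)) next
    j <- match(pl$pt, ptNames)
    hit <- which(suspect[evCase] == pl$drug & evPt == j)
    outcome[hit] <- sample(names(pl$outcomeProbs), length(hit),
                           replace = TRUE, prob = pl$outcomeProbs)
  }

  ## ledger: realized cells per planted pair, on the report unit,
  ## before any date degradation (cells do not involve dates)
  pairDrug <- suspect[evCase]
  pairPt <- ptNames[evPt]
  pairCounts <- as.data.frame(table(drug = pairDrug, pt = pairPt),
                              stringsAsFactors = FALSE)
  names(pairCounts)[3] <- "pairs"
  pairCounts <- pairCounts[pairCounts$pairs > 0, , drop = FALSE]
  rownames(pairCounts) <- NULL
  plantedLedger <- lapply(cfg$planted, function(pl) {
    a <- sum(pairDrug == pl$drug & pairPt == pl$pt)
    b <- sum(pairDrug == pl$drug & pairPt != pl$pt)
    cc <- sum(pairDrug != pl$drug & pairPt == pl$pt)
    d <- nEv - a - b - cc
    est <- if (a + b > 0 && cc + d > 0)
      .rorWoolf(a, b, cc, d)$ror else NA_real_
    list(drug = pl$drug, pt = pl$pt, targetRor = pl$targetRor,
         weibullAlpha = pl$weibullAlpha, weibullBeta = pl$weibullBeta,
         a = a, b = b, c = cc, d = d, sampleRor = est)
  })

  ## DRUG table: suspect rows (+ re-administration), concomitant rows
  endDate <- startDate + 60 + floor(stats::runif(n) * 300)
  drug <- data.frame(case_id = ids, drug_name = suspect,
                     involvement = "suspect",
                     start_raw = startDate, end_raw = endDate,
                     route = "oral", stringsAsFactors = FALSE)
  redose <- stats::runif(n) < cfg$multiDoseRate
  if (any(redose)) {
    gap <- 30 + floor(stats::runif(sum(redose)) * 170)
    drug2 <- drug[redose, , drop = FALSE]
    drug2$start_raw <- drug2$start_raw + gap
    drug2$end_raw <- drug2$start_raw + 60
    drug <- rbind(drug, drug2)
  }
  conc <- stats::runif(n) < cfg$concomitantRate
  if (any(conc) && length(drugNames) > 1) {
    other <- vapply(suspect[conc], function(s)
      sample(setdiff(drugNames, s), 1), "")
    drugC <- data.frame(case_id = ids[conc], drug_name = other,
                        involvement = "concomitant",
                        start_raw = startDate[conc],
                        end_raw = endDate[conc], route = "oral",
                        stringsAsFactors = FALSE)
    drug <- rbind(drug, drugC)
  }
  drug <- drug[order(drug$case_id, drug$drug_name, method = "radix"), ,
               drop = FALSE]
  drug$start_date <- .degradeDates(drug$start_raw, cfg$missingDateRate)
  drug$end_date <- format(drug$end_raw, "%Y%m%d")
  drug <- drug[c("case_id", "drug_name", "involvement", "start_date",
                 "end_date", "route")]

  ## REAC table
  reac <- data.frame(case_id = ids[evCase], pt = pairPt,
                     onset_date = .degradeDates(onsetDate,
                                                cfg$missingDateRate),
                     outcome = outcome, stringsAsFactors = FALSE)
  reac <- reac[order(reac$case_id, reac$pt, method = "radix"), ,
               drop = FALSE]

  ## HIST table
  hist <- data.frame(case_id = ids,
                     disease = sample(c("ovarian cancer", "breast cancer",
                                        "prostate cancer",
                                        "pancreatic cancer"),
                                      n, replace = TRUE,
                                      prob = c(0.65, 0.25, 0.05, 0.05)),
                     stringsAsFactors = FALSE)

  db <- srsDatabase(demo, drug, reac, hist)
  ledger <- list(seed = cfg$seed, nCases = n, totalPairs = nEv,
                 planted = plantedLedger, pairCounts = pairCounts)
  list(db = db, ledger = ledger)
}

#' Write a generated database and its ledger to disk
#'
#' Writes the four CSV tables plus \code{ledger.json}; identical seed
#' and config give byte-identical files.
#'
#' @param generated output of [generateSrs()].
#' @param dir output directory.
#' @param dialect dialect for the CSV files.
#' @return invisibly, the vector of paths written.
#' @export
writeSyntheticSrs <- function(generated, dir, dialect = srsDialect()) {
  paths <- writeSrsTables(generated$db, dir, dialect)
  lpath <- file.path(dir, "ledger.json")
  jsonlite::write_json(generated$ledger, lpath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, ledger = lpath))
}
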