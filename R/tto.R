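#' @include AllClasses.R
NULL

#' Time to onset for each (case, drug, event) pair
#'
#' Computes days from treatment start to event onset as
#' \code{onset - start + 0.5} days, so a same-day onset counts as half a
#' day rather than zero. Only full-precision (day-level) dates are
#' usable: a pair whose onset date, or all of whose start dates, lack
#' day precision is excluded. When a case has several start dates for
#' the drug (re-administrations), the start substituted into the
#' formula is by default the earliest day-precision start date on or
#' before the onset (\code{startRule = "earliest"}); the alternative
#' reading, the latest such date, is available as
#' \code{startRule = "latest"}. Pairs with no start date on or before
#' the onset, and pairs whose delay exceeds \code{capDays}, are
#' excluded. Every exclusion carries a machine-readable reason, and
#' observations plus exclusions always add up to the pairs examined.
#'
#' @param pairs a [PairTable-class].
#' @param drug optional drug name to restrict to.
#' @param pt optional preferred term to restrict to.
#' @param capDays maximum delay retained, in days (default 730, i.e.
#'   onsets more than two years after the start are dropped).
#' @param startRule \code{"earliest"} (default) or \code{"latest"}
#'   qualifying start date.
#' @return list with \code{observations} (data.frame case_id, drug,
#'   pt, days) and \code{exclusions} (data.frame case_id, drug, pt,
#'   reason; reasons are \code{onset_not_day_precision},
#'   \code{no_day_precision_start}, \code{no_start_on_or_before_onset},
#'   \code{exceeds_cap}).
#' @examples
#' # same-day onset gives 0.5 days; a nine-day delay gives 9.5
#' @export
onsetDays <- function(pairs, drug = NULL, pt = NULL, capDays = 730,
                      startRule = c("earliest", "latest")) {
  startRule <- match.arg(startRule)
  df <- pairData(pairs)
  if (!is.null(drug)) df <- df[df$drug_name == drug, , drop = FALSE]
  if (!is.null(pt)) df <- df[df$pt == pt, , drop = FALSE]

  n <- nrow(df)
  days <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  if (n) {
    onset <- parsePartialDate(df$onset_date)
    for (i in seq_len(n)) {
      if (onset$precision[i] != "day") {
        reason[i] <- "onset_not_day_precision"
        next
      }
      st <- parsePartialDate(df$start_dates[[i]])
      st <- st$date[st$precision == "day"]
      if (length(st) == 0) {
        reason[i] <- "no_day_precision_start"
        next
      }
      st <- st[st <= onset$date[i]]
      if (length(st) == 0) {
        reason[i] <- "no_start_on_or_before_onset"
        next
      }
      chosen <- if (startRule == "earliest") min(st) else max(st)
      dd <- as.numeric(onset$date[i] - chosen) + 0.5
      if (dd > capDays) {
        reason[i] <- "exceeds_cap"
        next
      }
      days[i] <- dd
    }
  }
  ok <- is.na(reason)
  list(observations = data.frame(case_id = df$case_id[ok],
                                 drug = df$drug_name[ok],
                                 pt = df$pt[ok], days = days[ok],
                                 stringsAsFactors = FALSE),
       exclusions = data.frame(case_id = df$case_id[!ok],
                               drug = df$drug_name[!ok],
                               pt = df$pt[!ok], reason = reason[!ok],
                               stringsAsFactors = FALSE))
}

#' Median and interquartile range of onset days
#'
#' Empirical quantiles of the raw onset-day values (not of any fitted
#' distribution), using linear interpolation between order statistics
#' (quantile type 7, R's default).
#'
#' @param days numeric vector of onset days (must be non-empty).
#' @return list with \code{median}, \code{q1}, \code{q3}, \code{n}.
#' @export
summarizeTto <- function(days) {
  if (length(days) == 0)
    pvStop("pv_estimate_error", "no onset observations to summarise")
  q <- stats::quantile(days, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(days))
}

# negative log-likelihood of the uncensored Weibull sample in
# theta = (log alpha, log beta)
.weibullNll <- function(theta, t) {
  la <- theta[1]; lb <- theta[2]
  beta <- exp(lb)
  # (t/alpha)^beta computed in log space; clamp overflow so the bounded
  # search sees a large finite penalty instead of Inf
  pow <- exp(pmin(beta * (log(t) - la), 700))
  nll <- -sum(lb - beta * la + (beta - 1) * log(t) - pow)
  if (!is.finite(nll)) nll <- 1e300
  nll
}

#' Fit a Weibull distribution to time-to-onset data
#'
#' Maximum-likelihood fit of the two-parameter Weibull distribution
#' \eqn{F(t) = 1 - \exp(-(t/\alpha)^\beta)} to uncensored onset times.
#' The likelihood is maximised over \eqn{(\log\alpha, \log\beta)} by
#' quasi-Newton search with the shape bounded to [0.05, 50] (the bound
#' only binds for degenerate samples, e.g. all observations equal);
#' confidence intervals are Wald intervals on the log scale from the
#' observed information, exponentiated, which guarantees positive
#' bounds. The fit also records the empirical median and IQR of the
#' raw days, and classifies the hazard trend from the shape CI (see
#' [classifyFailureType()]).
#'
#' @param days numeric vector of onset days, all positive, length >= 3.
#' @param alphaLevel significance level for the CIs (default 0.05).
#' @param shapeBounds numeric(2) search bounds for the shape parameter.
#' @return a [WeibullFit-class].
#' @section Errors: fewer than 3 observations raises an
#'   insufficient-data error; optimizer failure raises a fit error
#'   carrying the optimizer diagnostics.
#' @export
weibullFit <- function(days, alphaLevel = 0.05, shapeBounds = c(0.05, 50)) {
  t <- as.numeric(days)
  if (length(t) < 3)
    pvStop("pv_insufficient_data",
           "Weibull fit needs at least 3 observations, got %d", length(t))
  if (any(t <= 0))
    pvStop("pv_estimate_error", "onset days must be positive")

  # profile likelihood: for fixed beta the scale MLE is closed form,
  # alpha(beta) = (mean t^beta)^(1/beta), so the search is 1-D in
  # log beta over the bounded interval
  lt <- log(t)
  profAlpha <- function(beta) {
    m <- max(lt)                      # stabilise t^beta for large beta
    m + log(mean(exp(beta * (lt - m)))) / beta
  }
  profNll <- function(lb) {
    beta <- exp(lb)
    .weibullNll(c(profAlpha(beta), lb), t)
  }
  opt <- stats::optimize(profNll, log(shapeBounds), tol = 1e-10)
  lb <- opt$minimum
  beta <- exp(lb)
  la <- profAlpha(beta)
  alpha <- exp(la)
  if (!is.finite(opt$objective))
    pvStop("pv_fit_error", "Weibull likelihood is degenerate (n = %d)",
           length(t))

  z <- stats::qnorm(1 - alphaLevel / 2)
  atBound <- beta >= shapeBounds[2] * (1 - 1e-4) ||
    beta <= shapeBounds[1] * (1 + 1e-4)
  # Wald SEs on (log alpha, log beta) from the observed information
  ses <- tryCatch({
    hess <- stats::optimHess(c(la, lb), .weibullNll, t = t)
    sqrt(pmax(diag(solve(hess)), 0))
  }, error = function(e) c(NA_real_, NA_real_))
  if (atBound) ses <- c(NA_real_, NA_real_)
  alphaCi <- exp(la + c(-1, 1) * z * ses[1])
  betaCi <- exp(lb + c(-1, 1) * z * ses[2])

  s <- summarizeTto(t)
  new("WeibullFit", alpha = alpha, beta = beta,
      alphaCi = alphaCi, betaCi = betaCi, n = length(t),
      failureType = classifyFailureType(betaCi),
      medianDays = s$median, iqrDays = c(s$q1, s$q3),
      logLik = -opt$objective, level = 1 - alphaLevel)
}

#' @rdname WeibullFit-class
#' @param object a \code{WeibullFit}.
#' @export
weibullParams <- function(object) {
  list(alpha = object@alpha, beta = object@beta,
       alphaCi = object@alphaCi, betaCi = object@betaCi,
       n = object@n, failureType = object@failureType,
       medianDays = object@medianDays, iqrDays = object@iqrDays,
       logLik = object@logLik)
}
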