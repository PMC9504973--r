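#' @include AllClasses.R
NULL

#' Tabulate post-event outcomes per drug-event pair
#'
#' For each requested preferred term, counts the reports of that term
#' with the drug across the six outcome categories (recovered,
#' remission, not recovered, with sequelae, death, unclear). Reports
#' with no recorded outcome (\code{missing}) are excluded from the
#' denominator, so a term's outcome n can be smaller than its signal
#' case count. Counts attach to the (case, drug, PT) pair; when a case
#' reported the same term more than once, the pair table already
#' carries the worst outcome (death > with sequelae > not recovered >
#' remission > recovered > unclear).
#'
#' @param pairs a [PairTable-class].
#' @param drug drug name.
#' @param pts preferred terms to tabulate (typically the detected
#'   signals); defaults to all terms observed with the drug.
#' @return data.frame with one row per term: \code{drug}, \code{pt},
#'   \code{n} (outcome-bearing reports), one count column per category,
#'   and one \code{<category>_pct} column per category (100 * count /
#'   n, half-up to one decimal; \code{NA} when n = 0).
#' @export
tabulateOutcomes <- function(pairs, drug, pts = NULL) {
  df <- pairData(pairs)
  df <- df[df$drug_name == drug, , drop = FALSE]
  if (is.null(pts)) pts <- sort(unique(df$pt))
  cats <- setdiff(.outcomeLevels, "missing")
  out <- data.frame(drug = rep(drug, length(pts)), pt = pts,
                    n = integer(length(pts)), stringsAsFactors = FALSE)
  for (cc in cats) out[[cc]] <- integer(length(pts))
  for (cc in cats) out[[paste0(cc, "_pct")]] <- rep(NA_real_, length(pts))
  for (i in seq_along(pts)) {
    sub <- df[df$pt == pts[i] & df$outcome != "missing", , drop = FALSE]
    out$n[i] <- nrow(sub)
    counts <- table(factor(sub$outcome, levels = cats))
    for (cc in cats) out[[cc]][i] <- as.integer(counts[[cc]])
    if (out$n[i] > 0)
      for (cc in cats)
        out[[paste0(cc, "_pct")]][i] <-
          roundHalfUp(100 * counts[[cc]] / out$n[i], 1)
  }
  out
}

#' Write an outcome table as TSV
#'
#' Layout mirrors the conventional published table: one row per term,
#' category cells formatted as \code{"count (pct%)"}.
#'
#' @param outcomes data.frame from [tabulateOutcomes()].
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeOutcomes <- function(outcomes, path) {
  cats <- setdiff(.outcomeLevels, "missing")
  disp <- outcomes[c("drug", "pt", "n")]
  for (cc in cats) {
    pct <- outcomes[[paste0(cc, "_pct")]]
    disp[[cc]] <- ifelse(is.na(pct),
                         sprintf("%d (-)", outcomes[[cc]]),
                         sprintf("%d (%.1f%%)", outcomes[[cc]], pct))
  }
  utils::write.table(disp, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
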