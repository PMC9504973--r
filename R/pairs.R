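#' @include AllClasses.R AllGenerics.R
NULL

# order partial-date strings chronologically: the compact form sorts
# lexicographically within equal precision; shorter (less precise)
# strings are padded so that e.g. "202001" sorts before "20200115"
.orderDateStrings <- function(x) {
  order(vapply(x, function(s) sprintf("%-8s", s), ""), method = "radix")
}

.buildPairsFromTables <- function(demo, drug, reac, suspectOnly) {
  keep <- drug$case_id %in% demo$case_id
  drug <- drug[keep, , drop = FALSE]
  reac <- reac[reac$case_id %in% demo$case_id, , drop = FALSE]
  if (suspectOnly)
    drug <- drug[drug$involvement == "suspect", , drop = FALSE]

  empty <- data.frame(case_id = character(), drug_name = character(),
                      pt = character(), involvement = character(),
                      onset_date = character(), outcome = character(),
                      stringsAsFactors = FALSE)
  if (nrow(drug) == 0 || nrow(reac) == 0) {
    empty$start_dates <- list()
    return(empty)
  }

  # one row per (case, drug): keep highest-priority involvement and the
  # sorted vector of all start dates (re-administrations)
  dkey <- paste(drug$case_id, drug$drug_name, sep = "\r")
  ord <- order(dkey, -.involvementPriority[drug$involvement],
               method = "radix")
  drug <- drug[ord, , drop = FALSE]
  dkey <- dkey[ord]
  first <- !duplicated(dkey)
  starts <- split(drug$start_date, factor(dkey, levels = unique(dkey)))
  starts <- lapply(starts, function(s) {
    s <- s[nzchar(s)]
    s[.orderDateStrings(s)]
  })
  dcd <- data.frame(case_id = drug$case_id[first],
                    drug_name = drug$drug_name[first],
                    involvement = drug$involvement[first],
                    stringsAsFactors = FALSE)
  dcd$start_dates <- unname(starts)

  # one row per (case, PT): earliest onset date, worst outcome when the
  # same term repeats within a case
  rkey <- paste(reac$case_id, reac$pt, sep = "\r")
  ord <- order(rkey, vapply(reac$onset_date,
                            function(s) sprintf("%-8s", s), ""),
               method = "radix")
  reac <- reac[ord, , drop = FALSE]
  rkey <- rkey[ord]
  worst <- tapply(.outcomeSeverity[reac$outcome],
                  factor(rkey, levels = unique(rkey)), max)
  sevInv <- stats::setNames(names(.outcomeSeverity), .outcomeSeverity)
  first <- !duplicated(rkey)
  rcp <- data.frame(case_id = reac$case_id[first], pt = reac$pt[first],
                    onset_date = reac$onset_date[first],
                    outcome = unname(sevInv[as.character(worst)]),
                    stringsAsFactors = FALSE)

  pairs <- merge(dcd, rcp, by = "case_id", sort = FALSE)
  if (nrow(pairs) == 0) {
    empty$start_dates <- list()
    return(empty)
  }
  pairs <- pairs[order(pairs$case_id, pairs$drug_name, pairs$pt,
                       method = "radix"), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs[c("case_id", "drug_name", "pt", "involvement", "onset_date",
          "outcome", "start_dates")]
}

#' @describeIn buildPairs build the pair table from a linked database.
#' @export
setMethod("buildPairs", "SrsDatabase", function(x, suspectOnly = TRUE) {
  pairs <- .buildPairsFromTables(x@demo, x@drug, x@reac, suspectOnly)
  new("PairTable", pairs = pairs, suspectOnly = suspectOnly,
      nCases = nrow(x@demo))
})

#' @describeIn buildPairs build from the \code{cases} element of
#'   [linkCases()] output (orphans have already been removed there).
#' @export
setMethod("buildPairs", "list", function(x, suspectOnly = TRUE) {
  cases <- if (!is.null(x$cases)) x$cases else x
  demo <- do.call(rbind, lapply(cases, `[[`, "demo"))
  drug <- do.call(rbind, lapply(cases, `[[`, "drugs"))
  reac <- do.call(rbind, lapply(cases, `[[`, "reactions"))
  if (is.null(demo)) demo <- data.frame(case_id = character())
  if (is.null(drug)) drug <- data.frame(case_id = character(),
                                        drug_name = character(),
                                        involvement = character(),
                                        start_date = character())
  if (is.null(reac)) reac <- data.frame(case_id = character(),
                                        pt = character(),
                                        onset_date = character(),
                                        outcome = character())
  pairs <- .buildPairsFromTables(demo, drug, reac, suspectOnly)
  new("PairTable", pairs = pairs, suspectOnly = suspectOnly,
      nCases = nrow(demo))
})

#' @describeIn buildPairs a pair table is a fixed point: rebuilding
#'   returns it unchanged (optionally narrowed to suspect-drug rows).
#' @export
setMethod("buildPairs", "PairTable", function(x, suspectOnly = TRUE) {
  df <- x@pairs
  if (suspectOnly && !x@suspectOnly)
    df <- df[df$involvement == "suspect", , drop = FALSE]
  rownames(df) <- NULL
  new("PairTable", pairs = df, suspectOnly = suspectOnly || x@suspectOnly,
      nCases = x@nCases)
})

#' Count reported cases per preferred term for one drug
#'
#' @param pairs a [PairTable-class].
#' @param drug drug name. A drug absent from the table yields an empty
#'   result, not an error.
#' @return data.frame with columns \code{pt} and \code{cases} (distinct
#'   cases reporting that term with the drug), sorted by decreasing
#'   count.
#' @export
countEvents <- function(pairs, drug) {
  df <- pairData(pairs)
  df <- df[df$drug_name == drug, , drop = FALSE]
  if (nrow(df) == 0)
    return(data.frame(pt = character(), cases = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(df$pt)
  out <- data.frame(pt = names(tab), cases = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$cases, out$pt, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialise a pair table to TSV
#'
#' Deterministic row order (case_id, drug_name, pt); the start-date list
#' column is written semicolon-separated.
#'
#' @param pairs a [PairTable-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePairs <- function(pairs, path) {
  df <- pairData(pairs)
  df$start_dates <- vapply(df$start_dates, paste, "", collapse = ";")
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
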