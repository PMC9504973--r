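#' Construct an SrsDatabase from canonical data frames
#'
#' Lower-level constructor used by [readSrsTables()] and the synthetic
#' generator; expects tables already in the canonical vocabulary.
#' Missing optional columns are filled with empty strings.
#'
#' @param demo,drug,reac,hist data.frames in canonical form (see
#'   [srsDialect()] for the field lists). Any may be omitted.
#' @param dialect dialect the data were read with (kept for writing).
#' @return an [SrsDatabase-class].
#' @export
srsDatabase <- function(demo = NULL, drug = NULL, reac = NULL, hist = NULL,
                        dialect = srsDialect()) {
  fill <- function(df, cols) {
    if (is.null(df)) df <- data.frame()
    for (cc in cols) if (!cc %in% names(df))
      df[[cc]] <- rep("", max(nrow(df), 0))
    df <- df[cols]
    df[] <- lapply(df, as.character)
    rownames(df) <- NULL
    df
  }
  demo <- fill(demo, .demoCols)
  drug <- fill(drug, .drugCols)
  reac <- fill(reac, .reacCols)
  hist <- fill(hist, .histCols)
  if (nrow(demo) && !all(nzchar(demo$sex))) {
    demo$sex[!nzchar(demo$sex)] <- "unknown"
  }
  if (nrow(drug)) {
    drug$involvement[!drug$involvement %in% .involvementLevels] <- "unknown"
    drug$start_date <- normalizeDateString(drug$start_date)
    drug$end_date <- normalizeDateString(drug$end_date)
  }
  if (nrow(reac)) {
    reac$outcome[!reac$outcome %in% .outcomeLevels] <- "missing"
    reac$onset_date <- normalizeDateString(reac$onset_date)
  }
  new("SrsDatabase", demo = demo, drug = drug, reac = reac, hist = hist,
      dialect = unclass(dialect))
}

.mandatory <- list(demo = "case_id", drug = c("case_id", "drug_name"),
                   reac = c("case_id", "pt"), hist = "case_id")

#' Read the four SRS tables from CSV files
#'
#' Reads DEMO, DRUG, REAC and HIST comma-separated files (header row,
#' quoted fields), renames columns through the dialect's column maps,
#' translates involvement/outcome/sex labels to the canonical
#' vocabulary, and normalises dates to compact partial-date strings.
#' Unparseable dates are retained at reduced precision (or as missing),
#' never rejected; row counts are preserved exactly.
#'
#' @param paths named list/vector with elements \code{demo},
#'   \code{drug}, \code{reac}, \code{hist} giving the file paths.
#' @param dialect an [srsDialect()] object (or path handled by caller).
#' @return an [SrsDatabase-class].
#' @section Errors: a missing file raises an I/O error naming the table;
#'   a file lacking a mandatory column (case_id; drug_name for DRUG; pt
#'   for REAC) raises a schema error naming the column.
#' @export
readSrsTables <- function(paths, dialect = srsDialect()) {
  stopifnot(all(c("demo", "drug", "reac", "hist") %in% names(paths)))
  readOne <- function(tab) {
    path <- paths[[tab]]
    if (!file.exists(path))
      pvStop("pv_io_error", "file for table %s not found: %s",
             toupper(tab), path)
    raw <- utils::read.csv(path, colClasses = "character",
                           fileEncoding = dialect$encoding,
                           check.names = FALSE)
    map <- dialect$columns[[tab]]
    present <- names(map)[names(map) %in% names(raw)]
    df <- raw[present]
    names(df) <- unname(map[present])
    need <- .mandatory[[tab]]
    miss <- setdiff(need, names(df))
    if (length(miss))
      pvStop("pv_schema_error",
             "table %s is missing mandatory column(s): %s (file %s)",
             toupper(tab), paste(miss, collapse = ", "), path)
    df
  }
  demo <- readOne("demo")
  drug <- readOne("drug")
  reac <- readOne("reac")
  hist <- readOne("hist")
  if (nrow(demo) && "sex" %in% names(demo))
    demo$sex <- .mapValues(demo$sex, dialect$sex, "unknown")
  if (nrow(drug) && "involvement" %in% names(drug))
    drug$involvement <- .mapValues(drug$involvement, dialect$involvement,
                                   "unknown")
  if (nrow(reac) && "outcome" %in% names(reac))
    reac$outcome <- .mapValues(reac$outcome, dialect$outcomes, "missing")
  srsDatabase(demo, drug, reac, hist, dialect)
}

#' Write an SrsDatabase back to four CSV files
#'
#' Inverse of [readSrsTables()] under the same dialect: canonical values
#' are translated back through the (inverted) value maps and columns
#' renamed to the file's headers, so a write/read round trip reproduces
#' the records field-for-field.
#'
#' @param db an [SrsDatabase-class].
#' @param dir output directory (created if needed).
#' @param dialect dialect controlling headers, labels and encoding;
#'   defaults to the dialect stored in \code{db}.
#' @return invisibly, the named vector of file paths written.
#' @export
writeSrsTables <- function(db, dir, dialect = NULL) {
  if (is.null(dialect)) dialect <- do.call(srsDialect, db@dialect[
    c("columns", "involvement", "outcomes", "sex", "encoding")])
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(demo = db@demo, drug = db@drug, reac = db@reac,
               hist = db@hist)
  paths <- character()
  for (tab in names(tabs)) {
    df <- tabs[[tab]]
    if (tab == "demo" && nrow(df))
      df$sex <- .mapValues(df$sex, .invertMap(dialect$sex), "unknown")
    if (tab == "drug" && nrow(df))
      df$involvement <- .mapValues(df$involvement,
                                   .invertMap(dialect$involvement), "unknown")
    if (tab == "reac" && nrow(df))
      df$outcome <- .mapValues(df$outcome, .invertMap(dialect$outcomes),
                               "missing")
    map <- dialect$columns[[tab]]
    inv <- .invertMap(map)
    names(df) <- unname(inv[names(df)])
    path <- file.path(dir, paste0(tab, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = dialect$encoding)
    paths[tab] <- path
  }
  invisible(paths)
}

#' Link the four tables into case-centric records
#'
#' Produces one case record per distinct case id in DEMO, each holding
#' that case's demographic row and its DRUG/REAC/HIST rows. Rows in the
#' satellite tables whose case id does not appear in DEMO are collected
#' into an orphan report rather than dropped, so that record counts are
#' conserved: reactions over all cases plus orphan reactions equal the
#' REAC row count.
#'
#' @param db an [SrsDatabase-class].
#' @return a list with elements \code{cases} (named list of case
#'   records, each a list with \code{demo}, \code{drugs},
#'   \code{reactions}, \code{history}) and \code{orphans} (list of
#'   data.frames \code{drug}, \code{reac}, \code{hist} of unlinked rows).
#' @export
linkCases <- function(db) {
  ids <- db@demo$case_id
  splitKeep <- function(df) {
    known <- df$case_id %in% ids
    list(linked = split(df[known, , drop = FALSE],
                        factor(df$case_id[known], levels = ids)),
         orphan = df[!known, , drop = FALSE])
  }
  d <- splitKeep(db@drug)
  r <- splitKeep(db@reac)
  h <- splitKeep(db@hist)
  cases <- lapply(seq_along(ids), function(i) {
    list(demo = db@demo[i, , drop = FALSE],
         drugs = d$linked[[i]],
         reactions = r$linked[[i]],
         history = h$linked[[i]])
  })
  names(cases) <- ids
  list(cases = cases,
       orphans = list(drug = d$orphan, reac = r$orphan, hist = h$orphan))
}
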