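#' CSV dialect configuration for a four-table SRS database
#'
#' The real JADER distribution uses Japanese column headers, Japanese
#' involvement and outcome labels, and Shift-JIS encoding; test fixtures
#' and other FAERS-like exports use plain English. All of this is
#' captured in a dialect object rather than in code: a set of
#' column-name maps (file column -> canonical field), value maps for
#' involvement codes, outcome labels and sex labels (file value ->
#' canonical value), and the file encoding.
#'
#' Canonical fields are: DEMO \code{case_id, sex, age_band,
#' report_period}; DRUG \code{case_id, drug_name, involvement,
#' start_date, end_date, route}; REAC \code{case_id, pt, onset_date,
#' outcome}; HIST \code{case_id, disease}. Canonical involvement values
#' are \code{suspect, concomitant, interacting, unknown}; canonical
#' outcomes \code{recovered, remission, not_recovered, with_sequelae,
#' death, unclear, missing}.
#'
#' @param columns named list with elements \code{demo}, \code{drug},
#'   \code{reac}, \code{hist}; each a named character vector mapping the
#'   file's column name to the canonical field name. Defaults to the
#'   identity mapping on the canonical names.
#' @param involvement named character vector mapping file involvement
#'   codes to canonical values. Unmapped codes become \code{"unknown"}.
#' @param outcomes named character vector mapping file outcome labels to
#'   canonical values. Unmapped labels (and empty cells) become
#'   \code{"missing"}.
#' @param sex named character vector mapping file sex labels to
#'   canonical values; unmapped become \code{"unknown"}.
#' @param encoding file encoding, default \code{"UTF-8"}.
#' @return a list of class \code{"srs_dialect"}.
#' @seealso [readDialect()] to load a dialect from a YAML/JSON file.
#' @export
srsDialect <- function(columns = list(),
                       involvement = NULL,
                       outcomes = NULL,
                       sex = NULL,
                       encoding = "UTF-8") {
  defCols <- list(
    demo = stats::setNames(.demoCols, .demoCols),
    drug = stats::setNames(.drugCols, .drugCols),
    reac = stats::setNames(.reacCols, .reacCols),
    hist = stats::setNames(.histCols, .histCols))
  for (tab in names(columns)) {
    stopifnot(tab %in% names(defCols))
    defCols[[tab]] <- unlist(columns[[tab]])
  }
  if (is.null(involvement))
    involvement <- stats::setNames(.involvementLevels, .involvementLevels)
  if (is.null(outcomes))
    outcomes <- stats::setNames(.outcomeLevels, .outcomeLevels)
  if (is.null(sex))
    sex <- stats::setNames(.sexLevels, .sexLevels)
  structure(list(columns = defCols,
                 involvement = involvement,
                 outcomes = outcomes,
                 sex = sex,
                 encoding = encoding),
            class = "srs_dialect")
}

#' Read a dialect definition from a YAML or JSON file
#'
#' The file may define any subset of the keys \code{columns} (with
#' sub-keys demo/drug/reac/hist), \code{involvement}, \code{outcomes},
#' \code{sex} and \code{encoding}; omitted keys fall back to the
#' defaults of [srsDialect()].
#'
#' @param path path to a YAML (or JSON; YAML is a superset) file.
#' @return a dialect object as from [srsDialect()].
#' @export
readDialect <- function(path) {
  if (!file.exists(path))
    pvStop("pv_io_error", "dialect file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  srsDialect(columns = if (is.null(cfg$columns)) list() else
               lapply(cfg$columns, unlist),
             involvement = if (is.null(cfg$involvement)) NULL else
               unlist(cfg$involvement),
             outcomes = if (is.null(cfg$outcomes)) NULL else
               unlist(cfg$outcomes),
             sex = if (is.null(cfg$sex)) NULL else unlist(cfg$sex),
             encoding = if (is.null(cfg$encoding)) "UTF-8" else cfg$encoding)
}

# apply a value map; values not in the map become `default`
.mapValues <- function(x, map, default) {
  out <- unname(map[as.character(x)])
  out[is.na(out)] <- default
  out
}

# invert a value map for writing; when several file labels map to one
# canonical value the first is used
.invertMap <- function(map) {
  stats::setNames(names(map), unname(map))[!duplicated(unname(map))]
}
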