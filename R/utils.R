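#' Round half away from zero
#'
#' Display rounding used throughout the reports. Base \code{round()} uses
#' round-half-to-even; published pharmacovigilance tables round halves up,
#' so percentage cells such as 26.65 print as 26.7.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
roundHalfUp <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by an epsilon relative to x so that values that are exactly .5
  # after floating-point representation go up, not to even
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Severity ranking of outcome categories, worst first.  "missing" ranks
# below everything and never wins a tie.
.outcomeLevels <- c("recovered", "remission", "not_recovered",
                    "with_sequelae", "death", "unclear", "missing")

.outcomeSeverity <- c(death = 6, with_sequelae = 5, not_recovered = 4,
                      remission = 3, recovered = 2, unclear = 1, missing = 0)

.involvementLevels <- c("suspect", "interacting", "concomitant", "unknown")

# Priority used when one case lists the same drug with several involvement
# codes: suspect > interacting > concomitant > unknown.
.involvementPriority <- c(suspect = 4, interacting = 3, concomitant = 2,
                          unknown = 1)

.sexLevels <- c("female", "male", "unknown")

# Evaluate expr with the RNG seeded from `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user simulations.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# stop() with a class so callers can distinguish schema/config errors
pvStop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
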