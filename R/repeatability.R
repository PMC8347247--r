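# Repeatability (minimally detectable change) tables.
#
# The within-subject standard deviation Sw of a tomography variable, estimated
# from repeated measurements of the same eye, bounds what a single follow-up
# can detect: 95% of test-retest differences fall within
# r = 1.96 * sqrt(2) * Sw (about 2.77 * Sw). A change beyond r from baseline
# in the clinical direction of progression is the minimal evidence of true
# change and defines the "suspect progressive" label.

#' Build a repeatability table from within-subject standard deviations
#'
#' Computes the repeatability limit `r = 1.96 * sqrt(2) * Sw` for each of the
#' five progression variables and attaches the fixed clinical direction of
#' progression (increasing for `KmaxZonalMean3mm` and `LOGIK`, decreasing for
#' `RsF`, `BFSF` and `RmB`).
#'
#' @param sw Named numeric vector of within-subject SDs, in the units of each
#'   variable (D for `KmaxZonalMean3mm`, mm for the radii and best-fit sphere,
#'   unitless for `LOGIK`). Names must cover `kc_variables()`. All values must
#'   be non-negative.
#' @return A data frame of class `repeatability_table` with columns
#'   `variable`, `sw`, `r` and `direction`.
#' @examples
#' rt <- compute_repeatability(c(
#'   KmaxZonalMean3mm = 0.26, RsF = 0.05, BFSF = 0.05,
#'   RmB = 0.05, LOGIK = 0.15
#' ))
#' rt
#' @export
compute_repeatability <- function(sw) {
  check_that(is.numeric(sw), "'sw' must be a numeric vector")
  check_that(!is.null(names(sw)), "'sw' must be named by variable")
  missing <- setdiff(KC_VARIABLES, names(sw))
  check_that(length(missing) == 0L,
             "'sw' is missing variables: %s", paste(missing, collapse = ", "))
  sw <- sw[KC_VARIABLES]
  check_that(all(is.finite(sw)), "'sw' values must be finite")
  if (any(sw < 0)) {
    stop(sprintf("negative within-subject SD for: %s",
                 paste(KC_VARIABLES[sw < 0], collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    variable = KC_VARIABLES,
    sw = unname(sw),
    r = unname(sw) * KC_REPEATABILITY_FACTOR,
    direction = unname(KC_DIRECTIONS[KC_VARIABLES]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("repeatability_table", "data.frame")
  out
}

#' Build a repeatability table directly from repeatability limits
#'
#' Convenience inverse of [compute_repeatability()] for when the 95%
#' repeatability limits `r` are reported rather than the within-subject SDs.
#'
#' @param r Named numeric vector of repeatability limits covering
#'   `kc_variables()`.
#' @return A `repeatability_table` (see [compute_repeatability()]).
#' @export
repeatability_from_r <- function(r) {
  check_that(is.numeric(r) && !is.null(names(r)),
             "'r' must be a named numeric vector")
  compute_repeatability(r / KC_REPEATABILITY_FACTOR)
}

#' @export
print.repeatability_table <- function(x, ...) {
  cat("Repeatability table (r = 1.96 * sqrt(2) * Sw):\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# Internal: validate a repeatability_table and return it keyed by variable.
as_rt <- function(rt) {
  check_that(inherits(rt, "repeatability_table") ||
               (is.data.frame(rt) &&
                  all(c("variable", "r", "direction") %in% names(rt))),
             "'rt' must be a repeatability_table (see compute_repeatability)")
  missing <- setdiff(KC_VARIABLES, rt$variable)
  check_that(length(missing) == 0L,
             "repeatability table is missing variables: %s",
             paste(missing, collapse = ", "))
  rt[match(KC_VARIABLES, rt$variable), , drop = FALSE]
}

# Signed direction per variable: +1 if progression increases the value.
direction_sign <- function(rt) {
  rt <- as_rt(rt)
  ifelse(rt$direction == "INCREASING", 1, -1)
}

#' Default within-subject SDs for the synthetic cohort
#'
#' Plausible measurement-noise magnitudes for Scheimpflug tomography in
#' keratoconic eyes, used as generator defaults. The `KmaxZonalMean3mm` value
#' (0.26 D, i.e. r of about 0.72 D) reflects published repeatability of zonal
#' keratometry in KC; the remaining values are order-of-magnitude placeholders
#' that users with device-specific repeatability studies should override.
#'
#' @return Named numeric vector of within-subject SDs.
#' @export
default_sw <- function() {
  c(
    KmaxZonalMean3mm = 0.26, # D
    RsF  = 0.05,             # mm
    BFSF = 0.05,             # mm
    RmB  = 0.05,             # mm
    LOGIK = 0.15             # unitless
  )
}
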