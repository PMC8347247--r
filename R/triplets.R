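# Preprocessing: sliding triplets, quality/severity filtering, progression
# labelling, direction-aware noise reduction and Euclidean-norm normalization.
#
# A triplet is three consecutive examinations of one eye: baseline (bl),
# first follow-up (f1) and second follow-up (f2). An eye with k >= 3 exams
# contributes the k - 2 overlapping windows (1-2-3, 2-3-4, ...), which
# maximizes the number of progression patterns extracted from short series.
# The triplet table holds one row per window with columns <var>_bl, <var>_f1,
# <var>_f2 for each of the six variables plus dates, quality flags and the
# progression label.

TRIPLET_SLOTS <- c("bl", "f1", "f2")

slot_cols <- function(vars, slot) paste(vars, slot, sep = "_")

# n x length(vars) matrix of one exam slot of a triplet table, with bare
# variable names as columns
triplet_values <- function(triplets, slot, vars = KC_VARIABLES) {
  m <- as.matrix(triplets[, slot_cols(vars, slot), drop = FALSE])
  colnames(m) <- vars
  m
}

#' Build sliding triplets from an exam table
#'
#' Groups exams by eye, orders them chronologically and emits every window of
#' three consecutive examinations. Eyes with fewer than three exams emit no
#' triplet. Duplicate exam dates within an eye are rejected; consecutive
#' exams closer than 5 months apart only raise a warning, since spacing is a
#' property of data collection, not a filter.
#'
#' @param exams Exam table conforming to the cohort schema (see
#'   [read_cohort()]); a `kc_cohort` is also accepted.
#' @return A data frame of class `kc_triplets`, one row per window, with
#'   `label = NA` until [label_progression()] is applied.
#' @export
build_triplets <- function(exams) {
  if (inherits(exams, "kc_cohort")) exams <- exams$exams
  exams <- validate_exam_table(exams)
  if (nrow(exams) == 0L) return(empty_triplets())

  out <- vector("list", 0L)
  min_gap_warned <- FALSE
  for (id in unique(exams$eye_id)) {
    ex <- exams[exams$eye_id == id, , drop = FALSE]
    ex <- ex[order(ex$exam_date), , drop = FALSE]
    if (anyDuplicated(ex$exam_date)) {
      stop(sprintf("duplicate exam dates for eye '%s'", id), call. = FALSE)
    }
    gaps <- diff(as.numeric(ex$exam_date))
    if (!min_gap_warned && any(gaps < 5 * DAYS_PER_MONTH)) {
      warning(sprintf("eye '%s' has consecutive exams less than 5 months apart",
                      id), call. = FALSE)
      min_gap_warned <- TRUE
    }
    k <- nrow(ex)
    if (k < 3L) next
    for (w in seq_len(k - 2L)) {
      idx <- w:(w + 2L)
      row <- data.frame(eye_id = id, window_index = w,
                        stringsAsFactors = FALSE)
      for (s in seq_along(TRIPLET_SLOTS)) {
        slot <- TRIPLET_SLOTS[s]
        row[[paste0("date_", slot)]] <- ex$exam_date[idx[s]]
        row[[paste0("quality_", slot)]] <- ex$quality[idx[s]]
        for (v in KC_ALL_VARIABLES) {
          row[[paste(v, slot, sep = "_")]] <- ex[[v]][idx[s]]
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L) return(empty_triplets())
  tr <- do.call(rbind, out)
  tr$label <- NA_character_
  tr$n_exceed <- NA_integer_
  rownames(tr) <- NULL
  class(tr) <- c("kc_triplets", "data.frame")
  tr
}

empty_triplets <- function() {
  tr <- data.frame(eye_id = character(0), window_index = integer(0),
                   stringsAsFactors = FALSE)
  for (slot in TRIPLET_SLOTS) {
    tr[[paste0("date_", slot)]] <- as.Date(character(0))
    tr[[paste0("quality_", slot)]] <- character(0)
    for (v in KC_ALL_VARIABLES) tr[[paste(v, slot, sep = "_")]] <- numeric(0)
  }
  tr$label <- character(0)
  tr$n_exceed <- integer(0)
  class(tr) <- c("kc_triplets", "data.frame")
  tr
}

as_triplets <- function(triplets) {
  check_that(is.data.frame(triplets), "'triplets' must be a data frame")
  needed <- c("eye_id", unlist(lapply(TRIPLET_SLOTS, slot_cols,
                                      vars = KC_ALL_VARIABLES)))
  missing <- setdiff(needed, names(triplets))
  check_that(length(missing) == 0L, "triplet table is missing column(s): %s",
             paste(missing, collapse = ", "))
  triplets
}

#' Filter triplets by device quality flags
#'
#' Two policies mirror the two study datasets: `OPTION1` keeps only triplets
#' whose three exams are all flagged `OK`; `OPTION2` additionally allows one
#' of the three exams to be of lower quality (`YELLOW`). An exam flagged
#' `RED` (unusable) excludes its triplet under both policies.
#'
#' @param triplets A `kc_triplets` table.
#' @param policy `"OPTION1"` or `"OPTION2"`.
#' @return The filtered triplet table (possibly empty).
#' @export
filter_quality <- function(triplets, policy = c("OPTION1", "OPTION2")) {
  triplets <- as_triplets(triplets)
  policy <- match.arg(policy)
  q <- cbind(triplets$quality_bl, triplets$quality_f1, triplets$quality_f2)
  n_ok <- rowSums(q == "OK")
  any_red <- rowSums(q == "RED") > 0
  keep <- if (policy == "OPTION1") n_ok == 3L else (n_ok >= 2L & !any_red)
  triplets[keep, , drop = FALSE]
}

#' Exclude triplets that are severe at baseline
#'
#' Severe keratoconus (baseline `LOGIK` strictly above the threshold) is
#' excluded: such eyes rarely obtain reliable scans and behave as outliers in
#' training. Only the baseline exam is tested.
#'
#' @param triplets A `kc_triplets` table.
#' @param threshold Severity cut-off on baseline `LOGIK` (default 3.5).
#' @return The filtered triplet table.
#' @export
filter_severity <- function(triplets, threshold = 3.5) {
  triplets <- as_triplets(triplets)
  check_that(is.numeric(threshold) && length(threshold) == 1L && threshold > 0,
             "'threshold' must be a single positive number")
  triplets[triplets$LOGIK_bl <= threshold, , drop = FALSE]
}

# Internal: n x 5 logical matrix, TRUE where variable v of row i moved beyond
# its repeatability limit from baseline in the clinical direction, evaluated
# on the supplied follow-up values (default: the measured second follow-up).
exceed_matrix <- function(baseline, followup, rt) {
  rt <- as_rt(rt)
  sgn <- direction_sign(rt)
  delta <- followup - baseline
  sweep(delta, 2L, sgn, `*`) > matrix(rt$r, nrow = nrow(delta),
                                      ncol = length(rt$r), byrow = TRUE)
}

#' Label triplets as stable or suspect progressive
#'
#' A triplet is `SUSPECT_PROGRESSIVE` when at least one of the five non-age
#' variables of the second follow-up lies outside the 95% repeatability
#' interval `[-r, +r]` around its baseline value, in the clinical direction
#' of progression (a significant increase in `KmaxZonalMean3mm` or `LOGIK`,
#' or a significant decrease in `RsF`, `BFSF` or `RmB`). Changes at the first
#' follow-up never set the label. "Outside" is strict: a change exactly equal
#' to `r` is still stable.
#'
#' @param triplets A `kc_triplets` table.
#' @param rt A [compute_repeatability()] table.
#' @return `triplets` with `label` and `n_exceed` (0-5, the number of
#'   variables beyond their limit) filled in.
#' @export
label_progression <- function(triplets, rt) {
  triplets <- as_triplets(triplets)
  if (nrow(triplets) == 0L) return(triplets)
  ex <- exceed_matrix(triplet_values(triplets, "bl"),
                      triplet_values(triplets, "f2"), rt)
  triplets$n_exceed <- as.integer(rowSums(ex))
  triplets$label <- ifelse(triplets$n_exceed >= 1L,
                           "SUSPECT_PROGRESSIVE", "STABLE")
  triplets
}

#' Direction-aware three-branch noise reduction
#'
#' Shrinks follow-up excursions that carry no progression evidence while
#' leaving genuine progression untouched. The baseline is the reference and
#' is never modified. For each non-age variable of each follow-up, with
#' `delta` the difference from baseline: (1) a `delta` opposing the clinical
#' direction of progression is divided by `opposing_factor` (default 5);
#' (2) a `delta` in the clinical direction but inside the 95% repeatability
#' interval is divided by `inside_factor` (default 2), since such a trend may
#' carry information about future progression; (3) a `delta` in the clinical
#' direction and beyond the interval is kept unchanged. The progression label
#' is provably unaffected, because the interval boundary separates branch (3)
#' from the shrinking branches and shrinking never pushes a value across it.
#'
#' @param triplets A `kc_triplets` table.
#' @param rt A [compute_repeatability()] table.
#' @param opposing_factor,inside_factor Shrink factors for branches (1)
#'   and (2).
#' @return The transformed triplet table.
#' @examples
#' # worked single-variable example: (44, 43.5, 45) D with r = 0.72 D and
#' # increasing direction becomes (44, 43.9, 45) D
#' @export
noise_reduce <- function(triplets, rt, opposing_factor = 5, inside_factor = 2) {
  triplets <- as_triplets(triplets)
  check_that(opposing_factor >= 1 && inside_factor >= 1,
             "shrink factors must be >= 1")
  if (nrow(triplets) == 0L) return(triplets)
  rt <- as_rt(rt)
  sgn <- direction_sign(rt)
  bl <- triplet_values(triplets, "bl")
  rmat <- matrix(rt$r, nrow = nrow(bl), ncol = length(rt$r), byrow = TRUE)
  sgnmat <- matrix(sgn, nrow = nrow(bl), ncol = length(sgn), byrow = TRUE)
  for (slot in c("f1", "f2")) {
    delta <- triplet_values(triplets, slot) - bl
    signed <- delta * sgnmat                 # > 0 means clinical direction
    newdelta <- ifelse(signed <= 0, delta / opposing_factor,
                       ifelse(signed <= rmat, delta / inside_factor, delta))
    triplets[, slot_cols(KC_VARIABLES, slot)] <- bl + newdelta
  }
  triplets
}

#' Normalize triplet variables by their Euclidean column norm
#'
#' Divides each variable (including `Age`) by the Euclidean norm of all its
#' values (baseline and both follow-ups) across the supplied triplets. The
#' constants are frozen at training time, stored with the model and reused at
#' inference, so held-out triplets are scaled exactly as the training data.
#'
#' @param triplets A `kc_triplets` table.
#' @param constants Optional named vector of previously fitted scale factors;
#'   when `NULL` they are computed from `triplets`.
#' @return A list with elements `triplets` (scaled table) and `constants`.
#' @export
normalize_triplets <- function(triplets, constants = NULL) {
  triplets <- as_triplets(triplets)
  if (is.null(constants)) {
    check_that(nrow(triplets) > 0L, "cannot fit constants on an empty table")
    constants <- vapply(KC_ALL_VARIABLES, function(v) {
      vals <- unlist(triplets[, slot_cols(v, TRIPLET_SLOTS)], use.names = FALSE)
      sqrt(sum(vals^2))
    }, numeric(1))
    zero <- names(constants)[constants == 0]
    if (length(zero) > 0L) {
      stop(sprintf("zero Euclidean norm for variable(s): %s",
                   paste(zero, collapse = ", ")), call. = FALSE)
    }
  }
  check_that(all(KC_ALL_VARIABLES %in% names(constants)),
             "'constants' must cover all six variables")
  check_that(all(constants[KC_ALL_VARIABLES] > 0),
             "scale factors must be positive")
  for (v in KC_ALL_VARIABLES) {
    cols <- slot_cols(v, TRIPLET_SLOTS)
    triplets[, cols] <- triplets[, cols] / constants[[v]]
  }
  list(triplets = triplets, constants = constants[KC_ALL_VARIABLES])
}

#' Undo Euclidean-norm normalization
#'
#' @param values Numeric matrix (or vector) whose columns are named by
#'   variable, in normalized units.
#' @param constants Scale factors from [normalize_triplets()].
#' @return `values` on the original scale.
#' @export
denormalize_values <- function(values, constants) {
  if (is.null(dim(values))) {
    check_that(!is.null(names(values)), "'values' must be named by variable")
    return(values * constants[names(values)])
  }
  check_that(!is.null(colnames(values)), "'values' columns must be named")
  sweep(values, 2L, constants[colnames(values)], `*`)
}

#' Run the full preprocessing chain
#'
#' Applies the fixed composition build -> quality filter -> severity filter ->
#' label -> noise-reduce, recording the number of triplets surviving each
#' stage in the `"funnel"` attribute. Normalization is deliberately left to
#' training time, where the constants are fitted on the development split
#' only.
#'
#' @param exams Exam table or `kc_cohort`.
#' @param rt A [compute_repeatability()] table.
#' @param option Quality policy, see [filter_quality()].
#' @param severity_threshold Baseline `LOGIK` cut-off, see
#'   [filter_severity()].
#' @param noise_reduction Apply [noise_reduce()] after labelling (default
#'   `TRUE`).
#' @return A labelled (and by default noise-reduced) `kc_triplets` table with
#'   a `"funnel"` attribute of per-stage counts.
#' @export
prepare_triplets <- function(exams, rt, option = c("OPTION1", "OPTION2"),
                             severity_threshold = 3.5, noise_reduction = TRUE) {
  option <- match.arg(option)
  tr <- build_triplets(exams)
  funnel <- c(built = nrow(tr))
  tr <- filter_quality(tr, option)
  funnel["quality"] <- nrow(tr)
  tr <- filter_severity(tr, severity_threshold)
  funnel["severity"] <- nrow(tr)
  tr <- label_progression(tr, rt)
  if (noise_reduction) tr <- noise_reduce(tr, rt)
  attr(tr, "funnel") <- funnel
  tr
}
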