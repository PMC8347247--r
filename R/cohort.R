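# Synthetic longitudinal KC cohorts with known ground truth.
#
# Real multicentre registries of keratoconus tomography series are not freely
# redistributable, so every downstream stage is exercised on simulated
# cohorts. An eye is either stable (its noise-free trajectory is flat and the
# exams differ only by measurement noise) or progressive (its noise-free
# trajectory drifts monotonically in the clinical direction of each variable).
# Measurement noise is i.i.d. Gaussian with the per-variable within-subject
# SD; visit spacing is irregular with a hard lower bound of 5 months.

#' Specify a synthetic cohort
#'
#' Collects and validates the parameters of the cohort generator. Defaults
#' describe a mixed stable/progressive cohort with realistic baseline
#' distributions (mean age 26.8 years, SD 6.4, truncated to 10-60 years) and
#' measurement noise from [default_sw()].
#'
#' @param n_eyes Number of eyes to simulate.
#' @param visits_per_eye Either a single integer (fixed number of visits) or a
#'   length-2 vector `c(min, max)` from which visit counts are drawn
#'   uniformly. Minimum 2.
#' @param spacing_months Length-2 vector `c(min, max)`; consecutive visits are
#'   separated by a uniform draw from this interval, in months. The lower
#'   bound must be at least 5 months.
#' @param progressive_fraction Probability that an eye is progressive.
#' @param drift_per_visit Named numeric vector of signed per-visit drift for
#'   progressive eyes, in variable units. Signs must match the clinical
#'   direction of progression (positive for `KmaxZonalMean3mm` and `LOGIK`,
#'   negative for `RsF`, `BFSF`, `RmB`); zero entries are allowed. The default
#'   is one repeatability limit (r) per visit in the clinical direction, a
#'   borderline-detectable progression rate.
#' @param noise_table Named numeric vector of within-subject SDs (Sw) per
#'   variable; defaults to [default_sw()].
#' @param baseline_mean,baseline_sd Named numeric vectors (over
#'   `kc_variables(include_age = TRUE)`) giving the distribution of first-exam
#'   values.
#' @param p_yellow,p_red Probabilities that an exam is flagged `YELLOW` /
#'   `RED` by the device quality check.
#' @param p_severe Probability that an eye is severe at baseline
#'   (`LOGIK > 3.5`), generated to exercise the severity exclusion filter.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec including this seed.
#' @return A validated list of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_eyes = 20, visits_per_eye = 3, seed = 1)
#' cohort <- generate_cohort(spec)
#' head(cohort$exams)
#' @export
cohort_spec <- function(n_eyes,
                        visits_per_eye = c(3L, 6L),
                        spacing_months = c(6, 12),
                        progressive_fraction = 0.5,
                        drift_per_visit = NULL,
                        noise_table = default_sw(),
                        baseline_mean = c(
                          Age = 26.8, KmaxZonalMean3mm = 48, RsF = 6.8,
                          BFSF = 7.8, RmB = 6.4, LOGIK = 1.5
                        ),
                        baseline_sd = c(
                          Age = 6.4, KmaxZonalMean3mm = 3, RsF = 0.6,
                          BFSF = 0.25, RmB = 0.4, LOGIK = 0.8
                        ),
                        p_yellow = 0.10,
                        p_red = 0.03,
                        p_severe = 0.05,
                        seed = 1L) {
  check_that(is_count(n_eyes, min = 1L), "'n_eyes' must be a positive integer")
  if (length(visits_per_eye) == 1L) {
    visits_per_eye <- rep(visits_per_eye, 2L)
  }
  check_that(length(visits_per_eye) == 2L &&
               all(visits_per_eye == round(visits_per_eye)) &&
               visits_per_eye[1] <= visits_per_eye[2],
             "'visits_per_eye' must be an integer or an increasing c(min, max)")
  check_that(visits_per_eye[1] >= 2, "'visits_per_eye' minimum is 2")
  check_that(length(spacing_months) == 2L && spacing_months[1] <= spacing_months[2],
             "'spacing_months' must be c(min, max)")
  check_that(spacing_months[1] >= 5,
             "visit spacing lower bound must be at least 5 months")
  for (p in c(progressive_fraction = progressive_fraction, p_yellow = p_yellow,
              p_red = p_red, p_severe = p_severe)) {
    check_that(is_prob(p), "probabilities must lie in [0, 1]")
  }
  check_that(p_yellow + p_red <= 1, "'p_yellow' + 'p_red' must not exceed 1")

  # accept YAML-style lists as well as named vectors
  noise_table <- unlist(noise_table)
  if (!is.null(drift_per_visit)) drift_per_visit <- unlist(drift_per_visit)
  baseline_mean <- unlist(baseline_mean)
  baseline_sd <- unlist(baseline_sd)

  noise_table <- noise_table[KC_VARIABLES]
  check_that(!anyNA(noise_table), "'noise_table' must cover all five variables")
  if (any(noise_table < 0)) {
    stop("negative within-subject SD in 'noise_table'", call. = FALSE)
  }

  if (is.null(drift_per_visit)) {
    drift_per_visit <- KC_REPEATABILITY_FACTOR * noise_table *
      ifelse(KC_DIRECTIONS[KC_VARIABLES] == "INCREASING", 1, -1)
  }
  drift_per_visit <- drift_per_visit[KC_VARIABLES]
  check_that(!anyNA(drift_per_visit),
             "'drift_per_visit' must cover all five variables")
  sgn <- ifelse(KC_DIRECTIONS[KC_VARIABLES] == "INCREASING", 1, -1)
  bad <- sgn * drift_per_visit < 0
  if (any(bad)) {
    stop(sprintf("drift opposes the clinical direction for: %s",
                 paste(KC_VARIABLES[bad], collapse = ", ")), call. = FALSE)
  }

  for (nm in KC_ALL_VARIABLES) {
    check_that(nm %in% names(baseline_mean) && nm %in% names(baseline_sd),
               "baseline distribution missing for '%s'", nm)
  }
  check_that(all(baseline_sd[KC_ALL_VARIABLES] >= 0),
             "baseline SDs must be non-negative")
  check_that(is_count(seed) || is_count(-seed), "'seed' must be an integer")

  structure(
    list(
      n_eyes = as.integer(n_eyes),
      visits_per_eye = as.integer(visits_per_eye),
      spacing_months = as.numeric(spacing_months),
      progressive_fraction = progressive_fraction,
      drift_per_visit = drift_per_visit,
      noise_table = noise_table,
      baseline_mean = baseline_mean[KC_ALL_VARIABLES],
      baseline_sd = baseline_sd[KC_ALL_VARIABLES],
      p_yellow = p_yellow,
      p_red = p_red,
      p_severe = p_severe,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# truncated normal by rejection; sd = 0 degenerates to the mean
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates one exam table plus per-eye ground truth from a [cohort_spec()].
#' Within each eye, ages strictly increase, consecutive visits are at least 5
#' months apart, observed values are the noise-free trajectory plus
#' independent Gaussian noise with the per-variable within-subject SD, and
#' quality flags are drawn independently per exam.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `kc_cohort` with elements
#'   \describe{
#'     \item{exams}{data frame with columns `patient_id`, `eye`, `eye_id`,
#'       `exam_date`, `quality`, `Age`, `KmaxZonalMean3mm`, `RsF`, `BFSF`,
#'       `RmB`, `LOGIK` (one row per exam).}
#'     \item{truth}{data frame keyed by `eye_id` with `is_progressive` and
#'       `severe_baseline`.}
#'     \item{trajectory}{data frame of noise-free per-visit values (ground
#'       truth for recovery tests).}
#'     \item{spec}{the generating spec.}
#'   }
#' @export
generate_cohort <- function(spec) {
  check_that(inherits(spec, "cohort_spec"), "'spec' must be a cohort_spec")
  with_seed(spec$seed, {
    n <- spec$n_eyes
    visits <- if (spec$visits_per_eye[1] == spec$visits_per_eye[2]) {
      rep(spec$visits_per_eye[1], n)
    } else {
      sample(seq(spec$visits_per_eye[1], spec$visits_per_eye[2]), n, replace = TRUE)
    }
    is_prog <- runif(n) < spec$progressive_fraction
    is_severe <- runif(n) < spec$p_severe
    eye_side <- sample(c("OD", "OS"), n, replace = TRUE)
    base_date <- as.Date("2014-01-01") + floor(runif(n, 0, 3 * DAYS_PER_YEAR))

    exam_list <- vector("list", n)
    traj_list <- vector("list", n)
    for (e in seq_len(n)) {
      k <- visits[e]
      eye_id <- sprintf("E%04d", e)
      gaps_m <- runif(k - 1L, spec$spacing_months[1], spec$spacing_months[2])
      offsets_d <- c(0, cumsum(gaps_m * DAYS_PER_MONTH))
      dates <- base_date[e] + round(offsets_d)
      age0 <- rnorm_trunc(1L, spec$baseline_mean[KC_AGE], spec$baseline_sd[KC_AGE],
                          lower = 10, upper = 60)
      ages <- age0 + as.numeric(dates - dates[1]) / DAYS_PER_YEAR

      base <- vapply(KC_VARIABLES, function(v) {
        lower <- if (v == "LOGIK") 0 else 1e-6
        upper <- if (v == "LOGIK") 3.5 else Inf
        rnorm_trunc(1L, spec$baseline_mean[v], spec$baseline_sd[v],
                    lower = lower, upper = upper)
      }, numeric(1))
      if (is_severe[e]) base["LOGIK"] <- runif(1L, 3.6, 5.0)

      drift <- if (is_prog[e]) spec$drift_per_visit else rep(0, length(KC_VARIABLES))
      true_vals <- outer(seq_len(k) - 1L, drift) +
        matrix(base, nrow = k, ncol = length(KC_VARIABLES), byrow = TRUE)
      colnames(true_vals) <- KC_VARIABLES
      noise <- matrix(rnorm(k * length(KC_VARIABLES)), nrow = k) *
        matrix(spec$noise_table, nrow = k, ncol = length(KC_VARIABLES), byrow = TRUE)
      obs <- true_vals + noise

      u <- runif(k)
      quality <- ifelse(u < spec$p_red, "RED",
                        ifelse(u < spec$p_red + spec$p_yellow, "YELLOW", "OK"))

      exam_list[[e]] <- data.frame(
        patient_id = sprintf("P%04d", e),
        eye = eye_side[e],
        eye_id = eye_id,
        exam_date = dates,
        quality = quality,
        Age = ages,
        obs,
        stringsAsFactors = FALSE
      )
      traj_list[[e]] <- data.frame(
        eye_id = eye_id, visit = seq_len(k), Age = ages, true_vals,
        stringsAsFactors = FALSE
      )
    }

    cohort <- list(
      exams = do.call(rbind, exam_list),
      truth = data.frame(
        eye_id = sprintf("E%04d", seq_len(n)),
        is_progressive = is_prog,
        severe_baseline = is_severe,
        stringsAsFactors = FALSE
      ),
      trajectory = do.call(rbind, traj_list),
      spec = spec
    )
    rownames(cohort$exams) <- NULL
    rownames(cohort$trajectory) <- NULL
    class(cohort) <- "kc_cohort"
    cohort
  })
}

#' @export
print.kc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic KC cohort: %d eyes, %d exams (%d progressive, %d severe)\n",
              nrow(x$truth), nrow(x$exams), sum(x$truth$is_progressive),
              sum(x$truth$severe_baseline)))
  invisible(x)
}
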