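# Shared internal helpers and the fixed variable/direction vocabulary.

# The six tomography variables carried through the pipeline. Age is the time
# anchor; the other five drive the progression label.
KC_AGE <- "Age"
KC_VARIABLES <- c("KmaxZonalMean3mm", "RsF", "BFSF", "RmB", "LOGIK")
KC_ALL_VARIABLES <- c(KC_AGE, KC_VARIABLES)

# Clinical direction of progression: steepening increases keratometry and the
# logistic KC index, and decreases the front/back radii and best-fit sphere.
KC_DIRECTIONS <- c(
  KmaxZonalMean3mm = "INCREASING",
  RsF  = "DECREASING",
  BFSF = "DECREASING",
  RmB  = "DECREASING",
  LOGIK = "INCREASING"
)

KC_QUALITY_LEVELS <- c("OK", "YELLOW", "RED")

# 95% repeatability limit per unit of within-subject SD: 1.96 * sqrt(2).
KC_REPEATABILITY_FACTOR <- 1.96 * sqrt(2)

# Fixed month length for visit-spacing checks (mean Gregorian month).
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

#' Names of the tomography variables used by the pipeline
#'
#' @param include_age logical; include the `Age` time anchor (default `FALSE`,
#'   returning only the five variables that enter the progression rule).
#' @return Character vector of variable names.
#' @examples
#' kc_variables()
#' kc_variables(include_age = TRUE)
#' @export
kc_variables <- function(include_age = FALSE) {
  if (include_age) KC_ALL_VARIABLES else KC_VARIABLES
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded internals do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stopifnot with a formatted message
check_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
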