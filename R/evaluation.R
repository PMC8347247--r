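# Evaluation: forecast classification, confusion metrics, the repeated
# retrain protocol, Wilcoxon comparison of quality policies and Bland-Altman
# agreement summaries.

METRIC_NAMES <- c("sensitivity", "specificity", "ppv", "npv")

#' Classify forecast values with the measured-label rule
#'
#' Applies exactly the same 95% repeatability criterion as
#' [label_progression()], but to forecast (interpolated) values instead of
#' measured ones — both paths share one implementation of the exceedance
#' rule.
#'
#' @param values Numeric matrix of the five non-age variables (columns named
#'   by variable), e.g. the interpolated forecasts at the actual
#'   second-follow-up date.
#' @param baseline Numeric matrix of the corresponding baseline values, same
#'   shape and column names.
#' @param rt A [compute_repeatability()] table.
#' @return Data frame with `label` and `n_exceed` per row.
#' @export
classify_forecast <- function(values, baseline, rt) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L,
    dimnames = list(NULL, names(values)))
  if (is.null(dim(baseline))) baseline <- matrix(baseline, nrow = 1L,
    dimnames = list(NULL, names(baseline)))
  missing <- setdiff(KC_VARIABLES, colnames(values))
  check_that(length(missing) == 0L, "'values' is missing variable(s): %s",
             paste(missing, collapse = ", "))
  missing <- setdiff(KC_VARIABLES, colnames(baseline))
  check_that(length(missing) == 0L, "'baseline' is missing variable(s): %s",
             paste(missing, collapse = ", "))
  ex <- exceed_matrix(baseline[, KC_VARIABLES, drop = FALSE],
                      values[, KC_VARIABLES, drop = FALSE], rt)
  n_exceed <- as.integer(rowSums(ex))
  data.frame(label = ifelse(n_exceed >= 1L, "SUSPECT_PROGRESSIVE", "STABLE"),
             n_exceed = n_exceed, stringsAsFactors = FALSE)
}

#' Confusion counts and accuracy metrics
#'
#' `SUSPECT_PROGRESSIVE` is the positive class. Ratios with an empty
#' denominator are reported as `NA` (undefined), never silently as zero.
#'
#' @param predicted,measured Character vectors of labels
#'   (`"STABLE"`/`"SUSPECT_PROGRESSIVE"`), equal length.
#' @return List with `counts` (tp, fp, tn, fn) and `metrics` (sensitivity,
#'   specificity, ppv, npv as percentages).
#' @export
confusion_metrics <- function(predicted, measured) {
  check_that(length(predicted) == length(measured),
             "label vectors differ in length (%d vs %d)",
             length(predicted), length(measured))
  pos <- "SUSPECT_PROGRESSIVE"
  counts <- c(
    tp = sum(predicted == pos & measured == pos),
    fp = sum(predicted == pos & measured != pos),
    tn = sum(predicted != pos & measured != pos),
    fn = sum(predicted != pos & measured == pos)
  )
  ratio <- function(num, den) if (den == 0L) NA_real_ else 100 * num / den
  metrics <- c(
    sensitivity = ratio(counts[["tp"]], counts[["tp"]] + counts[["fn"]]),
    specificity = ratio(counts[["tn"]], counts[["tn"]] + counts[["fp"]]),
    ppv = ratio(counts[["tp"]], counts[["tp"]] + counts[["fp"]]),
    npv = ratio(counts[["tn"]], counts[["tn"]] + counts[["fn"]])
  )
  list(counts = counts, metrics = metrics)
}

#' Repeated-retrain evaluation protocol
#'
#' Retrains the network `n_iterations` times, each time with a fresh random
#' development/holdout partition seeded at `base_seed + i`, and evaluates the
#' forecast-based classification on the holdout triplets: the forecast is
#' interpolated to the actual second-follow-up date, classified with the
#' shared repeatability rule and compared against the measured label.
#'
#' @param triplets Preprocessed (labelled, noise-reduced) `kc_triplets` for
#'   one quality policy.
#' @param rt A [compute_repeatability()] table.
#' @param config A [training_config()]; its `seed` is overridden per
#'   iteration.
#' @param n_iterations Number of retrains (default 10).
#' @param base_seed Base seed; iteration `i` uses `base_seed + i`.
#' @param store_models Keep the trained `tdnn_model` of each iteration.
#' @return A list of class `kc_protocol` with per-iteration `metrics` (data
#'   frame including confusion counts), their `mean`, per-triplet holdout
#'   `predictions` and optionally `models`.
#' @export
run_protocol <- function(triplets, rt, config = training_config(),
                         n_iterations = 10L, base_seed = 1L,
                         store_models = FALSE) {
  triplets <- as_triplets(triplets)
  check_that(all(!is.na(triplets$label)),
             "triplets must be labelled before running the protocol")
  check_that(is_count(n_iterations, 1L),
             "'n_iterations' must be a positive integer")
  metrics_rows <- vector("list", n_iterations)
  pred_rows <- vector("list", n_iterations)
  models <- if (store_models) vector("list", n_iterations) else NULL

  for (i in seq_len(n_iterations)) {
    res <- tryCatch(
      protocol_iteration(triplets, rt, config, seed = base_seed + i),
      error = function(err) {
        stop(sprintf("protocol iteration %d (seed %d) failed: %s",
                     i, base_seed + i, conditionMessage(err)), call. = FALSE)
      }
    )
    res$metrics$iteration <- i
    res$predictions$iteration <- i
    metrics_rows[[i]] <- res$metrics
    pred_rows[[i]] <- res$predictions
    if (store_models) models[[i]] <- res$model
  }

  metrics <- do.call(rbind, metrics_rows)
  metrics <- metrics[, c("iteration", "seed", "n_holdout", "tp", "fp", "tn",
                         "fn", METRIC_NAMES)]
  out <- list(
    metrics = metrics,
    mean = aggregate_iterations(metrics),
    predictions = do.call(rbind, pred_rows),
    models = models,
    base_seed = base_seed,
    n_iterations = as.integer(n_iterations)
  )
  class(out) <- "kc_protocol"
  out
}

# One protocol iteration: split, train, forecast, interpolate, classify.
protocol_iteration <- function(triplets, rt, config, seed) {
  sp <- split_data(triplets, config$holdout_fraction, seed = seed)
  cfg <- config
  cfg$seed <- as.integer(seed)
  model <- train_tdnn(sp$development, cfg)
  hold <- sp$holdout

  pred <- predict_followup2(model, hold)
  pred_vals <- as.matrix(pred[, paste0("predicted_", KC_VARIABLES)])
  colnames(pred_vals) <- KC_VARIABLES
  interp <- interpolate_to_actual_date(
    fu1_age = hold$Age_f1,
    fu1_values = triplet_values(hold, "f1"),
    predicted_age = pred$predicted_age,
    predicted_values = pred_vals,
    actual_age = hold$Age_f2
  )
  cls <- classify_forecast(interp, triplet_values(hold, "bl"), rt)

  cm <- confusion_metrics(cls$label, hold$label)
  metrics <- data.frame(seed = seed, n_holdout = nrow(hold),
                        t(cm$counts), t(cm$metrics))

  predictions <- data.frame(
    eye_id = hold$eye_id,
    window_index = hold$window_index,
    measured_label = hold$label,
    predicted_label = cls$label,
    predicted_age = pred$predicted_age,
    actual_age_f2 = hold$Age_f2,
    stringsAsFactors = FALSE
  )
  for (v in KC_VARIABLES) {
    predictions[[paste0("interpolated_", v)]] <- interp[, v]
    predictions[[paste0("measured_", v)]] <- hold[[paste0(v, "_f2")]]
  }
  list(metrics = metrics, predictions = predictions, model = model)
}

#' @export
print.kc_protocol <- function(x, ...) {
  cat(sprintf("Repeated-retrain protocol: %d iterations (base seed %d)\n",
              x$n_iterations, x$base_seed))
  tab <- x$metrics[, c("iteration", METRIC_NAMES)]
  tab[METRIC_NAMES] <- lapply(tab[METRIC_NAMES], round, 1)
  print.data.frame(tab, row.names = FALSE)
  cat("means:", paste(sprintf("%s %.1f%%", METRIC_NAMES,
                              x$mean[METRIC_NAMES]), collapse = ", "), "\n")
  invisible(x)
}

#' Average metrics across protocol iterations
#'
#' Arithmetic mean of sensitivity, specificity, PPV and NPV across
#' iterations. Undefined (NA) iteration values are excluded from the mean
#' with a warning. Values are returned at full precision; round to one
#' decimal for tabular reporting.
#'
#' @param metrics A `kc_protocol`, its `$metrics` data frame, or any data
#'   frame with the four metric columns.
#' @return Named numeric vector of mean percentages.
#' @export
aggregate_iterations <- function(metrics) {
  if (inherits(metrics, "kc_protocol")) metrics <- metrics$metrics
  check_that(is.data.frame(metrics) && nrow(metrics) >= 1L,
             "'metrics' must be a data frame with at least one iteration")
  missing <- setdiff(METRIC_NAMES, names(metrics))
  check_that(length(missing) == 0L, "'metrics' is missing column(s): %s",
             paste(missing, collapse = ", "))
  vapply(METRIC_NAMES, function(m) {
    v <- metrics[[m]]
    if (anyNA(v)) {
      warning(sprintf("excluding %d undefined value(s) of %s from the mean",
                      sum(is.na(v)), m), call. = FALSE)
    }
    mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Compare the metrics of two quality policies by Wilcoxon test
#'
#' The two policies are evaluated on different triplet sets with independent
#' retrains, so the default is the unpaired rank-sum test; `paired = TRUE`
#' switches to the signed-rank test for matched iteration designs. Fully tied
#' samples are reported as inconclusive (`NA` p-value), not as an error.
#'
#' @param metrics1,metrics2 Protocol results (`kc_protocol` or metrics data
#'   frames) for the two policies, each with at least 3 iterations.
#' @param paired Use the paired signed-rank test.
#' @return Data frame with `metric`, `statistic`, `p_value` and `note`.
#' @export
compare_options_wilcoxon <- function(metrics1, metrics2, paired = FALSE) {
  if (inherits(metrics1, "kc_protocol")) metrics1 <- metrics1$metrics
  if (inherits(metrics2, "kc_protocol")) metrics2 <- metrics2$metrics
  check_that(nrow(metrics1) >= 3L && nrow(metrics2) >= 3L,
             "need at least 3 iterations per option")
  rows <- lapply(METRIC_NAMES, function(m) {
    x <- metrics1[[m]][!is.na(metrics1[[m]])]
    y <- metrics2[[m]][!is.na(metrics2[[m]])]
    if (paired) {
      check_that(length(x) == length(y),
                 "paired comparison needs equal iteration counts for %s", m)
      degenerate <- all(x == y)
    } else {
      degenerate <- stats::var(c(x, y)) == 0
    }
    if (degenerate) {
      return(data.frame(metric = m, statistic = NA_real_, p_value = NA_real_,
                        note = "all values tied; test inconclusive",
                        stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired))
    data.frame(metric = m, statistic = unname(wt$statistic),
               p_value = wt$p.value, note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bland-Altman agreement between forecast and measured values
#'
#' For each tomography variable: mean difference (predicted minus measured),
#' 95% limits of agreement (mean difference +/- 1.96 SD of the differences),
#' the repeatability limits +/- r for reference, and the number of
#' differences exceeding r in magnitude (an added convenience, separate from
#' the protocol metrics).
#'
#' @param predicted,measured Numeric matrices of paired values (columns named
#'   by variable, original units); typically interpolated forecasts vs
#'   measured second follow-ups.
#' @param rt A [compute_repeatability()] table.
#' @return Data frame of class `bland_altman`, one row per variable, with the
#'   raw pairs retained in the `"pairs"` attribute for plotting.
#' @export
bland_altman <- function(predicted, measured, rt) {
  check_that(!is.null(dim(predicted)) && !is.null(dim(measured)),
             "'predicted' and 'measured' must be matrices")
  check_that(nrow(predicted) == nrow(measured),
             "'predicted' and 'measured' must have the same number of rows")
  check_that(nrow(predicted) >= 2L, "need at least two pairs")
  rt <- as_rt(rt)
  rows <- lapply(seq_along(KC_VARIABLES), function(j) {
    v <- KC_VARIABLES[j]
    check_that(v %in% colnames(predicted) && v %in% colnames(measured),
               "missing variable '%s'", v)
    d <- predicted[, v] - measured[, v]
    m <- mean(d)
    s <- stats::sd(d)
    data.frame(variable = v, n = length(d), mean_diff = m, sd_diff = s,
               loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
               r = rt$r[j], n_outliers = sum(abs(d) > rt$r[j]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pairs") <- lapply(stats::setNames(KC_VARIABLES, KC_VARIABLES),
                               function(v) data.frame(
                                 mean = (predicted[, v] + measured[, v]) / 2,
                                 diff = predicted[, v] - measured[, v]))
  class(out) <- c("bland_altman", "data.frame")
  out
}

#' @export
plot.bland_altman <- function(x, variables = x$variable, ...) {
  pairs <- attr(x, "pairs")
  old <- graphics::par(mfrow = c(ceiling(length(variables) / 2), 2),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in variables) {
    row <- x[x$variable == v, ]
    p <- pairs[[v]]
    ylim <- range(p$diff, row$loa_lower, row$loa_upper, row$r, -row$r)
    graphics::plot(p$mean, p$diff, xlab = "mean of predicted and measured",
                   ylab = "predicted - measured", main = v, ylim = ylim, ...)
    graphics::abline(h = row$mean_diff, lty = 1)
    graphics::abline(h = c(row$loa_lower, row$loa_upper), lty = 2)
    graphics::abline(h = c(-row$r, row$r), lty = 3)
  }
  invisible(x)
}
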