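# Time-delay neural network: forecast the six second-follow-up values from
# the twelve inputs (six variables at baseline, six at the first follow-up).
#
# The "time delay" structure is a fixed two-exam input window: exam order
# matters, exact spacing does not. Time is anchored through age: the network
# also predicts the age at the forecast visit, and predictions are linearly
# interpolated (or extrapolated) to the actual second-follow-up date before
# classification.
#
# Architecture: 12 inputs -> n_hidden logistic units -> 6 linear outputs.
# Training minimizes the summed squared error over the training rows by
# Levenberg-Marquardt: solve (J'J + lambda I) dw = J'e with the analytic
# Jacobian, decreasing lambda after accepted steps and increasing it after
# rejected ones.

#' Training configuration for the time-delay network
#'
#' @param n_hidden Number of logistic hidden units (default 25).
#' @param holdout_fraction Fraction of triplets reserved for the external
#'   holdout validation (default 0.15); used by [split_data()] /
#'   [run_protocol()], not by [train_tdnn()] itself.
#' @param internal_split Named fractions `train`/`test`/`validation` of the
#'   development set (default 0.70/0.15/0.15; must sum to 1). The validation
#'   subset drives early stopping and model selection; the test subset is
#'   monitored for reporting only.
#' @param max_epochs Maximum number of accepted Levenberg-Marquardt steps.
#' @param lm_lambda0 Initial damping parameter.
#' @param lm_lambda_factor Multiplier applied to the damping on rejected
#'   steps (and its inverse on accepted steps).
#' @param lm_lambda_max Damping level beyond which training is considered
#'   converged/stalled and stops.
#' @param early_stop_patience Consecutive validation-error increases
#'   tolerated before stopping (use `Inf` to disable early stopping).
#' @param seed Integer seed governing weight initialization and the internal
#'   split.
#' @return A validated list of class `training_config`.
#' @export
training_config <- function(n_hidden = 25L,
                            holdout_fraction = 0.15,
                            internal_split = c(train = 0.70, test = 0.15,
                                               validation = 0.15),
                            max_epochs = 1000L,
                            lm_lambda0 = 1e-3,
                            lm_lambda_factor = 10,
                            lm_lambda_max = 1e10,
                            early_stop_patience = 6L,
                            seed = 1L) {
  check_that(is_count(n_hidden, 1L), "'n_hidden' must be a positive integer")
  check_that(is.numeric(holdout_fraction) && holdout_fraction > 0 &&
               holdout_fraction < 1, "'holdout_fraction' must be in (0, 1)")
  check_that(all(c("train", "test", "validation") %in% names(internal_split)),
             "'internal_split' needs train/test/validation entries")
  check_that(abs(sum(internal_split) - 1) < 1e-9,
             "'internal_split' fractions must sum to 1")
  check_that(all(internal_split >= 0), "'internal_split' fractions must be >= 0")
  check_that(is_count(max_epochs), "'max_epochs' must be a non-negative integer")
  check_that(lm_lambda0 > 0, "'lm_lambda0' must be positive")
  check_that(lm_lambda_factor > 1, "'lm_lambda_factor' must exceed 1")
  check_that(is.infinite(early_stop_patience) || is_count(early_stop_patience, 1L),
             "'early_stop_patience' must be a positive integer or Inf")
  structure(
    list(n_hidden = as.integer(n_hidden),
         holdout_fraction = holdout_fraction,
         internal_split = internal_split[c("train", "test", "validation")],
         max_epochs = as.integer(max_epochs),
         lm_lambda0 = lm_lambda0,
         lm_lambda_factor = lm_lambda_factor,
         lm_lambda_max = lm_lambda_max,
         early_stop_patience = early_stop_patience,
         seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Split triplets into a development and a holdout set
#'
#' Random partition at the triplet level (triplets from one eye have
#' different baselines, intervals and targets, so the triplet is the
#' exchangeable unit). The holdout size is `round(fraction * n)`.
#'
#' @param triplets A `kc_triplets` table.
#' @param holdout_fraction Fraction held out, in (0, 1).
#' @param seed Integer seed making the partition reproducible.
#' @return List with disjoint, exhaustive `development` and `holdout` tables.
#' @export
split_data <- function(triplets, holdout_fraction = 0.15, seed = 1L) {
  triplets <- as_triplets(triplets)
  n <- nrow(triplets)
  check_that(n >= 2L, "need at least two triplets to split")
  check_that(is.numeric(holdout_fraction) && holdout_fraction > 0 &&
               holdout_fraction < 1, "'holdout_fraction' must be in (0, 1)")
  n_hold <- round(holdout_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_hold))
  list(development = triplets[setdiff(seq_len(n), idx), , drop = FALSE],
       holdout = triplets[idx, , drop = FALSE])
}

## ---- weight packing ------------------------------------------------------

N_IN <- 12L
N_OUT <- 6L

n_params <- function(h) h * N_IN + h + N_OUT * h + N_OUT

unpack_weights <- function(w, h) {
  i <- 0L
  W1 <- matrix(w[i + seq_len(h * N_IN)], h, N_IN); i <- i + h * N_IN
  b1 <- w[i + seq_len(h)]; i <- i + h
  W2 <- matrix(w[i + seq_len(N_OUT * h)], N_OUT, h); i <- i + N_OUT * h
  b2 <- w[i + seq_len(N_OUT)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

pack_weights <- function(p) c(p$W1, p$b1, p$W2, p$b2)

logistic <- function(z) 1 / (1 + exp(-z))

# inputs: [baseline 6 vars, follow-up-1 6 vars] in normalized units
tdnn_design <- function(triplets) {
  X <- cbind(triplet_values(triplets, "bl", KC_ALL_VARIABLES),
             triplet_values(triplets, "f1", KC_ALL_VARIABLES))
  colnames(X) <- c(slot_cols(KC_ALL_VARIABLES, "bl"),
                   slot_cols(KC_ALL_VARIABLES, "f1"))
  X
}

tdnn_targets <- function(triplets) {
  Y <- triplet_values(triplets, "f2", KC_ALL_VARIABLES)
  colnames(Y) <- KC_ALL_VARIABLES
  Y
}

#' Forward pass of the time-delay network
#'
#' Computes `W2 %*% logistic(W1 %*% x + b1) + b2` for each row of `inputs`:
#' logistic hidden layer, linear output layer (the regression targets are
#' unbounded in normalized units).
#'
#' @param model A `tdnn_model` (or a bare list with `W1`, `b1`, `W2`, `b2`).
#' @param inputs Numeric matrix with 12 columns (or a single 12-vector), in
#'   normalized units.
#' @return Numeric matrix with 6 columns named by variable.
#' @export
forward_tdnn <- function(model, inputs) {
  p <- if (!is.null(model$W1)) model else unpack_weights(model$weights,
                                                         model$n_hidden)
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1L)
  check_that(ncol(inputs) == N_IN,
             "'inputs' must have %d columns, got %d", N_IN, ncol(inputs))
  H <- logistic(inputs %*% t(p$W1) +
                  matrix(p$b1, nrow(inputs), length(p$b1), byrow = TRUE))
  Y <- H %*% t(p$W2) + matrix(p$b2, nrow(inputs), N_OUT, byrow = TRUE)
  colnames(Y) <- KC_ALL_VARIABLES
  Y
}

# Analytic Jacobian of the stacked outputs w.r.t. the packed weights.
# Rows are ordered output-major: all samples for output 1, then output 2, ...
# matching c(Y) of an n x 6 output matrix.
tdnn_jacobian <- function(w, X, h) {
  p <- unpack_weights(w, h)
  n <- nrow(X)
  H <- logistic(X %*% t(p$W1) + matrix(p$b1, n, h, byrow = TRUE))
  D <- H * (1 - H)
  blocks <- vector("list", N_OUT)
  col_h <- rep(seq_len(h), times = N_IN)
  col_x <- rep(seq_len(N_IN), each = h)
  for (k in seq_len(N_OUT)) {
    A <- D * matrix(p$W2[k, ], n, h, byrow = TRUE)
    J_W1 <- A[, col_h, drop = FALSE] * X[, col_x, drop = FALSE]
    J_W2 <- matrix(0, n, N_OUT * h)
    J_W2[, (seq_len(h) - 1L) * N_OUT + k] <- H
    J_b2 <- matrix(0, n, N_OUT)
    J_b2[, k] <- 1
    blocks[[k]] <- cbind(J_W1, A, J_W2, J_b2)
  }
  do.call(rbind, blocks)
}

## ---- training ------------------------------------------------------------

#' Train the time-delay network by Levenberg-Marquardt
#'
#' Fits the 12-input/6-output network on a development set of preprocessed
#' (labelled, noise-reduced) triplets. Normalization constants are fitted on
#' the development set (unless supplied) and stored with the model. The
#' development set is split internally into training, test and validation
#' subsets; each accepted Levenberg-Marquardt step must decrease the training
#' error, and training stops at `max_epochs`, when the damping exceeds
#' `lm_lambda_max`, or after `early_stop_patience` consecutive increases of
#' the validation error. The returned weights are those with the lowest
#' validation error seen.
#'
#' @param triplets Development `kc_triplets` table.
#' @param config A [training_config()].
#' @param constants Optional pre-fitted normalization constants.
#' @return A `tdnn_model`: packed weights, layer sizes, normalization
#'   constants, config and an epoch-by-epoch history.
#' @export
train_tdnn <- function(triplets, config = training_config(), constants = NULL) {
  triplets <- as_triplets(triplets)
  check_that(inherits(config, "training_config"),
             "'config' must be a training_config")
  norm <- normalize_triplets(triplets, constants)
  X <- tdnn_design(norm$triplets)
  Y <- tdnn_targets(norm$triplets)
  check_that(nrow(X) >= 3L, "need at least three development triplets")
  fit <- lm_fit(X, Y, config)
  model <- c(fit, list(constants = norm$constants, config = config))
  class(model) <- "tdnn_model"
  model
}

# Core Levenberg-Marquardt trainer on raw (already normalized) design and
# target matrices. Returns packed weights (best validation error), layer
# size, history and the internal split indices.
lm_fit <- function(X, Y, config) {
  n <- nrow(X)
  h <- config$n_hidden

  state <- with_seed(config$seed, {
    perm <- sample.int(n)
    n_val <- round(config$internal_split[["validation"]] * n)
    n_test <- round(config$internal_split[["test"]] * n)
    w0 <- c(runif(h * N_IN, -1, 1) / sqrt(N_IN),
            runif(h, -1, 1) / sqrt(N_IN),
            runif(N_OUT * h, -1, 1) / sqrt(h),
            runif(N_OUT, -1, 1) / sqrt(h))
    list(perm = perm, n_val = n_val, n_test = n_test, w0 = w0)
  })
  idx_val <- state$perm[seq_len(state$n_val)]
  idx_test <- state$perm[state$n_val + seq_len(state$n_test)]
  n_held <- state$n_val + state$n_test
  idx_train <- if (n_held == 0L) state$perm else state$perm[-seq_len(n_held)]
  check_that(length(idx_train) >= 1L, "internal training subset is empty")

  mse <- function(w, idx) {
    if (length(idx) == 0L) return(NA_real_)
    E <- Y[idx, , drop = FALSE] - forward_tdnn(unpack_weights(w, h),
                                               X[idx, , drop = FALSE])
    mean(E^2)
  }

  w <- state$w0
  lambda <- config$lm_lambda0
  Xtr <- X[idx_train, , drop = FALSE]
  Ytr <- Y[idx_train, , drop = FALSE]
  resid_vec <- function(w) c(Ytr - forward_tdnn(unpack_weights(w, h), Xtr))
  e <- resid_vec(w)
  sse <- sum(e^2)
  if (!is.finite(sse)) stop("non-finite training loss at initialization",
                            call. = FALSE)

  history <- vector("list", 0L)
  best_w <- w
  best_val <- mse(w, idx_val)
  prev_val <- best_val
  streak <- 0L
  p <- n_params(h)

  epoch <- 0L
  while (epoch < config$max_epochs) {
    J <- tdnn_jacobian(w, Xtr, h)
    g <- crossprod(J, e)
    A <- crossprod(J)
    accepted <- FALSE
    while (!accepted && lambda <= config$lm_lambda_max) {
      step <- tryCatch(solve(A + diag(lambda, p), g), error = function(err) NULL)
      if (!is.null(step)) {
        w_new <- w + as.vector(step)
        e_new <- resid_vec(w_new)
        sse_new <- sum(e_new^2)
        if (is.finite(sse_new) && sse_new < sse) {
          w <- w_new; e <- e_new; sse <- sse_new
          lambda <- lambda / config$lm_lambda_factor
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * config$lm_lambda_factor
    }
    if (!accepted) break  # damping exhausted: no descent direction left
    epoch <- epoch + 1L

    val <- mse(w, idx_val)
    history[[epoch]] <- data.frame(
      epoch = epoch, lambda = lambda, train_mse = sse / length(e),
      val_mse = val, test_mse = mse(w, idx_test)
    )
    if (!is.na(val)) {
      if (val < best_val || is.na(best_val)) {
        best_val <- val
        best_w <- w
      }
      if (!is.na(prev_val) && val > prev_val) {
        streak <- streak + 1L
      } else {
        streak <- 0L
      }
      prev_val <- val
      if (streak >= config$early_stop_patience) break
    } else {
      best_w <- w
    }
  }
  if (length(idx_val) == 0L) best_w <- w

  list(
    weights = best_w,
    n_hidden = h,
    history = if (length(history)) do.call(rbind, history) else
      data.frame(epoch = integer(0), lambda = numeric(0),
                 train_mse = numeric(0), val_mse = numeric(0),
                 test_mse = numeric(0)),
    internal_split = list(train = idx_train, test = idx_test,
                          validation = idx_val)
  )
}

#' @export
print.tdnn_model <- function(x, ...) {
  cat(sprintf("Time-delay network: 12 -> %d logistic -> 6 linear (%d weights)\n",
              x$n_hidden, length(x$weights)))
  if (nrow(x$history) > 0L) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d accepted LM epochs; final train MSE %.3e, val MSE %.3e\n",
                nrow(x$history), last$train_mse, last$val_mse))
  } else {
    cat("  untrained (no accepted epochs)\n")
  }
  invisible(x)
}

#' Forecast the second follow-up of preprocessed triplets
#'
#' Feeds the 12 inputs (baseline and first follow-up, six variables each)
#' through the trained network and denormalizes the six outputs. The
#' predicted `Age` output anchors the forecast in time.
#'
#' @param model A trained `tdnn_model`.
#' @param triplets Preprocessed (noise-reduced, unnormalized) triplets; they
#'   are normalized internally with the model's stored constants.
#' @return Data frame with `eye_id`, `window_index`, `predicted_<var>` for
#'   the six variables, `predicted_age` (alias of `predicted_Age`) and
#'   `actual_age_f2`.
#' @export
predict_followup2 <- function(model, triplets) {
  check_that(inherits(model, "tdnn_model"), "'model' must be a tdnn_model")
  check_that(!is.null(model$constants), "model has no normalization constants")
  triplets <- as_triplets(triplets)
  norm <- normalize_triplets(triplets, model$constants)
  Yhat <- forward_tdnn(model, tdnn_design(norm$triplets))
  Yhat <- denormalize_values(Yhat, model$constants)
  out <- data.frame(
    eye_id = triplets$eye_id,
    window_index = if (!is.null(triplets$window_index)) triplets$window_index
      else NA_integer_,
    stringsAsFactors = FALSE
  )
  for (v in KC_ALL_VARIABLES) out[[paste0("predicted_", v)]] <- Yhat[, v]
  out$predicted_age <- Yhat[, KC_AGE]
  out$actual_age_f2 <- triplets$Age_f2
  out
}

#' Linearly interpolate a forecast to the actual follow-up date
#'
#' The network forecasts the five tomography variables at its own predicted
#' age; the patient returns at a different date. Each variable is carried
#' along the line through (first-follow-up age, first-follow-up value) and
#' (predicted age, predicted value), evaluated at the actual age — linear
#' extrapolation when the actual visit falls beyond the forecast date.
#'
#' @param fu1_age,predicted_age,actual_age Numeric vectors of ages in years.
#' @param fu1_values,predicted_values Numeric matrices (rows matching the age
#'   vectors) with columns named by variable.
#' @return Matrix of interpolated values, same shape as `predicted_values`.
#' @export
interpolate_to_actual_date <- function(fu1_age, fu1_values,
                                       predicted_age, predicted_values,
                                       actual_age) {
  if (is.null(dim(fu1_values))) fu1_values <- matrix(fu1_values, nrow = 1L,
    dimnames = list(NULL, names(fu1_values)))
  if (is.null(dim(predicted_values))) predicted_values <- matrix(
    predicted_values, nrow = 1L, dimnames = list(NULL, names(predicted_values)))
  check_that(identical(colnames(fu1_values), colnames(predicted_values)),
             "value matrices must have identical variable columns")
  if (any(predicted_age == fu1_age)) {
    stop("degenerate forecast: predicted age equals first-follow-up age",
         call. = FALSE)
  }
  t <- (actual_age - fu1_age) / (predicted_age - fu1_age)
  fu1_values + (predicted_values - fu1_values) * t
}

## ---- persistence ---------------------------------------------------------

#' Save / load a trained model as plain-text JSON
#'
#' The archive holds the packed weights, layer size, normalization constants,
#' configuration and training history, so a run can be re-examined or reused
#' without retraining.
#'
#' @param model A `tdnn_model`.
#' @param path File path for the JSON archive.
#' @return `save_tdnn()` returns `path` invisibly; `load_tdnn()` returns the
#'   restored `tdnn_model`.
#' @export
save_tdnn <- function(model, path) {
  check_that(inherits(model, "tdnn_model"), "'model' must be a tdnn_model")
  cfg <- unclass(model$config)
  # JSON has no Inf: encode "no early stopping" as -1
  if (is.infinite(cfg$early_stop_patience)) cfg$early_stop_patience <- -1
  cfg$internal_split <- as.list(cfg$internal_split)  # keep the names in JSON
  payload <- list(
    weights = model$weights,
    n_hidden = model$n_hidden,
    constants = as.list(model$constants),
    config = cfg,
    history = model$history
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_tdnn
#' @export
load_tdnn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- training_config(
    n_hidden = cfg$n_hidden,
    holdout_fraction = cfg$holdout_fraction,
    internal_split = unlist(cfg$internal_split),
    max_epochs = cfg$max_epochs,
    lm_lambda0 = cfg$lm_lambda0,
    lm_lambda_factor = cfg$lm_lambda_factor,
    lm_lambda_max = cfg$lm_lambda_max,
    early_stop_patience = if (is.null(cfg$early_stop_patience) ||
                                cfg$early_stop_patience < 0) Inf else
      cfg$early_stop_patience,
    seed = cfg$seed
  )
  model <- list(
    weights = as.numeric(payload$weights),
    n_hidden = as.integer(payload$n_hidden),
    constants = unlist(payload$constants),
    config = config,
    history = as.data.frame(payload$history)
  )
  class(model) <- "tdnn_model"
  model
}
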