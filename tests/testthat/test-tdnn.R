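# Network forward pass, analytic Jacobian, Levenberg-Marquardt trainer,
# data splitting, forecasting and date interpolation.

test_that("forward pass handles degenerate weight settings", {
  h <- 7
  zero <- list(W1 = matrix(0, h, 12), b1 = rep(0, h),
               W2 = matrix(0, 6, h), b2 = rep(0, 6))
  X <- matrix(rnorm(24), 2, 12)
  expect_equal(unname(forward_tdnn(zero, X)), matrix(0, 2, 6))

  const <- zero
  const$b2 <- 1:6
  expect_equal(unname(forward_tdnn(const, X)),
               matrix(1:6, 2, 6, byrow = TRUE))

  expect_error(forward_tdnn(zero, matrix(0, 2, 5)), "12 columns")
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(17)
  for (h in c(3L, 8L)) {
    w <- runif(keraprog:::n_params(h), -0.8, 0.8)
    X <- matrix(runif(4 * 12, -1, 1), 4, 12)
    J <- keraprog:::tdnn_jacobian(w, X, h)
    eps <- 1e-6
    num <- vapply(seq_along(w), function(j) {
      wp <- w; wp[j] <- wp[j] + eps
      wm <- w; wm[j] <- wm[j] - eps
      (c(forward_tdnn(keraprog:::unpack_weights(wp, h), X)) -
         c(forward_tdnn(keraprog:::unpack_weights(wm, h), X))) / (2 * eps)
    }, numeric(4 * 6))
    expect_lt(max(abs(J - num)) / max(abs(J)), 1e-6)
  }
})

test_that("development/holdout split is a seeded partition of the triplets", {
  rt <- default_rt()
  tr <- random_triplets(20, rt, seed = 2)
  sp <- split_data(tr, 0.15, seed = 10)
  expect_equal(nrow(sp$holdout), 3L)
  expect_equal(nrow(sp$development), 17L)

  sp2 <- split_data(tr, 0.15, seed = 10)
  expect_identical(sp$holdout$eye_id, sp2$holdout$eye_id)

  for (n in c(7, 23, 104)) {
    trn <- random_triplets(n, rt, seed = n)
    spn <- split_data(trn, 0.2, seed = 3)
    ids <- sort(c(spn$holdout$eye_id, spn$development$eye_id))
    expect_identical(ids, sort(trn$eye_id))
    expect_length(intersect(spn$holdout$eye_id, spn$development$eye_id), 0L)
  }
  expect_error(split_data(tr, 1.2, seed = 1), "in \\(0, 1\\)")
})

test_that("Levenberg-Marquardt training is seeded, monotone and stoppable", {
  set.seed(23)
  X <- matrix(runif(120 * 12, -1, 1), 120, 12)
  Y <- X[, 1:6] + 0.05 * matrix(rnorm(120 * 6), 120, 6)
  cfg <- training_config(n_hidden = 6, max_epochs = 40, seed = 4)

  fit1 <- keraprog:::lm_fit(X, Y, cfg)
  fit2 <- keraprog:::lm_fit(X, Y, cfg)
  expect_identical(fit1$weights, fit2$weights)
  expect_identical(fit1$history, fit2$history)

  # accepted-step training loss is non-increasing
  expect_false(is.unsorted(rev(fit1$history$train_mse)))

  # max_epochs = 0 returns the untrained initialization
  cfg0 <- training_config(n_hidden = 6, max_epochs = 0, seed = 4)
  fit0a <- keraprog:::lm_fit(X, Y, cfg0)
  fit0b <- keraprog:::lm_fit(X, Y, cfg0)
  expect_equal(nrow(fit0a$history), 0L)
  expect_identical(fit0a$weights, fit0b$weights)
  # the init differs from the trained weights
  expect_false(isTRUE(all.equal(fit0a$weights, fit1$weights)))
})

test_that("the trainer recovers a noiseless identity mapping to high accuracy", {
  set.seed(3)
  n <- 400
  X <- matrix(runif(n * 12, -1, 1), n, 12)
  Y <- X[, 1:6]
  cfg <- training_config(n_hidden = 10, max_epochs = 250,
                         early_stop_patience = Inf, seed = 5)
  fit <- keraprog:::lm_fit(X, Y, cfg)
  final_rmse <- sqrt(fit$history$train_mse[nrow(fit$history)])
  expect_lt(final_rmse, 1e-3)
})

test_that("the trainer matches an independent Levenberg-Marquardt optimizer", {
  skip_if_not_installed("minpack.lm")
  set.seed(47)
  n <- 60
  X <- matrix(runif(n * 12, -1, 1), n, 12)
  Y <- X[, 1:6] * 0.5 + 0.1
  cfg <- training_config(n_hidden = 3, max_epochs = 150,
                         early_stop_patience = Inf, seed = 6,
                         internal_split = c(train = 1, test = 0,
                                            validation = 0))
  fit <- keraprog:::lm_fit(X, Y, cfg)
  sse_own <- fit$history$train_mse[nrow(fit$history)] * n * 6

  # same residual function, same seeded initialization, reference optimizer
  w0 <- keraprog:::with_seed(6, {
    sample.int(n)
    c(runif(3 * 12, -1, 1) / sqrt(12), runif(3, -1, 1) / sqrt(12),
      runif(6 * 3, -1, 1) / sqrt(3), runif(6, -1, 1) / sqrt(3))
  })
  resid_fn <- function(w) {
    c(Y - forward_tdnn(keraprog:::unpack_weights(w, 3), X))
  }
  ref <- minpack.lm::nls.lm(par = w0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, maxfev = 100000))
  sse_ref <- sum(ref$fvec^2)
  # both optimizers should reach an essentially equivalent minimum
  expect_lt(abs(sse_own - sse_ref), 0.1 * max(sse_ref, 1e-6) + 1e-8)
})

test_that("a model trained on a stationary cohort forecasts the baseline", {
  rt <- default_rt()
  sw_tiny <- setNames(rep(1e-4, 5), kc_variables()) * unname(default_sw())
  spec <- cohort_spec(n_eyes = 80, visits_per_eye = 3,
                      progressive_fraction = 0, noise_table = sw_tiny,
                      p_yellow = 0, p_red = 0, p_severe = 0, seed = 19)
  pp <- prepare_triplets(generate_cohort(spec), rt)
  model <- train_tdnn(pp, training_config(n_hidden = 8, max_epochs = 80,
                                          seed = 19))
  pred <- predict_followup2(model, pp)
  for (v in kc_variables()) {
    rel <- abs(pred[[paste0("predicted_", v)]] - pp[[paste0(v, "_bl")]]) /
      abs(pp[[paste0(v, "_bl")]])
    expect_lt(stats::median(rel), 0.02)
  }
  # forecasting is deterministic
  pred2 <- predict_followup2(model, pp)
  expect_identical(pred, pred2)
})

test_that("predicted age moves forward on an aging cohort", {
  rt <- default_rt()
  spec <- clean_spec(n_eyes = 60, visits = 3, progressive_fraction = 0.5,
                     seed = 29)
  pp <- prepare_triplets(generate_cohort(spec), rt)
  model <- train_tdnn(pp, training_config(n_hidden = 10, max_epochs = 120,
                                          seed = 29))
  pred <- predict_followup2(model, pp)
  expect_gt(mean(pred$predicted_age > pp$Age_f1), 0.95)
})

test_that("interpolation follows the line through follow-up 1 and the forecast", {
  f1_age <- 30
  pred_age <- 31
  f1 <- setNames(c(48, 6.8, 7.8, 6.4, 1.5), kc_variables())
  pred <- setNames(c(49, 6.7, 7.7, 6.3, 1.9), kc_variables())

  # endpoint: actual age equal to the predicted age returns the forecast
  expect_equal(
    interpolate_to_actual_date(f1_age, f1, pred_age, pred, pred_age)[1, ],
    pred)
  # midpoint: arithmetic mean
  expect_equal(
    interpolate_to_actual_date(f1_age, f1, pred_age, pred, 30.5)[1, ],
    (f1 + pred) / 2)

  # extrapolation checked against an independent two-point line fit
  actual <- 31.8
  got <- interpolate_to_actual_date(f1_age, f1, pred_age, pred, actual)[1, ]
  for (v in kc_variables()) {
    line <- lm(y ~ x, data = data.frame(x = c(f1_age, pred_age),
                                        y = c(f1[[v]], pred[[v]])))
    expect_equal(got[[v]],
                 unname(predict(line, newdata = data.frame(x = actual))))
  }

  # degenerate slope is rejected
  expect_error(interpolate_to_actual_date(f1_age, f1, f1_age, pred, 30.5),
               "degenerate")
})

test_that("model archives round trip through JSON", {
  rt <- default_rt()
  pp <- prepare_triplets(
    generate_cohort(clean_spec(30, progressive_fraction = 0.5, seed = 37)), rt)
  model <- train_tdnn(pp, fast_config(seed = 37))
  path <- tempfile(fileext = ".json")
  save_tdnn(model, path)
  back <- load_tdnn(path)
  expect_equal(back$weights, model$weights)
  expect_equal(back$constants, model$constants)
  expect_equal(predict_followup2(back, pp), predict_followup2(model, pp))
})
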