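test_that("early stopping reproduces hand-stepped decisions", {
  # spec of the stopping rule: improvement = beating the best loss so far by
  # at least min_delta; stop after `patience` consecutive non-improvements
  expect_equal(early_stop_epoch(c(1.0, 0.999, 0.998, 0.9975, 0.997, 0.9968),
                                min_delta = 0.003, patience = 5), 6L)
  # steadily improving run exhausts max_epochs
  expect_equal(early_stop_epoch(seq(1, 0.5, length.out = 40)), 35L)
  # big improvements reset the wait counter
  expect_equal(early_stop_epoch(c(1, 0.996, 0.9, 0.899, 0.898, 0.8975,
                                  0.897, 0.8965, 0.85, 0.849, 0.8485,
                                  0.848, 0.8475, 0.847)), 14L)
  expect_equal(early_stop_epoch(rep(0.5, 20), patience = 3), 4L)
})

test_that("smoothed error matches the hand-stepped EWMA recursion", {
  e <- c(0, 0, 1, 0, 0)
  se <- smoothed_error(e, rep(0, 5), span = 2)     # alpha = 2/3
  expect_equal(se$e_s, c(0, 0, 2 / 3, 2 / 9, 2 / 27))
  expect_true(all(se$e_s >= 0 & se$e_s <= 1))
  # span 1 is the no-smoothing limit; identical series give zero error
  expect_equal(smoothed_error(c(1, 2, 3), c(0, 1, 1), span = 1)$e_s,
               c(1, 1, 2))
  expect_equal(smoothed_error(c(1, 2), c(1, 2), span = 3)$e_s, c(0, 0))
  expect_error(smoothed_error(1:3, 1:4), class = "seegwatch_parameter_error")
})

test_that("smoothed error is monotone: larger raw errors never lower e_s", {
  set.seed(11)
  for (i in 1:20) {
    a <- abs(rnorm(50)); p <- rep(0, 50)
    bump <- a + runif(50, 0, 0.5)
    lo <- smoothed_error(a, p, span = 5)$e_s
    hi <- smoothed_error(bump, p, span = 5)$e_s
    expect_true(all(hi >= lo - 1e-12))
  }
})

test_that("MAPE computes percent error with a denominator floor", {
  expect_equal(mape(c(1, 2, 4), c(1, 2, 4)), 0)
  expect_equal(mape(c(1, 2, 4), c(1.1, 1.8, 4.4)), 10)
  expect_equal(mape(c(1e-4, 1), c(1, 1), denom_floor = 1e-3), 0)
  expect_error(mape(c(1e-5, 1e-6), c(1, 1)), class = "seegwatch_data_error")
})

test_that("naive and AR forecasters satisfy the rolling-forecast contract", {
  s <- channel_series(c(1, 2, 3, 4), 10)
  cfg <- forecast_config(history_window = 2L)
  m <- fit_forecaster(s, cfg, method = "naive")
  expect_equal(predict(m, s), c(2, 3))           # predicts the last seen value

  # alignment: length l_b + k input gives k predictions for any method
  set.seed(3)
  tr <- channel_series(rnorm(500), 100)
  for (method in c("naive", "ar")) {
    m <- fit_forecaster(tr, forecast_config(history_window = 50L),
                        method = method)
    te <- channel_series(rnorm(57), 100)
    expect_length(predict(m, te), 7L)
  }

  # AR baseline is a sane one-step predictor on a periodic signal: its errors
  # are far below signal scale and comparable to an independent stats::ar fit
  s <- sine_series()
  sp <- split_train_test(s, 0.3)
  m <- fit_forecaster(sp$train, forecast_config(history_window = 32L),
                      method = "ar")
  pred <- predict(m, sp$test)
  actual <- sp$test$values[33:length(sp$test$values)]
  expect_lt(sqrt(mean((actual - pred)^2)), 0.05)
  expect_error(predict(m, channel_series(1:10, 64)),
               class = "seegwatch_parameter_error")   # shorter than l_b
})

test_that("held-out error does not grow with more training data (AR, clean signal)", {
  errs <- vapply(c(10, 30, 60), function(dur) {
    s <- sine_series(duration_s = dur + 20)
    tr <- channel_series(s$values[seq_len(dur * 64)], 64)
    te <- channel_series(s$values[(dur * 64 + 1):length(s$values)], 64)
    m <- fit_forecaster(tr, forecast_config(history_window = 32L), method = "ar")
    mape(te$values[33:length(te$values)], predict(m, te))
  }, numeric(1))
  expect_true(all(diff(errs) < 0.5))   # decreasing or flat within tolerance
})

test_that("LSTM gradients match central finite differences", {
  set.seed(42)
  par <- seegwatch:::lstm_init(3L, 2L)
  X <- matrix(rnorm(8), 2, 4)
  Y <- matrix(rnorm(4), 2, 2)
  fwd <- seegwatch:::lstm_forward(par, X, keep_cache = TRUE)
  gr <- seegwatch:::lstm_backward(par, fwd, X, Y)
  eps <- 1e-5
  for (nm in c("Wx", "Wh", "b", "Wy", "by")) {
    idx <- sample(length(par[[nm]]), min(5L, length(par[[nm]])))
    for (i in idx) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (mean((seegwatch:::lstm_forward(pp, X)$pred - Y)^2) -
               mean((seegwatch:::lstm_forward(pm, X)$pred - Y)^2)) / (2 * eps)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("LSTM training is seeded-deterministic and fits a trivial series", {
  z <- channel_series(rep(0, 400), 64)
  cfg <- forecast_config(hidden_units = 8L, history_window = 16L,
                         max_epochs = 10L, seed = 5L)
  m1 <- fit_forecaster(z, cfg, method = "lstm")
  m2 <- fit_forecaster(z, cfg, method = "lstm")
  expect_identical(m1$training_history, m2$training_history)
  expect_lt(m1$training_history$train_loss[nrow(m1$training_history)], 1e-4)
  expect_lte(nrow(m1$training_history), 10L)
  expect_error(fit_forecaster(channel_series(1:10, 64), cfg, method = "lstm"),
               class = "seegwatch_parameter_error")
})

test_that("models save/load losslessly and flag foreign patients, not reject them", {
  s <- sine_series(duration_s = 15, patient = "patA")
  m <- fit_forecaster(split_train_test(s, 0.5)$train,
                      lstm_test_config(max_epochs = 3L), method = "lstm")
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  te <- split_train_test(s, 0.5)$test
  expect_identical(predict(m, te), predict(m2, te))

  other <- sine_series(duration_s = 10, patient = "patB")
  expect_message(predict(m2, other), "crossover")   # allowed, logged

  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_model(bad), class = "seegwatch_data_error")
  saveRDS(list(a = 1), bad)
  expect_error(load_model(bad), class = "seegwatch_data_error")
})
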