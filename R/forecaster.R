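#' Forecaster configuration
#'
#' Training regimen for the self-supervised per-channel forecaster. Defaults
#' follow the clinical pipeline this package implements: up to 35 epochs with
#' early stopping once 5 consecutive epochs fail to improve the validation
#' MSE by at least 0.003, Adam optimisation, dropout 0.3, a chronological 20%
#' validation split, and an 80-unit recurrent layer.
#'
#' @param hidden_units LSTM hidden-state size (default 80).
#' @param max_epochs maximum training epochs (default 35).
#' @param early_stop_min_delta minimum absolute decrease in validation MSE
#'   that counts as an improvement (default 0.003).
#' @param early_stop_patience consecutive non-improving epochs tolerated
#'   before stopping (default 5).
#' @param dropout dropout probability on the final hidden state (default 0.3).
#' @param validation_fraction chronological tail of the training windows held
#'   out for validation (default 0.2).
#' @param history_window `l_b`: samples of history fed to the model (default
#'   250).
#' @param horizon `l_f`: samples predicted per step (default 1; when > 1 only
#'   the first predicted value is retained, stride 1).
#' @param learning_rate Adam learning rate (default 0.01).
#' @param lr_plateau_decay multiplicative learning-rate decay applied after
#'   each non-improving epoch while waiting out the patience window
#'   (default 0.5).
#' @param batch_size minibatch size (default 32).
#' @param train_stride stride between training windows; `NULL` picks the
#'   smallest stride that caps the window count at `max_windows`.
#' @param max_windows cap on training windows when `train_stride` is `NULL`.
#' @param ar_order order of the autoregressive baseline (default 16).
#' @param seed RNG seed for weight init, shuffling and dropout.
#' @return a validated list of class `forecast_config`.
#' @export
forecast_config <- function(hidden_units = 80L, max_epochs = 35L,
                            early_stop_min_delta = 0.003,
                            early_stop_patience = 5L, dropout = 0.3,
                            validation_fraction = 0.2,
                            history_window = 250L, horizon = 1L,
                            learning_rate = 0.01, lr_plateau_decay = 0.5,
                            batch_size = 32L,
                            train_stride = NULL, max_windows = 1500L,
                            ar_order = 16L, seed = 1L) {
  assert_scalar_number(hidden_units, "hidden_units", lower = 1)
  assert_scalar_number(max_epochs, "max_epochs", lower = 1)
  assert_scalar_number(early_stop_patience, "early_stop_patience", lower = 1)
  assert_scalar_number(validation_fraction, "validation_fraction",
                       lower = 1e-9, upper = 1 - 1e-9)
  assert_scalar_number(history_window, "history_window", lower = 1)
  assert_scalar_number(horizon, "horizon", lower = 1)
  assert_scalar_number(dropout, "dropout", lower = 0, upper = 0.99)
  structure(list(
    hidden_units = as.integer(hidden_units), max_epochs = as.integer(max_epochs),
    early_stop_min_delta = early_stop_min_delta,
    early_stop_patience = as.integer(early_stop_patience), dropout = dropout,
    validation_fraction = validation_fraction,
    history_window = as.integer(history_window), horizon = as.integer(horizon),
    learning_rate = learning_rate, lr_plateau_decay = lr_plateau_decay,
    batch_size = as.integer(batch_size),
    train_stride = train_stride, max_windows = as.integer(max_windows),
    ar_order = as.integer(ar_order), seed = as.integer(seed)
  ), class = "forecast_config")
}

# Early-stopping bookkeeping, applied epoch by epoch on validation losses:
# an epoch improves iff it beats the best loss so far by >= min_delta;
# otherwise a wait counter increments, and training stops once `patience`
# consecutive non-improving epochs have occurred.

#' Early-stopping decision for a loss trace
#'
#' Applies the training stop rule (minimum improvement `min_delta` over the
#' best loss so far, tolerated for at most `patience` consecutive epochs) to a
#' full per-epoch loss trace and reports at which epoch training would halt.
#'
#' @param losses numeric vector of per-epoch losses.
#' @param min_delta minimum absolute improvement (default 0.003).
#' @param patience consecutive non-improving epochs tolerated (default 5).
#' @param max_epochs epoch cap (default 35).
#' @return the 1-based index of the last epoch that runs.
#' @export
early_stop_epoch <- function(losses, min_delta = 0.003, patience = 5L,
                             max_epochs = 35L) {
  best <- Inf; wait <- 0L
  n <- min(length(losses), max_epochs)
  for (e in seq_len(n)) {
    if (losses[e] < best - min_delta) {
      best <- losses[e]; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(e)
    }
  }
  n
}

#' Fit a per-channel sequence forecaster
#'
#' Trains a forecaster on the (unlabelled) training segment of one channel.
#' `method = "lstm"` trains the compact recurrent network with the regimen in
#' [forecast_config()]; `method = "ar"` fits a deterministic Yule-Walker
#' autoregressive baseline that satisfies the same forecasting contract and is
#' used where neural training would be wasteful (benchmarks, threshold tests);
#' `method = "naive"` predicts the last observed value (a contract stub).
#'
#' @param train a [channel_series()], typically filtered and scaled.
#' @param config a [forecast_config()].
#' @param method `"lstm"`, `"ar"` or `"naive"`.
#' @return an object of class `seeg_forecaster` with the training history,
#'   config, and provenance; see [predict.seeg_forecaster()].
#' @export
fit_forecaster <- function(train, config = forecast_config(),
                           method = c("lstm", "ar", "naive")) {
  method <- match.arg(method)
  if (!inherits(train, "channel_series")) stop_param("'train' must be a channel_series")
  x <- train$values
  l_b <- config$history_window; l_f <- config$horizon
  model <- switch(method,
    naive = list(),
    ar = {
      if (length(x) < max(config$ar_order * 2L, l_b + l_f)) {
        stop_param("training series too short for the AR baseline")
      }
      if (pop_sd(x) == 0) {               # constant training segment
        list(coef = numeric(0), mean = mean(x), order = 0L)
      } else {
        fit <- stats::ar(x, aic = FALSE, order.max = config$ar_order,
                         method = "yule-walker", demean = TRUE)
        list(coef = fit$ar, mean = fit$x.mean, order = fit$order)
      }
    },
    lstm = fit_lstm(x, config)
  )
  structure(list(
    method = method, params = model, config = config,
    training_history = attr(model, "history"),
    trained_on = list(patient_id = train$patient_id,
                      channel_id = train$channel_id, fs = train$fs),
    schema_version = 1L
  ), class = c(paste0(method, "_forecaster"), "seeg_forecaster"))
}

fit_lstm <- function(x, config) {
  l_b <- config$history_window; l_f <- config$horizon
  need <- l_b + l_f + 1L
  if (length(x) < need / (1 - config$validation_fraction)) {
    stop_param("training series too short for history window + validation split")
  }
  stride <- config$train_stride
  with_seed(config$seed, {
    w_all <- make_windows(x, l_b, l_f,
                          stride = stride %||% 1L)
    if (is.null(stride) && nrow(w_all$X) > config$max_windows) {
      stride <- max(1L, floor(nrow(w_all$X) / config$max_windows))
      w_all <- make_windows(x, l_b, l_f, stride = stride)
    }
    n_win <- nrow(w_all$X)
    n_val <- max(1L, floor(config$validation_fraction * n_win))
    if (n_win - n_val < 1L) stop_param("not enough training windows after validation split")
    tr_idx <- seq_len(n_win - n_val)             # chronological split
    va_idx <- (n_win - n_val + 1L):n_win
    Xtr <- w_all$X[tr_idx, , drop = FALSE]; Ytr <- w_all$Y[tr_idx, , drop = FALSE]
    Xva <- w_all$X[va_idx, , drop = FALSE]; Yva <- w_all$Y[va_idx, , drop = FALSE]

    par <- lstm_init(config$hidden_units, l_f)
    st <- adam_state(par)
    step <- 0L
    best <- Inf; wait <- 0L
    best_val <- Inf; best_par <- par
    lr <- config$learning_rate
    hist_train <- numeric(0); hist_val <- numeric(0)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(nrow(Xtr))
      ep_loss <- 0; nb <- 0L
      for (b0 in seq.int(1L, length(ord), by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        Xb <- Xtr[idx, , drop = FALSE]; Yb <- Ytr[idx, , drop = FALSE]
        mask <- NULL
        if (config$dropout > 0) {
          keep <- 1 - config$dropout
          mask <- matrix(stats::rbinom(length(idx) * config$hidden_units, 1L,
                                       keep) / keep,
                         length(idx), config$hidden_units)
        }
        fwd <- lstm_forward(par, Xb, keep_cache = TRUE, dropout_mask = mask)
        loss <- mean((fwd$pred - Yb)^2)
        if (!is.finite(loss)) {
          stop(errorCondition("training diverged: non-finite loss",
                              class = c("seegwatch_divergence_error", "error")))
        }
        grads <- lstm_backward(par, fwd, Xb, Yb, dropout_mask = mask)
        step <- step + 1L
        upd <- adam_step(par, grads, st, step, lr = lr)
        par <- upd$par; st <- upd$state
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      val_pred <- lstm_forward(par, Xva)$pred
      val_loss <- mean((val_pred - Yva)^2)
      hist_train <- c(hist_train, ep_loss / nb)
      hist_val <- c(hist_val, val_loss)
      if (val_loss < best_val) {           # weights restored from the best
        best_val <- val_loss               # validation epoch at the end
        best_par <- par
      }
      if (val_loss < best - config$early_stop_min_delta) {
        best <- val_loss; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) break
        lr <- lr * config$lr_plateau_decay   # anneal while on a plateau
      }
    }
    structure(best_par, history = data.frame(epoch = seq_along(hist_val),
                                             train_loss = hist_train,
                                             val_loss = hist_val))
  })
}

#' Rolling one-step forecasts on a test series
#'
#' For each position `t >= l_b` (0-based) the model predicts the next
#' `horizon` values from the preceding `l_b` observed values; the first
#' predicted value per step is retained (stride 1), so the output aligns
#' one-to-one with `test$values[(l_b+1):n]`.
#'
#' @param object a fitted `seeg_forecaster`.
#' @param series the test [channel_series()].
#' @param chunk_size windows processed per forward pass (memory control).
#' @param ... unused.
#' @return numeric vector of length `length(series) - l_b`.
#' @export
predict.seeg_forecaster <- function(object, series, chunk_size = 1024L, ...) {
  if (!inherits(series, "channel_series")) stop_param("'series' must be a channel_series")
  if (!identical(object$trained_on$patient_id, series$patient_id)) {
    message(sprintf("crossover forecast: model trained on '%s', applied to '%s'",
                    object$trained_on$patient_id, series$patient_id))
  }
  x <- series$values
  l_b <- object$config$history_window
  if (length(x) <= l_b) stop_param("test series no longer than the history window")
  n_pred <- length(x) - l_b
  if (object$method == "naive") {
    return(x[l_b:(length(x) - 1L)])
  }
  if (object$method == "ar") {
    p <- object$params$order
    phi <- object$params$coef; mu <- object$params$mean
    if (p == 0L) return(rep(mu, n_pred))
    if (l_b < p) stop_param("history window shorter than the AR order")
    xc <- x - mu
    acc <- rep(0, length(x))
    for (i in seq_len(p)) {
      acc[(i + 1L):length(x)] <- acc[(i + 1L):length(x)] +
        phi[i] * xc[1L:(length(x) - i)]
    }
    return(mu + acc[(l_b + 1L):length(x)])
  }
  # lstm: batch the rolling windows through the network in chunks
  preds <- numeric(n_pred)
  starts <- seq_len(n_pred)
  for (c0 in seq.int(1L, n_pred, by = chunk_size)) {
    idx <- c0:min(c0 + chunk_size - 1L, n_pred)
    Xb <- matrix(0, length(idx), l_b)
    for (k in seq_along(idx)) Xb[k, ] <- x[idx[k]:(idx[k] + l_b - 1L)]
    preds[idx] <- lstm_forward(object$params, Xb)$pred[, 1L]
  }
  preds
}

#' @export
print.seeg_forecaster <- function(x, ...) {
  cat(sprintf("<seeg_forecaster: %s> trained on %s/%s, l_b=%d, l_f=%d\n",
              x$method, x$trained_on$patient_id, x$trained_on$channel_id,
              x$config$history_window, x$config$horizon))
  if (!is.null(x$training_history)) {
    h <- x$training_history
    cat(sprintf("  %d epoch(s); final val MSE %.5g\n", nrow(h),
                h$val_loss[nrow(h)]))
  }
  invisible(x)
}

#' Forecast residuals on a series
#'
#' @param object a fitted `seeg_forecaster`.
#' @param series the test [channel_series()].
#' @param ... unused.
#' @return numeric vector of absolute one-step errors aligned with
#'   `series$values[(l_b+1):n]`.
#' @export
residuals.seeg_forecaster <- function(object, series, ...) {
  pred <- predict(object, series)
  actual <- series$values[(object$config$history_window + 1L):length(series$values)]
  abs(actual - pred)
}

#' Smoothed forecast-error series
#'
#' Absolute errors `e(t) = |actual(t) - predicted(t)|` smoothed with an
#' exponentially weighted moving average (`alpha = 2 / (span + 1)`,
#' initialised at the first error), the quantity the dynamic threshold
#' classifies.
#'
#' @param actual,predicted aligned numeric vectors of equal length.
#' @param span EWMA span (>= 1); `span = 1` disables smoothing. `NULL` picks
#'   `max(1, round(0.01 * length))`.
#' @return an object of class `smoothed_error_series` with fields `e_s`
#'   (smoothed), `raw`, and `span`.
#' @export
smoothed_error <- function(actual, predicted, span = NULL) {
  if (length(actual) != length(predicted)) {
    stop_param("actual and predicted must have equal length")
  }
  e <- abs(actual - predicted)
  if (is.null(span)) span <- max(1L, round(0.01 * length(e)))
  assert_scalar_number(span, "span", lower = 1)
  if (span == 1L || length(e) == 1L) {
    es <- e
  } else {
    alpha <- 2 / (span + 1)
    # recursion e_s[t] = alpha e[t] + (1-alpha) e_s[t-1], anchored e_s[1] = e[1]
    es <- as.numeric(stats::filter(alpha * e, 1 - alpha, method = "recursive",
                                   init = e[1]))
  }
  structure(list(e_s = as.numeric(es), raw = e, span = as.integer(span)),
            class = "smoothed_error_series")
}

#' @export
print.smoothed_error_series <- function(x, ...) {
  cat(sprintf("<smoothed_error_series> %d values, span %d, max %.5g\n",
              length(x$e_s), x$span, max(x$e_s)))
  invisible(x)
}

#' Mean absolute percentage error
#'
#' MAPE in percent over samples whose actual magnitude is at least
#' `denom_floor` (signals scaled to (-1, 1) cross zero, so near-zero
#' denominators are excluded rather than allowed to blow up the metric).
#'
#' @param actual,predicted aligned numeric vectors.
#' @param denom_floor exclusion threshold on `|actual|` (default 1e-3).
#' @return MAPE in percent.
#' @export
mape <- function(actual, predicted, denom_floor = 1e-3) {
  if (length(actual) != length(predicted)) {
    stop_param("actual and predicted must have equal length")
  }
  assert_scalar_number(denom_floor, "denom_floor", lower = .Machine$double.eps)
  keep <- abs(actual) >= denom_floor
  if (!any(keep)) {
    stop_data("MAPE undefined: every sample is below the denominator floor")
  }
  mean(abs(actual[keep] - predicted[keep]) / abs(actual[keep])) * 100
}

#' Save / load a fitted forecaster
#'
#' Single-file checkpoint with an embedded schema version; a loaded model
#' reproduces forecasts bit-identically.
#'
#' @param model a `seeg_forecaster`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "seeg_forecaster")) stop_param("'model' must be a seeg_forecaster")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  model <- tryCatch(readRDS(path), error = function(e) {
    stop_data("could not deserialize model file: ", conditionMessage(e))
  })
  if (!inherits(model, "seeg_forecaster")) {
    stop_data("file does not contain a seeg_forecaster checkpoint")
  }
  if (!identical(model$schema_version, 1L)) {
    stop_data("unsupported model schema version: ", model$schema_version)
  }
  model
}
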