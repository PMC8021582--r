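# Minimal batched LSTM with Adam, written against base BLAS. One recurrent
# layer over a scalar input stream, a dense head mapping the final hidden
# state to the forecast horizon, inverted dropout on the final hidden state.
# Gate column order throughout: [input, forget, cell, output].

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(hidden, horizon, input_dim = 1L) {
  r <- 1 / sqrt(hidden)
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -r, r), nr, nc)
  b <- numeric(4L * hidden)
  b[(hidden + 1L):(2L * hidden)] <- 1          # forget-gate bias at +1
  list(
    Wx = rmat(input_dim, 4L * hidden),
    Wh = rmat(hidden, 4L * hidden),
    b  = b,
    Wy = rmat(hidden, horizon),
    by = numeric(horizon),
    hidden = hidden, horizon = horizon
  )
}

# Forward pass over a batch of windows. X: (batch x T) matrix of scalar
# inputs. Returns predictions and (optionally) the caches needed for BPTT.
lstm_forward <- function(par, X, keep_cache = FALSE, dropout_mask = NULL) {
  H <- par$hidden
  n <- nrow(X); T_ <- ncol(X)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- if (keep_cache) vector("list", T_) else NULL
  idx_i <- seq_len(H); idx_f <- H + idx_i; idx_g <- 2L * H + idx_i
  idx_o <- 3L * H + idx_i
  for (t in seq_len(T_)) {
    z <- X[, t] %o% par$Wx[1L, ] + h %*% par$Wh
    z <- sweep(z, 2L, par$b, "+")
    i <- sigmoid(z[, idx_i, drop = FALSE])
    f <- sigmoid(z[, idx_f, drop = FALSE])
    g <- tanh(z[, idx_g, drop = FALSE])
    o <- sigmoid(z[, idx_o, drop = FALSE])
    c_prev <- cc
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    if (keep_cache) {
      cache[[t]] <- list(i = i, f = f, g = g, o = o, c = cc, c_prev = c_prev,
                         tc = tc, h_prev = h_prev, x = X[, t])
    }
  }
  h_out <- h
  if (!is.null(dropout_mask)) h_out <- h_out * dropout_mask
  pred <- sweep(h_out %*% par$Wy, 2L, par$by, "+")
  list(pred = pred, h = h, h_out = h_out, cache = cache)
}

# Backward pass for mean-squared-error loss over the batch. Returns gradients
# with the same shapes as the parameters.
lstm_backward <- function(par, fwd, X, Y, dropout_mask = NULL) {
  H <- par$hidden
  n <- nrow(X); T_ <- ncol(X)
  idx_i <- seq_len(H); idx_f <- H + idx_i; idx_g <- 2L * H + idx_i
  idx_o <- 3L * H + idx_i
  dpred <- 2 * (fwd$pred - Y) / length(Y)       # d(MSE)/d(pred)
  gWy <- crossprod(fwd$h_out, dpred)
  gby <- colSums(dpred)
  dh <- dpred %*% t(par$Wy)
  if (!is.null(dropout_mask)) dh <- dh * dropout_mask
  dc <- matrix(0, n, H)
  gWx <- matrix(0, 1L, 4L * H); gWh <- matrix(0, H, 4L * H)
  gb <- numeric(4L * H)
  for (t in rev(seq_len(T_))) {
    cc <- fwd$cache[[t]]
    do <- dh * cc$tc
    dct <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dct * cc$g
    dg <- dct * cc$i
    df <- dct * cc$c_prev
    dc <- dct * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    gWx <- gWx + cc$x %*% dZ
    gWh <- gWh + crossprod(cc$h_prev, dZ)
    gb <- gb + colSums(dZ)
    dh <- dZ %*% t(par$Wh)
  }
  list(Wx = gWx, Wh = gWh, b = gb, Wy = gWy, by = gby)
}

adam_state <- function(par) {
  lapply(par[c("Wx", "Wh", "b", "Wy", "by")], function(p) {
    list(m = p * 0, v = p * 0)
  })
}

adam_step <- function(par, grads, state, step, lr = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(state)) {
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * grads[[nm]]
    st$v <- beta2 * st$v + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m / (1 - beta1^step)
    vhat <- st$v / (1 - beta2^step)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(par = par, state = state)
}

# Sliding-window supervised pairs from a numeric vector: inputs are l_b
# consecutive samples, targets the following l_f samples.
make_windows <- function(x, l_b, l_f, stride = 1L) {
  n <- length(x)
  last_start <- n - l_b - l_f + 1L
  if (last_start < 1L) stop_param("series too short for the history window + horizon")
  starts <- seq.int(1L, last_start, by = stride)
  X <- matrix(0, length(starts), l_b)
  Y <- matrix(0, length(starts), l_f)
  for (k in seq_along(starts)) {
    s <- starts[k]
    X[k, ] <- x[s:(s + l_b - 1L)]
    Y[k, ] <- x[(s + l_b):(s + l_b + l_f - 1L)]
  }
  list(X = X, Y = Y, starts = starts)
}
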