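# Desk-scale convolutional-LSTM autoencoder for video regularity scoring.
#
# Architecture (layer counts fixed by design, sizes configurable): two strided
# convolutional encoder layers applied per frame, three stacked convolutional
# LSTM layers over time at the bottleneck resolution, and two transposed-
# convolution decoder layers reconstructing each frame. Implemented directly
# on base BLAS with im2col/col2im convolutions and hand-written
# backpropagation through time; gradients are validated against finite
# differences in the test suite.

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

# Unfold an (H, W, C) array into a (Hout*Wout) x (k*k*C) patch matrix.
im2col <- function(x, k, s, p) {
  xp <- pad_hw(x, p)
  d <- dim(xp); C <- d[3]
  Hout <- (d[1] - k) %/% s + 1L
  Wout <- (d[2] - k) %/% s + 1L
  si <- seq.int(1L, by = s, length.out = Hout)
  sj <- seq.int(1L, by = s, length.out = Wout)
  cols <- matrix(0, Hout * Wout, k * k * C)
  col <- 0L
  for (ch in seq_len(C)) for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    col <- col + 1L
    cols[, col] <- as.vector(xp[si + di, sj + dj, ch])
  }
  structure(cols, geom = list(Hout = Hout, Wout = Wout, Hp = d[1], Wp = d[2],
                              C = C, k = k, s = s, p = p))
}

# Scatter-add a patch matrix back to an (Hin, Win, C) array (adjoint of
# im2col for the given geometry).
col2im <- function(cols, geom, Hin, Win) {
  g <- geom
  xp <- array(0, c(g$Hp, g$Wp, g$C))
  si <- seq.int(1L, by = g$s, length.out = g$Hout)
  sj <- seq.int(1L, by = g$s, length.out = g$Wout)
  col <- 0L
  for (ch in seq_len(g$C)) for (dj in 0:(g$k - 1L)) for (di in 0:(g$k - 1L)) {
    col <- col + 1L
    xp[si + di, sj + dj, ch] <- xp[si + di, sj + dj, ch] +
      matrix(cols[, col], g$Hout, g$Wout)
  }
  if (g$p > 0L) {
    xp <- xp[g$p + seq_len(Hin), g$p + seq_len(Win), , drop = FALSE]
  }
  xp
}

conv_out_hw <- function(hw, k, s, p) (hw + 2L * p - k) %/% s + 1L

conv_forward <- function(x, W, b, k, s, p, act = c("tanh", "linear", "sigmoid")) {
  act <- match.arg(act)
  cols <- im2col(x, k, s, p)
  g <- attr(cols, "geom")
  pre <- sweep(cols %*% W, 2L, b, "+")
  out <- switch(act, tanh = tanh(pre), sigmoid = sigmoid(pre), linear = pre)
  list(out = array(out, c(g$Hout, g$Wout, ncol(W))), pre = pre, cols = cols,
       geom = g, act = act, in_hw = dim(x)[1:2])
}

conv_backward <- function(fw, W, d_out) {
  dmat <- matrix(d_out, nrow(fw$pre), ncol(fw$pre))
  dpre <- switch(fw$act,
                 tanh = dmat * (1 - tanh(fw$pre)^2),
                 sigmoid = { s <- sigmoid(fw$pre); dmat * s * (1 - s) },
                 linear = dmat)
  list(dW = crossprod(fw$cols, dpre),
       db = colSums(dpre),
       dx = col2im(dpre %*% t(W), fw$geom, fw$in_hw[1], fw$in_hw[2]))
}

# Transposed convolution: the adjoint of a conv with weight W mapping the
# *output* (big) space to the input (small) space, so upsampling is exactly
# col2im of z %*% t(W).
deconv_forward <- function(z, W, b, k, s, p, out_hw,
                           act = c("tanh", "linear", "sigmoid")) {
  act <- match.arg(act)
  d <- dim(z)
  C_big <- ncol(W) * 0L  # unused; W is (k*k*C_big) x C_small
  zmat <- matrix(z, d[1] * d[2], d[3])
  geom <- list(Hout = d[1], Wout = d[2], Hp = out_hw[1] + 2L * p,
               Wp = out_hw[2] + 2L * p, C = nrow(W) %/% (k * k), k = k, s = s,
               p = p)
  pre <- col2im(zmat %*% t(W), geom, out_hw[1], out_hw[2])
  pre <- sweep(pre, 3L, b, "+")
  out <- switch(act, tanh = tanh(pre), sigmoid = sigmoid(pre), linear = pre)
  list(out = out, pre = pre, zmat = zmat, geom = geom, act = act,
       out_hw = out_hw, z_dim = d)
}

deconv_backward <- function(fw, W, d_out) {
  dpre <- switch(fw$act,
                 tanh = d_out * (1 - tanh(fw$pre)^2),
                 sigmoid = { s <- sigmoid(fw$pre); d_out * s * (1 - s) },
                 linear = d_out)
  dcols <- im2col(dpre, fw$geom$k, fw$geom$s, fw$geom$p)
  list(dW = crossprod(dcols, fw$zmat),
       db = apply(dpre, 3L, sum),
       dz = array(dcols %*% W, fw$z_dim))
}

#' Video autoencoder configuration
#'
#' Fixed layer counts (2 conv, 3 conv-LSTM, 2 deconv) with desk-scale sizes:
#' the defaults train in minutes on one CPU at 64x64 input while preserving
#' the architecture's structure.
#'
#' @param input_size `c(height, width)` frames are resized to (default 64x64;
#'   must be divisible by 4).
#' @param temporal_depth frames per input volume (default 10).
#' @param conv_filters channel counts of the two encoder convolutions
#'   (default `c(8, 12)`; the three conv-LSTM layers run at the second count).
#' @param epochs training epochs (default 30).
#' @param learning_rate Adam learning rate (default 0.05; volumes are few
#'   at desk scale, so steps are large).
#' @param error_convention `"squared"` (default) or `"absolute"` per-pixel
#'   reconstruction error when summing frame errors.
#' @param seed RNG seed.
#' @return a list of class `autoencoder_config`.
#' @export
autoencoder_config <- function(input_size = c(64L, 64L), temporal_depth = 10L,
                               conv_filters = c(8L, 12L), epochs = 30L,
                               learning_rate = 0.05,
                               error_convention = c("squared", "absolute"),
                               seed = 1L) {
  error_convention <- match.arg(error_convention)
  if (any(input_size %% 4L != 0L)) stop_param("input_size must be divisible by 4")
  assert_scalar_number(temporal_depth, "temporal_depth", lower = 1)
  structure(list(
    input_size = as.integer(input_size), temporal_depth = as.integer(temporal_depth),
    conv_layers = 2L, convlstm_layers = 3L, deconv_layers = 2L,
    conv_filters = as.integer(conv_filters), epochs = as.integer(epochs),
    learning_rate = learning_rate, error_convention = error_convention,
    seed = as.integer(seed)
  ), class = "autoencoder_config")
}

convae_init <- function(cfg) {
  F1 <- cfg$conv_filters[1]; F2 <- cfg$conv_filters[2]
  rmat <- function(nr, nc, fan_in) {
    matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
  }
  par <- list(
    c1_W = rmat(5 * 5 * 1, F1, 25), c1_b = numeric(F1),
    c2_W = rmat(3 * 3 * F1, F2, 9 * F1), c2_b = numeric(F2)
  )
  for (l in 1:3) {
    par[[paste0("l", l, "_Wx")]] <- rmat(3 * 3 * F2, 4 * F2, 9 * F2)
    par[[paste0("l", l, "_Wh")]] <- rmat(3 * 3 * F2, 4 * F2, 9 * F2)
    b <- numeric(4 * F2); b[F2 + seq_len(F2)] <- 1
    par[[paste0("l", l, "_b")]] <- b
  }
  # decoder weights are conv weights for the adjoint direction:
  # d1: bottleneck (F2) -> mid (F1) at 2x; W shape (k*k*C_big) x C_small
  par$d1_W <- rmat(4 * 4 * F1, F2, 16 * F2); par$d1_b <- numeric(F1)
  par$d2_W <- rmat(4 * 4 * 1, F1, 16 * F1); par$d2_b <- 0
  par
}

convlstm_step <- function(Wx, Wh, b, x, h_prev_arr, c_prev, Fh) {
  cx <- im2col(x, 3L, 1L, 1L)
  chh <- im2col(h_prev_arr, 3L, 1L, 1L)
  Z <- sweep(cx %*% Wx + chh %*% Wh, 2L, b, "+")
  np <- nrow(Z)
  i <- sigmoid(Z[, seq_len(Fh), drop = FALSE])
  f <- sigmoid(Z[, Fh + seq_len(Fh), drop = FALSE])
  g <- tanh(Z[, 2L * Fh + seq_len(Fh), drop = FALSE])
  o <- sigmoid(Z[, 3L * Fh + seq_len(Fh), drop = FALSE])
  cc <- f * c_prev + i * g
  tc <- tanh(cc)
  h <- o * tc
  list(h = h, c = cc, i = i, f = f, g = g, o = o, tc = tc,
       cx = cx, chh = chh, c_prev = c_prev)
}

# Full forward pass over one volume (H, W, T). Returns reconstructions and
# all caches needed for backprop.
convae_forward <- function(par, vol, cfg, keep_cache = FALSE) {
  hw <- dim(vol)[1:2]; T_ <- dim(vol)[3]
  F1 <- cfg$conv_filters[1]; F2 <- cfg$conv_filters[2]
  hw1 <- conv_out_hw(hw, 5L, 2L, 2L)
  hw2 <- conv_out_hw(hw1, 3L, 2L, 1L)
  np <- hw2[1] * hw2[2]
  h <- lapply(1:3, function(l) matrix(0, np, F2))
  cs <- lapply(1:3, function(l) matrix(0, np, F2))
  recon <- array(0, dim(vol))
  cache <- if (keep_cache) list(enc = vector("list", T_),
                                lstm = vector("list", T_),
                                dec = vector("list", T_)) else NULL
  for (t in seq_len(T_)) {
    x <- array(vol[, , t], c(hw, 1L))
    e1 <- conv_forward(x, par$c1_W, par$c1_b, 5L, 2L, 2L, act = "tanh")
    e2 <- conv_forward(e1$out, par$c2_W, par$c2_b, 3L, 2L, 1L, act = "tanh")
    steps <- vector("list", 3L)
    inp <- e2$out
    for (l in 1:3) {
      st <- convlstm_step(par[[paste0("l", l, "_Wx")]],
                          par[[paste0("l", l, "_Wh")]],
                          par[[paste0("l", l, "_b")]],
                          inp, array(h[[l]], c(hw2, F2)), cs[[l]], F2)
      h[[l]] <- st$h; cs[[l]] <- st$c
      steps[[l]] <- st
      inp <- array(st$h, c(hw2, F2))
    }
    d1 <- deconv_forward(array(h[[3]], c(hw2, F2)), par$d1_W, par$d1_b,
                         4L, 2L, 1L, hw1, act = "tanh")
    d2 <- deconv_forward(d1$out, par$d2_W, par$d2_b, 4L, 2L, 1L, hw,
                         act = "sigmoid")
    recon[, , t] <- d2$out[, , 1L]
    if (keep_cache) {
      cache$enc[[t]] <- list(e1 = e1, e2 = e2)
      cache$lstm[[t]] <- steps
      cache$dec[[t]] <- list(d1 = d1, d2 = d2)
    }
  }
  list(recon = recon, cache = cache, hw1 = hw1, hw2 = hw2)
}

convae_backward <- function(par, fwd, vol, cfg) {
  hw <- dim(vol)[1:2]; T_ <- dim(vol)[3]
  F1 <- cfg$conv_filters[1]; F2 <- cfg$conv_filters[2]
  hw2 <- fwd$hw2; np <- hw2[1] * hw2[2]
  grads <- lapply(par, function(p) p * 0)
  dh_next <- lapply(1:3, function(l) matrix(0, np, F2))
  dc_next <- lapply(1:3, function(l) matrix(0, np, F2))
  for (t in rev(seq_len(T_))) {
    drec <- array(0, c(hw, 1L))
    drec[, , 1L] <- 2 * (fwd$recon[, , t] - vol[, , t]) / length(vol)
    dec <- fwd$cache$dec[[t]]
    b2 <- deconv_backward(dec$d2, par$d2_W, drec)
    grads$d2_W <- grads$d2_W + b2$dW; grads$d2_b <- grads$d2_b + b2$db
    b1 <- deconv_backward(dec$d1, par$d1_W, b2$dz)
    grads$d1_W <- grads$d1_W + b1$dW; grads$d1_b <- grads$d1_b + b1$db
    d_inp <- matrix(b1$dz, np, F2)      # grad wrt top conv-LSTM h_t
    for (l in 3:1) {
      st <- fwd$cache$lstm[[t]][[l]]
      dh <- d_inp + dh_next[[l]]
      do <- dh * st$tc
      dct <- dc_next[[l]] + dh * st$o * (1 - st$tc^2)
      di <- dct * st$g; dg <- dct * st$i; df <- dct * st$c_prev
      dc_next[[l]] <- dct * st$f
      dZ <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  dg * (1 - st$g^2),
                  do * st$o * (1 - st$o))
      nWx <- paste0("l", l, "_Wx"); nWh <- paste0("l", l, "_Wh")
      nb <- paste0("l", l, "_b")
      grads[[nWx]] <- grads[[nWx]] + crossprod(st$cx, dZ)
      grads[[nWh]] <- grads[[nWh]] + crossprod(st$chh, dZ)
      grads[[nb]] <- grads[[nb]] + colSums(dZ)
      gx <- attr(st$cx, "geom")
      dx_arr <- col2im(dZ %*% t(par[[nWx]]), gx, hw2[1], hw2[2])
      dh_prev_arr <- col2im(dZ %*% t(par[[nWh]]), attr(st$chh, "geom"),
                            hw2[1], hw2[2])
      dh_next[[l]] <- matrix(dh_prev_arr, np, F2)
      d_inp <- matrix(dx_arr, np, F2)   # to layer below (or encoder at l=1)
    }
    enc <- fwd$cache$enc[[t]]
    be2 <- conv_backward(enc$e2, par$c2_W, array(d_inp, c(hw2, F2)))
    grads$c2_W <- grads$c2_W + be2$dW; grads$c2_b <- grads$c2_b + be2$db
    be1 <- conv_backward(enc$e1, par$c1_W, be2$dx)
    grads$c1_W <- grads$c1_W + be1$dW; grads$c1_b <- grads$c1_b + be1$db
  }
  grads
}

#' Train the video autoencoder
#'
#' Trains the 2-conv / 3-conv-LSTM / 2-deconv autoencoder to reconstruct
#' consecutive volumes of `temporal_depth` frames under mean-squared-error
#' loss with Adam. Fully deterministic for a fixed seed (single-threaded).
#'
#' @param frames a [frame_sequence()] whose shape matches
#'   `config$input_size` (resize at load time otherwise).
#' @param config an [autoencoder_config()].
#' @return an object of class `conv_lstm_autoencoder` with the learned
#'   parameters and per-epoch loss history.
#' @export
train_autoencoder <- function(frames, config = autoencoder_config()) {
  if (!inherits(frames, "frame_sequence")) stop_param("'frames' must be a frame_sequence")
  d <- dim(frames$frames)
  if (!all(d[1:2] == config$input_size)) {
    stop_param("frame shape does not match config$input_size")
  }
  T_all <- d[3]; depth <- config$temporal_depth
  if (T_all < depth) stop_param("need at least temporal_depth frames")
  vol_starts <- seq.int(1L, T_all - depth + 1L, by = depth)
  with_seed(config$seed, {
    par <- convae_init(config)
    st <- lapply(par, function(p) list(m = p * 0, v = p * 0))
    step <- 0L
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ep_loss <- 0
      for (s in vol_starts) {
        vol <- frames$frames[, , s:(s + depth - 1L), drop = FALSE]
        fwd <- convae_forward(par, vol, config, keep_cache = TRUE)
        loss <- mean((fwd$recon - vol)^2)
        if (!is.finite(loss)) {
          stop(errorCondition("autoencoder training diverged",
                              class = c("seegwatch_divergence_error", "error")))
        }
        grads <- convae_backward(par, fwd, vol, config)
        step <- step + 1L
        upd <- adam_step(par, grads, st, step, lr = config$learning_rate)
        par <- upd$par; st <- upd$state
        ep_loss <- ep_loss + loss
      }
      history[epoch] <- ep_loss / length(vol_starts)
    }
    structure(list(params = par, config = config,
                   training_history = history, schema_version = 1L),
              class = "conv_lstm_autoencoder")
  })
}

#' @export
print.conv_lstm_autoencoder <- function(x, ...) {
  h <- x$training_history
  cat(sprintf(
    "<conv_lstm_autoencoder> %dx%d input, depth %d; %d epoch(s), loss %.5g -> %.5g\n",
    x$config$input_size[1], x$config$input_size[2], x$config$temporal_depth,
    length(h), h[1], h[length(h)]))
  invisible(x)
}

#' Reconstruct frames with a trained autoencoder
#'
#' Processes the sequence in consecutive volumes of `temporal_depth` frames;
#' a trailing partial volume is handled by anchoring the final volume at the
#' end of the sequence (overlapped frames take the later reconstruction).
#'
#' @param model a trained [train_autoencoder()] result.
#' @param frames a [frame_sequence()].
#' @return an array of reconstructed frames, same shape as the input.
#' @export
reconstruct_frames <- function(model, frames) {
  d <- dim(frames$frames); depth <- model$config$temporal_depth
  if (d[3] < depth) stop_param("need at least temporal_depth frames")
  starts <- seq.int(1L, d[3] - depth + 1L, by = depth)
  if (starts[length(starts)] + depth - 1L < d[3]) starts <- c(starts, d[3] - depth + 1L)
  recon <- array(0, d)
  for (s in starts) {
    idx <- s:(s + depth - 1L)
    recon[, , idx] <- convae_forward(model$params,
                                     frames$frames[, , idx, drop = FALSE],
                                     model$config)$recon
  }
  recon
}
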