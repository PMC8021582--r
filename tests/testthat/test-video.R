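test_that("frames round-trip through PGM and load in lexicographic order", {
  set.seed(1)
  dir <- withr::local_tempdir()
  frames <- lapply(1:20, function(i) matrix(runif(64 * 64), 64, 64))
  for (i in seq_along(frames)) {
    write_pgm(frames[[i]], file.path(dir, sprintf("frame_%03d.pgm", i)))
  }
  fs <- load_frames(dir, fps = 30)
  expect_equal(length(fs), 20L)
  expect_equal(fs$frame_shape, c(64L, 64L))
  expect_lt(max(abs(fs$frames[, , 7] - frames[[7]])), 1 / 255)
  # stride halves the count (and the effective rate)
  fs2 <- load_frames(dir, stride = 2, fps = 30)
  expect_equal(length(fs2), 10L)
  expect_equal(fs2$fps, 15)
  # resize
  fs3 <- load_frames(dir, target_size = c(16, 16))
  expect_equal(fs3$frame_shape, c(16L, 16L))
  # all-black frames stay zero
  dir2 <- withr::local_tempdir()
  write_pgm(matrix(0, 8, 8), file.path(dir2, "z.pgm"))
  expect_equal(max(load_frames(dir2)$frames), 0)
})

test_that("unreadable frames error in strict mode and skip with a warning otherwise", {
  dir <- withr::local_tempdir()
  write_pgm(matrix(0.5, 8, 8), file.path(dir, "a.pgm"))
  writeLines("garbage", file.path(dir, "b.pgm"))
  expect_error(load_frames(dir), class = "seegwatch_data_error")
  expect_warning(fs <- load_frames(dir, strict = FALSE), "skipping")
  expect_equal(length(fs), 1L)
  expect_error(load_frames("/no/such/dir"), class = "seegwatch_data_error")
})

test_that("autoencoder gradients match finite differences on a tiny model", {
  set.seed(7)
  cfg <- autoencoder_config(input_size = c(8, 8), temporal_depth = 3,
                            conv_filters = c(2, 3), epochs = 1)
  par <- seegwatch:::convae_init(cfg)
  vol <- array(runif(8 * 8 * 3), c(8, 8, 3))
  fwd <- seegwatch:::convae_forward(par, vol, cfg, keep_cache = TRUE)
  expect_identical(dim(fwd$recon), dim(vol))
  gr <- seegwatch:::convae_backward(par, fwd, vol, cfg)
  eps <- 1e-5
  for (nm in names(par)) {
    idx <- sample(length(par[[nm]]), min(3L, length(par[[nm]])))
    for (i in idx) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (mean((seegwatch:::convae_forward(pp, vol, cfg)$recon - vol)^2) -
               mean((seegwatch:::convae_forward(pm, vol, cfg)$recon - vol)^2)) /
        (2 * eps)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-3)
    }
  }
})

test_that("autoencoder learns a static scene and is seeded-deterministic", {
  set.seed(5)
  base <- matrix(runif(16 * 16), 16, 16)
  frames <- frame_sequence(array(rep(base, 20), c(16, 16, 20)), fps = 30)
  cfg <- autoencoder_config(input_size = c(16, 16), temporal_depth = 5,
                            conv_filters = c(4, 6), epochs = 30, seed = 2)
  m <- train_autoencoder(frames, cfg)
  par0 <- seegwatch:::with_seed(2, seegwatch:::convae_init(cfg))
  vol <- frames$frames[, , 1:5]
  init_per_frame <- sum((seegwatch:::convae_forward(par0, vol, cfg)$recon -
                           vol)^2) / 5
  final_err <- mean(frame_errors(m, frames))
  expect_lt(final_err, 0.10 * init_per_frame)    # < 10% of untrained error
  m2 <- train_autoencoder(frames, cfg)
  expect_identical(m$training_history, m2$training_history)
  expect_error(train_autoencoder(
    frame_sequence(array(0.5, c(16, 16, 3)), 30),
    autoencoder_config(input_size = c(16, 16), temporal_depth = 5)),
    class = "seegwatch_parameter_error")
})

test_that("frame errors follow the configured pixel-error convention", {
  frames <- frame_sequence(array(0.5, c(4, 4, 3)), fps = 30)
  identity_stub <- function(x) x
  expect_equal(frame_errors(identity_stub, frames), rep(0, 3))
  zero_stub <- function(x) x * 0
  # N = 16 pixels at intensity 0.5: squared -> 0.25 N; absolute -> 0.5 N
  expect_equal(frame_errors(zero_stub, frames, convention = "squared"),
               rep(0.25 * 16, 3))
  expect_equal(frame_errors(zero_stub, frames, convention = "absolute"),
               rep(0.5 * 16, 3))
  # doubling pixel errors doubles e_t under the absolute convention
  half_stub <- function(x) x * 0.5
  e1 <- frame_errors(half_stub, frames, convention = "absolute")
  e2 <- frame_errors(zero_stub, frames, convention = "absolute")
  expect_equal(e2, 2 * e1)
})

test_that("regularity score matches hand-evaluated formulas and invariances", {
  r <- regularity_score(c(0, 10))
  expect_equal(r$a_t, c(0, 1))
  expect_equal(r$s_t, c(1, 0))
  expect_equal(regularity_score(c(5, 5, 5))$s_t, c(1, 1, 1))
  r3 <- regularity_score(c(2, 4, 10))
  expect_equal(r3$a_t, c(0, 0.2, 0.8))
  expect_equal(r3$s_t, c(1, 0.8, 0.2))
  expect_equal(regularity_score(rep(0, 4))$s_t, rep(1, 4))

  set.seed(8)
  e <- abs(rnorm(200))
  base <- regularity_score(e)
  for (c_ in c(0.1, 3, 100)) {          # invariant to positive rescaling
    expect_equal(regularity_score(c_ * e)$a_t, base$a_t)
  }
  expect_true(all(base$s_t >= 0 & base$s_t <= 1))
  expect_equal(min(base$a_t), 0)
  expect_equal(max(base$s_t), 1)
  expect_error(regularity_score(c(-1, 2)), class = "seegwatch_data_error")
})

test_that("regularity series round-trips through CSV", {
  r <- regularity_score(c(2, 4, 10), fps = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_regularity(r, path)
  back <- read_regularity(path, fps = 30)
  expect_equal(back$s_t, r$s_t)
  expect_equal(back$e_t, r$e_t)
})

test_that("video path flags a deep regularity drop; a shallow dip depends on pruning", {
  gen <- gen_regularity_trace(300, fps = 30, seed = 42, n_events = 1,
                              event_depth = 0.8,
                              nuisance = nuisance_spec(n_dips = 1,
                                                       dip_depth = 0.3))
  det <- detect_video_anomalies(gen$trace, fconfig = forecast_config(seed = 1))
  counts <- match_events(det$intervals, gen$labels)
  expect_equal(counts$detected_events, 1L)       # the deep drop is found
  # constant trace -> nothing
  flat <- detect_video_anomalies(rep(1, 9000), fps = 30,
                                 fconfig = forecast_config(seed = 1))
  expect_equal(nrow(flat$intervals), 0L)
  # identical interval schema as the SEEG path
  expect_identical(sort(names(det$intervals)),
                   sort(c("start", "end", "peak_error", "modality",
                          "channel_id")))
  expect_true(all(det$intervals$modality == "video"))
})
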