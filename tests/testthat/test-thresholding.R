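test_that("threshold objective matches the hand-computed window example", {
  w <- c(1, 1, 1, 1, 10)
  # population stats: mu = 2.8, sigma = 3.6
  r2 <- threshold_objective(w, z = 2, penalized = FALSE)
  expect_equal(r2$epsilon, 10.0)
  expect_equal(r2$objective, 0)          # nothing strictly above epsilon
  r1 <- threshold_objective(w, z = 1, penalized = FALSE)
  expect_equal(r1$epsilon, 6.4)
  expect_equal(r1$delta_mu, 1.8)
  expect_equal(r1$delta_sigma, 3.6)
  expect_equal(r1$objective, 1.8 / 2.8 + 3.6 / 3.6)
  r1p <- threshold_objective(w, z = 1, penalized = TRUE)
  expect_equal(r1p$objective, (1.8 / 2.8 + 1) / (1 + 1^2))
  expect_equal(r1p$n_anom_points, 1L)
  expect_equal(r1p$n_anom_seqs, 1L)
})

test_that("threshold objective handles degenerate windows", {
  r <- threshold_objective(rep(2, 10), z = 3)
  expect_true(r$degenerate)
  expect_equal(r$objective, 0)
  # epsilon above the max: empty exceedance branch
  r2 <- threshold_objective(c(1, 2, 3), z = 50)
  expect_equal(r2$objective, 0)
  expect_error(threshold_objective(1, z = 2),
               class = "seegwatch_parameter_error")
})

test_that("removing exceedances never raises the window mean (z >= 0)", {
  set.seed(21)
  for (i in 1:50) {
    w <- abs(rnorm(100, sd = runif(1, 0.1, 5)))
    z <- runif(1, 0, 6)
    r <- threshold_objective(w, z)
    expect_gte(r$delta_mu, 0)
  }
})

test_that("find_dynamic_threshold equals exhaustive search and breaks ties to larger z", {
  set.seed(9)
  cfg <- dynamic_config(window_size = 10, z_grid = seq(2, 10, by = 0.5))
  for (i in 1:25) {
    w <- abs(rnorm(sample(10:200, 1), sd = runif(1, 0.1, 3)))
    if (i %% 3 == 0) w[sample(length(w), 2)] <- w[sample(length(w), 2)] + 20
    dec <- find_dynamic_threshold(w, cfg)
    oracle <- brute_threshold(w, cfg$z_grid, cfg$penalized)
    expect_identical(dec$z, oracle$z)
    expect_equal(dec$objective, oracle$obj)
  }
  # all-equal objective (no exceedance anywhere): largest z wins
  dec <- find_dynamic_threshold(c(1, 1.01, 1.02, 0.99, 1), dynamic_config(window_size = 10))
  expect_equal(dec$z, 10)
})

test_that("a lone spike is isolated by the chosen threshold across seeds", {
  cfg <- dynamic_config(window_size = 10, z_grid = seq(2, 10, by = 1))
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    w <- abs(rnorm(150))
    w[75] <- 50
    dec <- find_dynamic_threshold(w, cfg)
    if (dec$epsilon < 50 && dec$n_anom_points == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("detect_anomalous_sequences recovers a constructed anomaly and obeys the schema", {
  e <- rep(0.01, 1000); e[101:110] <- 5
  cfg <- dynamic_config(window_size = 64, step = 32)
  iv <- detect_anomalous_sequences(e, cfg)
  expect_equal(nrow(iv), 1L)
  expect_lte(iv$start, 100)
  expect_gte(iv$end, 110)
  expect_equal(iv$peak_error, 5)

  expect_equal(nrow(detect_anomalous_sequences(rep(3, 500), cfg)), 0L)
  expect_error(detect_anomalous_sequences(1:10, cfg),
               class = "seegwatch_parameter_error")

  set.seed(4)
  e2 <- abs(rnorm(2000)); e2[c(300:320, 900:905)] <- e2[c(300:320, 900:905)] + 30
  iv2 <- detect_anomalous_sequences(e2, cfg)
  expect_true(all(iv2$start < iv2$end))
  expect_true(all(iv2$start >= 0 & iv2$end <= 2000))
  expect_true(all(diff(iv2$start) > 0))
  expect_true(all(iv2$end[-nrow(iv2)] <= iv2$start[-1]))   # non-overlapping
})

test_that("pruning reproduces the hand-stepped rule and its limit cases", {
  # peaks 100 / 40 / 38 over a floor with outside max 37:
  # d = (0.60, 0.05, 0.026) -> only the peak-100 interval survives at p = 0.10
  e <- rep(1, 100)
  e[11:15] <- c(2, 100, 3, 2, 1.5)
  e[41:45] <- c(2, 40, 3, 2, 1.5)
  e[71:75] <- c(2, 38, 3, 2, 1.5)
  e[90] <- 37
  iv <- anomaly_intervals(c(10, 40, 70), c(15, 45, 75),
                          peak_error = c(100, 40, 38))
  kept <- prune_anomalies(iv, e, p = 0.10)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$peak_error, 100)

  # p = 0 with strictly decreasing peaks keeps everything
  expect_equal(nrow(prune_anomalies(iv, e, p = 0)), 3L)
  # empty in, empty out
  expect_equal(nrow(prune_anomalies(anomaly_intervals(), e, 0.1)), 0L)
  # nothing separated from the floor: everything reclassified
  flat <- anomaly_intervals(c(10, 40), c(15, 45), peak_error = c(1.05, 1.02))
  expect_equal(nrow(prune_anomalies(flat, rep(1, 100), p = 0.10)), 0L)
})

test_that("pruning output is a subset and monotone in p", {
  set.seed(31)
  for (i in 1:20) {
    rs <- random_interval_set()
    p_small <- prune_anomalies(rs$iv, rs$e, p = 0.05)
    p_big <- prune_anomalies(rs$iv, rs$e, p = 0.3)
    expect_true(all(p_small$start %in% rs$iv$start))
    expect_true(all(p_big$start %in% p_small$start))   # larger p keeps fewer
  }
})

test_that("static threshold matches its arithmetic oracles", {
  # n = 4: mu 25, population sigma 43.30 -> threshold 111.6, nothing flagged
  expect_equal(nrow(static_threshold_detect(c(0, 0, 0, 100))), 0L)
  # n = 10: mu 10, sigma 30, threshold 70 -> exactly [9, 10)
  iv <- static_threshold_detect(c(rep(0, 9), 100))
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, 9)
  expect_equal(iv$end, 10)
  expect_equal(iv$peak_error, 100)
  # constant series: no spread, no anomalies
  expect_equal(nrow(static_threshold_detect(rep(5, 100))), 0L)
})

test_that("static 2-sigma threshold flags the Gaussian one-sided tail fraction", {
  set.seed(12)
  e <- rnorm(1e5)
  iv <- static_threshold_detect(e)
  flagged <- sum(iv$end - iv$start)
  expect_equal(flagged / 1e5, pnorm(2, lower.tail = FALSE),
               tolerance = 0.15)   # Monte-Carlo tolerance
})
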