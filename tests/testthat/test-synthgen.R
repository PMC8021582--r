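test_that("channel generation is a pure function of spec and seed", {
  g1 <- gen_seeg_channel(background_spec(duration_s = 60),
                         seizure_spec(n_events = 1), seed = 42)
  g2 <- gen_seeg_channel(background_spec(duration_s = 60),
                         seizure_spec(n_events = 1), seed = 42)
  expect_identical(g1$series$values, g2$series$values)
  expect_identical(as.data.frame(g1$labels), as.data.frame(g2$labels))
  g3 <- gen_seeg_channel(background_spec(duration_s = 60),
                         seizure_spec(n_events = 1), seed = 43)
  expect_false(identical(g1$series$values, g3$series$values))
})

test_that("no events means empty labels and a drift-stationary background", {
  g <- gen_seeg_channel(background_spec(duration_s = 120),
                        seizure_spec(n_events = 0), seed = 1)
  expect_equal(nrow(g$labels), 0L)
  expect_equal(length(g$series$values), 120 * 256)
  expect_true(all(is.finite(g$series$values)))
})

test_that("event intervals carry the amplitude they claim, strictly inside their support", {
  bg <- background_spec(duration_s = 300, artifact_rate_per_min = 0)
  g <- gen_seeg_channel(bg, seizure_spec(n_events = 2, amplitude_gain = 5),
                        seed = 9)
  expect_equal(nrow(g$labels), 2L)
  x <- g$series$values
  rms <- function(v) sqrt(mean(v^2))
  for (i in 1:2) {
    ev <- x[(g$labels$start[i] + 1):g$labels$end[i]]
    flank_idx <- setdiff(seq_along(x),
                         unlist(lapply(1:2, function(j)
                           (g$labels$start[j] + 1):g$labels$end[j])))
    expect_gte(rms(ev), 3 * rms(x[flank_idx]))
  }
  # event effect confined to [start, end): regenerating without events under
  # the same seed leaves every outside sample untouched
  g0 <- gen_seeg_channel(bg, seizure_spec(n_events = 2, amplitude_gain = 5),
                         seed = 9, events = event_labels(fs = 256,
                                                         source = "synthetic-truth"))
  inside <- unlist(lapply(1:2, function(j)
    (g$labels$start[j] + 1):g$labels$end[j]))
  expect_equal(x[-inside], g0$series$values[-inside])
})

test_that("regularity traces put events below nuisance dips and stay in [0, 1]", {
  g <- gen_regularity_trace(300, fps = 30, seed = 4, n_events = 1,
                            event_depth = 0.8,
                            nuisance = nuisance_spec(n_dips = 1,
                                                     dip_depth = 0.3))
  s <- g$trace$s_t
  expect_true(all(s >= 0 & s <= 1))
  ev <- (g$labels$start[1] + 1):g$labels$end[1]
  expect_lt(min(s[ev]), 0.35)                     # deep true-event drop
  outside_min <- min(s[-ev])
  expect_gt(outside_min, min(s[ev]))              # nuisance dips are shallower
  g2 <- gen_regularity_trace(300, fps = 30, seed = 4, n_events = 1,
                             event_depth = 0.8,
                             nuisance = nuisance_spec(n_dips = 1,
                                                      dip_depth = 0.3))
  expect_identical(g$trace$s_t, g2$trace$s_t)
  # null case: quiet trace near 1
  g0 <- gen_regularity_trace(60, fps = 30, seed = 2, n_events = 0,
                             nuisance = nuisance_spec(n_dips = 0))
  expect_gt(min(g0$trace$s_t), 0.8)
})

test_that("families are spectrally separated beyond their within-family spread", {
  centroid <- function(series) {
    sp <- stats::spec.pgram(series$values, plot = FALSE, taper = 0,
                            detrend = TRUE)
    f <- sp$freq * series$fs
    keep <- f >= 1 & f <= 40
    sum(f[keep] * sp$spec[keep]) / sum(sp$spec[keep])
  }
  famA <- gen_patient_family(family_spec("A"), 2, seed = 7, n_channels = 1,
                             duration_s = 120,
                             seizures = seizure_spec(n_events = 0))
  famB <- gen_patient_family(family_spec("B"), 2, seed = 8, n_channels = 1,
                             duration_s = 120,
                             seizures = seizure_spec(n_events = 0))
  cA <- vapply(famA, function(p) centroid(p$channels[[1]]), numeric(1))
  cB <- vapply(famB, function(p) centroid(p$channels[[1]]), numeric(1))
  gap <- abs(mean(cA) - mean(cB))
  expect_gt(gap, 0.5)                              # across-family margin (Hz)
  expect_lt(max(diff(range(cA)), diff(range(cB))), gap)
  expect_length(gen_patient_family(family_spec("A"), 1, seed = 1,
                                   duration_s = 60,
                                   seizures = seizure_spec(n_events = 0)), 1L)
})

test_that("the emu-default benchmark generates within its time budget", {
  t0 <- proc.time()
  pats <- c(gen_patient_family(family_spec("A"), 2, seed = 1),
            gen_patient_family(family_spec("B"), 2, seed = 2))
  elapsed <- (proc.time() - t0)[["elapsed"]]
  expect_length(pats, 4L)
  expect_true(all(vapply(pats, function(p) length(p$channels), 0L) == 2L))
  expect_true(all(vapply(pats, function(p) nrow(p$labels) >= 1, TRUE)))
  expect_lt(elapsed, 30)
})
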