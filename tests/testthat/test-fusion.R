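test_that("channel pooling is a union-merge that keeps disjoint intervals", {
  a <- anomaly_intervals(0, 10, 1, "seeg", "chA")
  b <- anomaly_intervals(5, 20, 2, "seeg", "chB")
  pooled <- pool_channels(list(a, b))
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$start, 0)
  expect_equal(pooled$end, 20)
  expect_equal(pooled$peak_error, 2)

  far <- anomaly_intervals(200, 210, 1, "seeg", "chB")
  both <- pool_channels(list(a, far))
  expect_equal(nrow(both), 2L)
  expect_equal(nrow(pool_channels(list(anomaly_intervals(),
                                       anomaly_intervals()))), 0L)
})

test_that("multimodal pooling converts time bases, keeps provenance, and is a superset", {
  seeg <- anomaly_intervals(100, 200, 1, "seeg", "ch1")
  video <- anomaly_intervals(150 / 256 * 30, 300 / 256 * 30, 2, "video", "cam")
  pooled <- pool_multimodal(seeg, video, fs = 256, fps = 30)
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$start, 100)
  expect_gte(pooled$end, 300)
  expect_match(pooled$modality, "seeg\\+video")

  # video-only detection survives pooling (union can only add coverage)
  vid_only <- pool_multimodal(anomaly_intervals(),
                              anomaly_intervals(30, 60, 1, "video", "cam"),
                              fs = 256, fps = 30)
  expect_equal(nrow(vid_only), 1L)
  expect_equal(vid_only$start, floor(30 * 256 / 30))
  expect_equal(nrow(pool_multimodal(anomaly_intervals(), anomaly_intervals(),
                                    256, 30)), 0L)
})

test_that("event matching pins overlap and one-to-many semantics", {
  truth <- event_labels(15, 25, fs = 1)
  m <- match_events(anomaly_intervals(10, 20, 1), truth)
  expect_equal(m, list(tp_pred = 1L, fp_pred = 0L, detected_events = 1L,
                       missed_events = 0L))
  m2 <- match_events(anomaly_intervals(0, 5, 1), truth)
  expect_equal(m2$fp_pred, 1L)
  expect_equal(m2$missed_events, 1L)
  # one prediction covering two events: one TP prediction, two detections
  truth2 <- event_labels(c(12, 20), c(14, 22), fs = 1)
  m3 <- match_events(anomaly_intervals(10, 30, 1), truth2)
  expect_equal(m3$tp_pred, 1L)
  expect_equal(m3$detected_events, 2L)
  # half-open: touching intervals do not overlap
  m4 <- match_events(anomaly_intervals(10, 15, 1), truth)
  expect_equal(m4$tp_pred, 0L)
})

test_that("event matching is invariant under a common time shift", {
  set.seed(14)
  pred <- anomaly_intervals(c(5, 50), c(15, 60), c(1, 1))
  truth <- event_labels(c(10, 100), c(20, 110), fs = 1)
  base <- match_events(pred, truth)
  sh <- 1000
  pred2 <- anomaly_intervals(pred$start + sh, pred$end + sh, pred$peak_error)
  truth2 <- event_labels(truth$start + sh, truth$end + sh, fs = 1)
  expect_equal(match_events(pred2, truth2), base)
})

test_that("scores compute PPV/sensitivity/F1 and report undefined PPV as missing", {
  r <- score_detection(counts = list(tp_pred = 1L, fp_pred = 1L,
                                     detected_events = 1L, missed_events = 0L))
  expect_equal(r$ppv, 50)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$f1, 2 * 0.5 * 1 / 1.5)

  none <- score_detection(anomaly_intervals(), event_labels(10, 20, fs = 1))
  expect_true(none$ppv_undefined)
  expect_true(is.na(none$ppv))
  expect_equal(none$sensitivity, 0)

  perfect <- score_detection(anomaly_intervals(10, 20, 1),
                             event_labels(12, 18, fs = 1))
  expect_equal(perfect$ppv, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$f1, 1)
})

test_that("report aggregation computes mean and SEM, excluding undefined values", {
  mk <- function(ppv, cond = "seeg-dynamic") {
    score_detection(counts = list(tp_pred = 1L, fp_pred = 0L,
                                  detected_events = 1L, missed_events = 0L),
                    condition = cond) -> r
    r$ppv <- ppv
    r
  }
  tab <- aggregate_reports(list(mk(1), mk(2), mk(3)))
  row <- tab[tab$metric == "ppv", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sem, sd(c(1, 2, 3)) / sqrt(3))
  single <- aggregate_reports(list(mk(5)))
  expect_true(is.na(single$sem[single$metric == "ppv"]))
  mixed <- aggregate_reports(list(mk(4), mk(NA_real_)))
  prow <- mixed[mixed$metric == "ppv", ]
  expect_equal(prow$n, 1L)
  expect_equal(prow$n_undefined, 1L)
})

test_that("crossover runs score foreign models and reject rate mismatches", {
  gen <- gen_seeg_channel(background_spec(duration_s = 120),
                          seizure_spec(n_events = 1), seed = 5,
                          patient_id = "pA")
  sp <- split_train_test(lowpass_filter(gen$series), 0.3)
  model <- fit_forecaster(scale_minmax(sp$train),
                          forecast_config(history_window = 64L), method = "ar")
  genB <- gen_seeg_channel(background_spec(duration_s = 120),
                           seizure_spec(n_events = 1), seed = 6,
                           patient_id = "pB")
  rep <- suppressMessages(crossover_run(model, genB$series, genB$labels))
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$condition, "crossover")

  wrong_fs <- channel_series(rnorm(5000), 128, patient_id = "pC")
  expect_error(crossover_run(model, wrong_fs, genB$labels),
               "mismatch", class = "seegwatch_parameter_error")
})
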