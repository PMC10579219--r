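# Training loop behaviour, evaluation, repeat aggregation, and the bridge
# from prediction tracks to intervals and durations.

test_that("train_config validates ranges", {
  m <- tiny_model()
  expect_error(train_config("XYZ", m), "PHASE_NAMES|phase")
  expect_error(train_config("PTT", m, epochs = 0), "epochs")
  expect_error(train_config("PTT", m, threshold = 1), "threshold")
})

test_that("training refuses single-class data", {
  ds <- easy_dataset()
  # OPD labels are all-positive only if the interval covered everything;
  # build a degenerate phase by relabeling through an impossible threshold:
  # use a phase whose interval is empty in a hand-built dataset instead
  ev <- event_set("flat", 0, 13, 13, 15, 16, 22, 24, clip_length = 30)
  fr <- array(0.4, dim = c(30, 16, 16, 3))
  clip <- structure(list(frames = fr, fps = 15, clip_id = "flat"),
                    class = "video_clip")
  flat <- phase_dataset(list(clip), list(ev))
  tcfg <- train_config("PDT", tiny_model(), epochs = 1, seed = 1)
  expect_error(train_phase_detector(flat, NULL, tcfg), "single class")
})

test_that("the detector learns the easy fixture and is reproducible", {
  ds <- easy_dataset()
  det <- easy_detector()
  h <- det$history
  # learning happened: final-epoch loss below first-epoch loss
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  # separability bar on the easy fixture
  expect_gte(max(h$val_f1), 0.8)
  # positive windows score higher than negative windows on test clips
  clip <- ds$test$clips[[1]]
  truth <- label_frames(ds$test$events[[1]], "PTT", dim(clip$frames)[1])
  tr <- predict_video(det, clip, "PTT")
  expect_gt(mean(tr$probs[truth == 1]), mean(tr$probs[truth == 0]))
})

test_that("two trainings with the same seed give identical results", {
  ds <- easy_dataset()
  small <- phase_dataset(ds$train$clips[1:4], ds$train$events[1:4])
  tcfg <- train_config("PTT", tiny_model(widths = c(2, 2, 4, 8)), epochs = 1,
                       batch_size = 16, windows_per_clip = 12, seed = 5)
  d1 <- train_phase_detector(small, ds$val, tcfg)
  d2 <- train_phase_detector(small, ds$val, tcfg)
  expect_identical(d1$history, d2$history)
  expect_identical(coef(d1), coef(d2))
})

test_that("evaluate_detector pools frames and reports sane metrics", {
  ds <- easy_dataset()
  det <- easy_detector()
  ev <- evaluate_detector(det, ds$test)
  expect_equal(sum(ev$counts),
               sum(vapply(ds$test$clips, function(c) dim(c$frames)[1], numeric(1))))
  for (m in c("accuracy", "precision", "recall", "f1", "ap")) {
    expect_true(is.na(ev$metrics[[m]]) ||
                  (ev$metrics[[m]] >= 0 && ev$metrics[[m]] <= 1))
  }
  # the easy fixture should evaluate well, not just train well
  expect_gte(ev$metrics$f1, 0.8)
  # per-clip averaging is available as a switch
  ev2 <- evaluate_detector(det, ds$test, pooled = FALSE)
  expect_false(ev2$pooled)
})

test_that("repeat aggregation returns per-repeat records with mean and SD", {
  ds <- easy_dataset()
  small_train <- phase_dataset(ds$train$clips[1:4], ds$train$events[1:4])
  tcfg <- train_config("PTT", tiny_model(widths = c(2, 2, 4, 8)), epochs = 1,
                       windows_per_clip = 10, n_repeats = 2, seed = 3)
  rep_out <- repeat_experiment(small_train, NULL, ds$test, tcfg)
  expect_s3_class(rep_out, "metrics_report")
  expect_equal(nrow(rep_out$records), 2)
  expect_equal(rep_out$aggregate$accuracy$mean, mean(rep_out$records$accuracy))
  expect_equal(rep_out$aggregate$accuracy$sd, sd(rep_out$records$accuracy))
  expect_gte(rep_out$aggregate$accuracy$sd, 0)
})

test_that("track_to_interval binarizes with the requested smoothing", {
  probs <- rep(0.1, 20)
  probs[6:12] <- 0.9
  iv <- track_to_interval(probs, 0.5, "none")
  expect_equal(c(iv$start, iv$end), c(5, 12))        # half-open [5, 12)

  probs2 <- rep(0.1, 25)
  probs2[4:6] <- 0.9                                  # run [3, 6)
  probs2[11:20] <- 0.9                                # run [10, 20)
  iv2 <- track_to_interval(probs2, 0.5, "longest_run")
  expect_equal(c(iv2$start, iv2$end), c(10, 20))

  iv3 <- track_to_interval(rep(0.2, 10), 0.5)
  expect_true(iv3$empty)
  expect_equal(c(iv3$start, iv3$end), c(0, 0))

  # close_gaps(k) fills sub-k negative gaps before extracting the run
  probs4 <- rep(0.9, 15)
  probs4[8] <- 0.1
  iv4 <- track_to_interval(probs4, 0.5, "close_gaps", k = 2)
  expect_equal(c(iv4$start, iv4$end), c(0, 15))
})

test_that("measure_from_predictions reports durations and deltas", {
  ev <- ref_events()
  ivs <- stats::setNames(lapply(PHASE_NAMES, function(ph) {
    iv <- events_to_phase_interval(ev, ph)
    list(phase = ph, start = iv$start, end = iv$end, empty = FALSE)
  }), PHASE_NAMES)
  out <- measure_from_predictions(ivs, 15, truth = ev)
  expect_equal(out$delta_ms, rep(0, 7))
  expect_equal(out$pred_ms[out$phase == "PTT"], 800)

  ivs$PTT <- list(phase = "PTT", start = 0L, end = 0L, empty = TRUE)
  ivs$OPD <- NULL
  out2 <- measure_from_predictions(ivs, 15)
  expect_equal(out2$pred_ms[out2$phase == "PTT"], 0)
  expect_true(out2$empty[out2$phase == "PTT"])
  expect_true(is.na(out2$pred_ms[out2$phase == "OPD"]))  # absent, not faked
})
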