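# Event calculus: frame/duration conversion, the seven temporal parameters,
# phase intervals, annotation IO.

test_that("frames_to_duration converts, preserves sign, and is linear", {
  expect_equal(frames_to_duration(15, 15, "s"), 1)
  expect_equal(frames_to_duration(0, 15, "ms"), 0)
  expect_equal(frames_to_duration(3, 15, "ms"), 200)
  expect_equal(frames_to_duration(-3, 15, "ms"), -200)
  # linearity: f(a+b) = f(a) + f(b), f(-a) = -f(a)
  set.seed(1)
  a <- runif(50, -100, 100); b <- runif(50, -100, 100)
  expect_equal(frames_to_duration(a + b, 15),
               frames_to_duration(a, 15) + frames_to_duration(b, 15))
  expect_equal(frames_to_duration(-a, 15), -frames_to_duration(a, 15))
  # rounding applies to seconds at presentation only
  expect_equal(frames_to_duration(4.526, 15, "s", rounded = TRUE), 0.302)
  expect_gt(abs(frames_to_duration(4.526, 15, "s") - 0.302), 0)
  expect_error(frames_to_duration(1, 0), "fps")
  expect_error(frames_to_duration(1, -15), "fps")
})

test_that("compute_parameters maps events to the seven durations", {
  ev <- ref_events()
  p <- compute_parameters(ev, 15)
  expect_equal(p$opd_ms, 10 * 1000 / 15)
  expect_equal(p$pdt_ms, 200)
  expect_equal(p$prt_ms, 600)
  expect_equal(p$ptt_ms, 800)
  expect_equal(p$lvcrt_ms, 2 * 1000 / 15)
  expect_equal(p$lvcd_ms, 600)
  expect_equal(p$uesod_ms, 400)

  # coincident hyoid burst and bolus-past-mandible
  ev2 <- event_set("c", 0, 13, 13, 15, 16, 22, 24)
  expect_equal(compute_parameters(ev2, 15)$pdt_ms, 0)

  # hyoid burst preceding the bolus: signed negative delay
  ev3 <- event_set("c", 0, 12, 10, 15, 16, 22, 24)
  expect_equal(compute_parameters(ev3, 15)$pdt_ms, -2 * 1000 / 15)
})

test_that("event_set invariants are enforced with named errors", {
  expect_error(event_set("x", 1, 10, 13, 15, 16, 22, 24), "oral_start")
  expect_error(event_set("x", 0, 10, 13, 15, 22, 16, 24), "ues_opening")
  expect_error(event_set("x", 0, 10, 13, 24, 16, 22, 15), "lvc_onset")
  expect_error(event_set("x", 0, -1, 13, 15, 16, 22, 24), "negative")
  expect_error(event_set("x", 0, 10, 13, 15, 16, 22, 24, clip_length = 20),
               "clip_length")
  # permitted irregular orders: hyoid before bolus, LVC onset before hyoid
  expect_silent(validate_event_set(event_set("x", 0, 12, 10, 8, 16, 22, 24)))
})

test_that("PTT = PDT + PRT exactly, and intervals match parameter magnitudes", {
  set.seed(42)
  for (i in 1:200) {
    ev <- random_events(paste0("r", i))
    fr <- swallowphase:::phase_frame_counts(ev)
    # the identity is exact in the represented quantity: integer frame counts
    expect_identical(fr[["PTT"]], fr[["PDT"]] + fr[["PRT"]])
    p <- compute_parameters(ev, 15)
    expect_equal(p$ptt_ms, p$pdt_ms + p$prt_ms)
    for (ph in PHASE_NAMES) {
      iv <- events_to_phase_interval(ev, ph)
      key <- c(OPD = "opd_ms", PDT = "pdt_ms", PRT = "prt_ms", PTT = "ptt_ms",
               LVCRT = "lvcrt_ms", LVC_DURATION = "lvcd_ms", UESOD = "uesod_ms")[[ph]]
      expect_equal(frames_to_duration(iv$end - iv$start, 15), abs(p[[key]]))
    }
  }
})

test_that("phase intervals are half-open with a reversed flag for PDT/LVCRT", {
  ev <- ref_events()
  iv <- events_to_phase_interval(ev, "PTT")
  expect_equal(c(iv$start, iv$end), c(10, 22))
  expect_false(iv$reversed)

  ev2 <- event_set("c", 0, 13, 13, 15, 16, 22, 24)
  iv2 <- events_to_phase_interval(ev2, "PDT")
  expect_equal(c(iv2$start, iv2$end), c(13, 13))   # legal empty interval

  ev3 <- event_set("c", 0, 12, 10, 15, 16, 22, 24)
  iv3 <- events_to_phase_interval(ev3, "PDT")
  expect_equal(c(iv3$start, iv3$end), c(10, 12))
  expect_true(iv3$reversed)

  expect_error(events_to_phase_interval(ev, "NOT_A_PHASE"), "unknown phase")
})

test_that("annotation round trip is lossless for CSV and JSON", {
  set.seed(7)
  evs <- lapply(1:5, function(i) random_events(paste0("clip", i)))
  for (ext in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_annotations(evs, path)
    back <- read_annotations(path)
    expect_equal(lapply(back, unclass), lapply(evs, unclass))
  }
})

annotations_df_fixture <- function() {
  data.frame(clip_id = c("a", "b"), oral_start = 0L,
             bolus_past_mandible = 10L, hyoid_burst = 13L, lvc_onset = 15L,
             ues_opening = 16L, ues_closure = 22L,
             lvc_offset = c(24L, 14L))   # row 2: lvc_offset < lvc_onset
}

test_that("annotation parsing reports missing columns and bad rows", {
  path <- tempfile(fileext = ".csv")
  write_annotations(list(ref_events()), path)
  df <- read.csv(path)
  write.csv(df[, setdiff(names(df), "ues_closure")], path, row.names = FALSE)
  expect_error(read_annotations(path), "ues_closure")

  df2 <- annotations_df_fixture()
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_annotations(path), "row 2")

  df2$lvc_offset <- c(24L, 24L)
  df2$oral_start <- c(0L, 0.5)
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_annotations(path), "non-integer")
})

test_that("parameter_report gives one row per clip in milliseconds", {
  evs <- list(ref_events("a"), ref_events("b"))
  rep <- parameter_report(evs, 15)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$ptt_ms, c(800, 800))
  expect_equal(rep$fps, c(15, 15))
})
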