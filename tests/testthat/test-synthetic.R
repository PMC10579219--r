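# Synthetic generator: schedule sampling (calibration, determinism), scene
# rendering consistency with the event schedule, dataset writing.

test_that("degenerate zero-SD config draws the rounded means deterministically", {
  st <- default_duration_stats()
  st$mean_frames <- round(st$mean_frames)
  st$sd_frames <- 0
  cfg <- scene_config(duration_stats = st, negative_pdt_prob = 0,
                      negative_lvcrt_prob = 0)
  ev <- sample_event_schedule(cfg, seed = 1)
  expect_equal(ev$bolus_past_mandible, 28L)          # rounded OPD mean
  fr <- swallowphase:::phase_frame_counts(ev)
  expect_equal(unname(fr[c("PDT", "PRT", "LVCRT", "LVC_DURATION", "UESOD")]),
               c(21, 10, 5, 10, 6))
})

test_that("schedule sampling is deterministic given a seed", {
  cfg <- scene_config()
  e1 <- sample_event_schedule(cfg, seed = 99)
  e2 <- sample_event_schedule(cfg, seed = 99)
  expect_identical(unclass(e1), unclass(e2))
  e3 <- sample_event_schedule(cfg, seed = 100)
  expect_false(identical(unclass(e1), unclass(e3)))
})

test_that("unsatisfiable duration configs are rejected", {
  st <- default_duration_stats()
  st$sd_frames <- 0
  st$mean_frames[1] <- 0
  cfg <- scene_config(duration_stats = st)
  expect_error(sample_event_schedule(cfg, seed = 1), "unsatisfiable")
})

test_that("phase frame counts are calibrated to the configured means", {
  cfg <- scene_config(negative_pdt_prob = 0, negative_lvcrt_prob = 0)
  evs <- lapply(1:1000, function(i) sample_event_schedule(cfg, seed = 40000 + i))
  fr <- t(vapply(evs, function(e) swallowphase:::phase_frame_counts(e),
                 numeric(7)))
  st <- default_duration_stats()
  for (ph in st$phase) {
    m <- mean(fr[, ph])
    se <- sd(fr[, ph]) / sqrt(nrow(fr))
    target <- st$mean_frames[st$phase == ph]
    expect_lt(abs(m - target), 3 * se)
    expect_true(all(fr[, ph] >= 1))                  # 1-frame floor
  }
})

test_that("reversed-order events occur at the configured rates", {
  cfg <- scene_config(negative_pdt_prob = 0.5, negative_lvcrt_prob = 0)
  evs <- lapply(1:300, function(i) sample_event_schedule(cfg, seed = 70000 + i))
  neg <- mean(vapply(evs, function(e) e$hyoid_burst < e$bolus_past_mandible,
                     logical(1)))
  # some draws cannot be flipped (OPD or PRT of 1 frame), so the realized
  # rate sits at or slightly below the configured probability
  expect_gt(neg, 0.3)
  expect_lte(neg, 0.55)
})

test_that("rendered clips honour the length contract and pixel range", {
  cfg <- scene_config()
  ev <- sample_event_schedule(cfg, seed = 5, clip_id = "render1")
  clip <- render_clip(ev, cfg, seed = 5)
  expect_equal(dim(clip$frames)[1],
               1L + max(unlist(ev[EVENT_NAMES])) + cfg$rest_margin)
  expect_equal(dim(clip$frames)[2:4], c(64, 64, 3))
  expect_true(all(clip$frames >= 0 & clip$frames <= 1))
  # grayscale replicated across the three channels
  expect_equal(clip$frames[, , , 1], clip$frames[, , , 2])
})

test_that("pixel range survives every irregularity", {
  cfg <- scene_config(drift = TRUE, occluder = TRUE, hand = TRUE,
                      contrast_jitter = TRUE, noise_sd = 0.08)
  ev <- sample_event_schedule(cfg, seed = 3, clip_id = "irr")
  clip <- render_clip(ev, cfg, seed = 3)
  expect_true(all(clip$frames >= 0 & clip$frames <= 1))
})

test_that("the bolus leading edge crosses the mandible line exactly at its event frame", {
  cfg <- scene_config(noise_sd = 0.01)
  geo <- scene_geometry(cfg)
  for (s in 1:4) {
    ev <- sample_event_schedule(cfg, seed = 200 + s, clip_id = "edge")
    clip <- render_clip(ev, cfg, seed = 200 + s)
    m <- measure_scene(clip, cfg)
    bpm <- ev$bolus_past_mandible
    if (bpm >= 1) expect_lt(m$bolus_edge[bpm], geo$mandible_x)
    expect_gte(m$bolus_edge[bpm + 1], geo$mandible_x)
  }
})

test_that("vestibule intensity jumps at LVC onset beyond the noise level", {
  cfg <- scene_config(noise_sd = 0.02)
  geo <- scene_geometry(cfg)
  ev <- sample_event_schedule(cfg, seed = 9, clip_id = "vest")
  clip <- render_clip(ev, cfg, seed = 9)
  vmean <- function(t0) mean(clip$frames[t0 + 1, geo$vest_rows, geo$vest_cols, 1])
  jump <- abs(vmean(ev$lvc_onset) - vmean(ev$lvc_onset - 1))
  expect_gt(jump, cfg$noise_sd)
})

test_that("read-back oracles recover every event within one frame", {
  cfg <- scene_config(negative_pdt_prob = 0, negative_lvcrt_prob = 0)
  for (s in 1:6) {
    ev <- sample_event_schedule(cfg, seed = 300 + s, clip_id = "rb")
    clip <- render_clip(ev, cfg, seed = 300 + s)
    rec <- recover_events(clip, cfg)
    d <- abs(unlist(rec[EVENT_NAMES]) - unlist(ev[EVENT_NAMES]))
    expect_true(all(d <= 1))
  }
})

test_that("generate_dataset is reproducible and splits 81/9/10", {
  d1 <- file.path(tempdir(), "ds_a"); d2 <- file.path(tempdir(), "ds_b")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- scene_config()
  generate_dataset(10, cfg, d1, seed = 1)
  generate_dataset(10, cfg, d2, seed = 1)
  expect_identical(readLines(file.path(d1, "annotations.csv")),
                   readLines(file.path(d2, "annotations.csv")))
  man <- read_manifest(d1)
  expect_equal(nrow(man$clips), 10)
  expect_true(all(file.exists(file.path(d1, man$clips$path))))
  # split-size rule: floor for train and val, remainder to test
  sp100 <- split_assignment(100)
  expect_equal(unname(c(sum(sp100 == "train"), sum(sp100 == "val"),
                        sum(sp100 == "test"))), c(81, 9, 10))
  expect_equal(sum(man$clips$split == "train"), 8)
  expect_equal(sum(man$clips$split == "test"), 2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("clips round trip through the packed clip files", {
  dir <- file.path(tempdir(), "ds_rt")
  unlink(dir, recursive = TRUE)
  generate_dataset(3, scene_config(), dir, seed = 2)
  man <- read_manifest(dir)
  clip <- load_clip(file.path(dir, man$clips$path[1]))
  expect_s3_class(clip, "video_clip")
  expect_equal(clip$fps, 15)
  ev <- man$events[[clip$clip_id]]
  expect_equal(dim(clip$frames)[1], ev$clip_length)
  unlink(dir, recursive = TRUE)
})
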