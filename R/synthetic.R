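# Synthetic fluoroscopy-like clip generator.
#
# Emulates the structure a lateral-view swallow recording: a bolus traverses
# oral cavity -> mandible line -> pharynx -> UES; the hyoid jumps
# anterosuperiorly at its burst frame; the laryngeal vestibule air space fills
# during closure; the UES gate opens and closes. Phase durations are drawn
# from distributions calibrated to published per-phase frame statistics.

#' Published per-phase frame-count statistics (mean, SD)
#'
#' Mean and standard deviation of the number of frames per swallowing phase at
#' 15 FPS, used as the default calibration of the synthetic generator. PTT is
#' not sampled: it is the sum of PDT and PRT by construction.
#' @export
default_duration_stats <- function() {
  data.frame(
    phase = c("OPD", "PDT", "PRT", "LVCRT", "LVC_DURATION", "UESOD"),
    mean_frames = c(27.658, 20.809, 10.148, 4.526, 10.053, 6.483),
    sd_frames = c(34.215, 42.856, 2.060, 1.687, 3.987, 1.746),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic fluoroscopy scene
#'
#' @param height,width frame size in pixels (>= 32).
#' @param fps frames per second (default 15, the fluoroscopy acquisition rate).
#' @param duration_stats data.frame with columns `phase`, `mean_frames`,
#'   `sd_frames` for the six sampled phases; defaults to
#'   [default_duration_stats()].
#' @param negative_pdt_prob probability that the hyoid burst precedes the
#'   bolus passing the mandible (reversed pharyngeal delay time).
#' @param negative_lvcrt_prob probability that LVC onset precedes the hyoid
#'   burst (reversed LVC reaction time).
#' @param drift,occluder,hand,contrast_jitter irregularity flags: gradual
#'   patient drift toward the frame edge, a static occluding rectangle over
#'   the throat, a moving hand-like blob entering the frame, per-frame
#'   contrast fluctuation.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param rest_margin frames of swallow rest appended after the last event.
#' @param max_frames maximum clip length; schedules longer than this are
#'   redrawn (default `Inf`, no cap).
#' @return an object of class `"scene_config"`.
#' @export
scene_config <- function(height = 64, width = 64, fps = 15,
                         duration_stats = default_duration_stats(),
                         negative_pdt_prob = 0.1,
                         negative_lvcrt_prob = 0.05,
                         drift = FALSE, occluder = FALSE, hand = FALSE,
                         contrast_jitter = FALSE,
                         noise_sd = 0.01, rest_margin = 5,
                         max_frames = Inf) {
  stopifnot(height >= 32, width >= 32, fps > 0,
            negative_pdt_prob >= 0, negative_pdt_prob <= 1,
            negative_lvcrt_prob >= 0, negative_lvcrt_prob <= 1,
            noise_sd >= 0, rest_margin >= 0)
  need <- c("phase", "mean_frames", "sd_frames")
  if (!all(need %in% names(duration_stats))) {
    stop("duration_stats must have columns: ", paste(need, collapse = ", "))
  }
  if (any(duration_stats$sd_frames < 0)) stop("duration SDs must be >= 0")
  structure(list(
    height = as.integer(height), width = as.integer(width), fps = fps,
    duration_stats = duration_stats,
    negative_pdt_prob = negative_pdt_prob,
    negative_lvcrt_prob = negative_lvcrt_prob,
    drift = drift, occluder = occluder, hand = hand,
    contrast_jitter = contrast_jitter,
    noise_sd = noise_sd, rest_margin = as.integer(rest_margin),
    max_frames = max_frames
  ), class = "scene_config")
}

# ---- seeded execution ------------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded draws never perturb the
#' caller's random stream. With `seed = NULL` the expression runs on the
#' current stream.
#' @param seed integer seed or NULL.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible 31-bit sub-seed from a root seed and a label
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", seed))) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# ---- moment-matched duration sampling --------------------------------------

# Frame counts are integers >= 1: a latent normal is rounded and floored at 1.
# The latent location is solved so the expectation of the discretised draw
# equals the target mean, keeping the calibration exact despite the floor
# (for phases whose SD exceeds the mean, naive truncation would inflate the
# mean by many frames).
.mu_cache <- new.env(parent = emptyenv())

matched_location <- function(target_mean, sd) {
  if (sd == 0) {
    if (round(target_mean) < 1) {
      stop("unsatisfiable duration config: mean ", target_mean,
           " with zero SD rounds below 1 frame")
    }
    return(target_mean)
  }
  if (target_mean <= 1) {
    stop("unsatisfiable duration config: mean ", target_mean,
         " frames cannot be met with a 1-frame floor")
  }
  key <- paste(target_mean, sd)
  if (!is.null(.mu_cache[[key]])) return(.mu_cache[[key]])
  expected <- function(mu) {
    kmax <- max(3, ceiling(mu + 12 * sd))
    k <- seq(2L, kmax)
    pnorm(1.5, mu, sd) +
      sum(k * (pnorm(k + 0.5, mu, sd) - pnorm(k - 0.5, mu, sd))) +
      (kmax + 1) * pnorm(kmax + 0.5, mu, sd, lower.tail = FALSE)
  }
  mu <- uniroot(function(m) expected(m) - target_mean,
                lower = target_mean - 10 * sd - 2,
                upper = target_mean + 2, tol = 1e-9)$root
  .mu_cache[[key]] <- mu
  mu
}

# n integer frame counts >= 1 with expectation target_mean (sd > 0)
draw_frames <- function(n, target_mean, sd) {
  mu <- matched_location(target_mean, sd)
  if (sd == 0) return(rep(as.integer(round(target_mean)), n))
  pmax(1L, as.integer(round(rnorm(n, mu, sd))))
}

#' Sample a consistent swallowing-event schedule
#'
#' Draws the six phase frame counts from the configured distributions and
#' assembles them into a valid [event_set()] with `oral_start = 0`. With the
#' configured probabilities the pharyngeal delay time or LVC reaction time is
#' reversed (hyoid burst before bolus-past-mandible, or LVC onset before the
#' hyoid burst) by a small number of frames, as observed clinically. The clip
#' length is `1 + max(event index) + rest_margin`.
#'
#' @param config a [scene_config()].
#' @param seed integer seed or NULL (use the current RNG stream).
#' @return an [event_set()] with `clip_length` set.
#' @export
sample_event_schedule <- function(config, seed = NULL, clip_id = "synthetic") {
  with_seed(seed, {
    for (attempt in 1:100) {
      ev <- sample_schedule_once(config, clip_id)
      if (ev$clip_length <= config$max_frames) return(ev)
    }
    stop("could not sample a schedule within max_frames = ", config$max_frames)
  })
}

#' @param clip_id identifier stored in the returned event set.
#' @rdname sample_event_schedule
sample_schedule_once <- function(config, clip_id) {
  st <- config$duration_stats
  g <- function(phase) {
    row <- st[st$phase == phase, ]
    if (nrow(row) != 1) stop("duration_stats missing phase ", phase)
    draw_frames(1L, row$mean_frames, row$sd_frames)
  }
  opd <- g("OPD"); pdt <- g("PDT"); prt <- g("PRT")
  lvcrt <- g("LVCRT"); lvcd <- g("LVC_DURATION"); uesod <- g("UESOD")

  # reversed-order events: small negative offsets bounded by the invariants
  if (runif(1) < config$negative_pdt_prob) {
    m <- min(sample.int(3L, 1L), opd - 1L, prt - 1L)
    if (m >= 1L) pdt <- -m
  }
  hyoid <- opd + pdt                      # bolus_past_mandible = opd
  if (runif(1) < config$negative_lvcrt_prob) {
    m <- min(sample.int(2L, 1L), hyoid)
    if (m >= 1L) lvcrt <- -m
  }
  ues_closure <- hyoid + prt
  uesod <- min(uesod, ues_closure)        # keep ues_opening >= 0 (rare clamp)
  ues_opening <- ues_closure - uesod
  lvc_onset <- hyoid + lvcrt
  lvc_offset <- lvc_onset + lvcd
  len <- 1L + max(opd, hyoid, lvc_onset, ues_opening, ues_closure, lvc_offset) +
    config$rest_margin
  event_set(clip_id, 0L, opd, hyoid, lvc_onset, ues_opening, ues_closure,
            lvc_offset, clip_length = len)
}

# ---- scene geometry --------------------------------------------------------

#' Pixel geometry of the rendered scene
#'
#' Fixed anatomical landmarks expressed in pixel coordinates for a given frame
#' size: the mandible line column, pharyngeal wall, vestibule and UES-gate
#' rectangles, hyoid rest position, and the rendering intensities. Exposed so
#' read-back oracles share the renderer's geometry.
#' @param config a [scene_config()].
#' @export
scene_geometry <- function(config) {
  H <- config$height; W <- config$width
  list(
    mandible_x = round(0.40 * W),
    mandible_rows = round(0.15 * H):round(0.55 * H),
    pharynx_x = round(0.80 * W),
    pharynx_rows = round(0.20 * H):round(0.90 * H),
    vest_rows = round(0.55 * H):round(0.64 * H),
    vest_cols = round(0.62 * W):round(0.72 * W),
    gate_rows = round(0.84 * H):round(0.88 * H),
    gate_cols = round(0.70 * W):round(0.80 * W),
    hyoid_xy = c(round(0.55 * W), round(0.70 * H)),   # (col, row) at rest
    hyoid_jump = c(-3L, -5L),                         # anterosuperior (left, up)
    hyoid_r = 2,
    bolus_r = 2.5,
    oral_y = round(0.30 * H),
    oral_x0 = round(0.12 * W),
    # intensities
    bg = 0.15, line = 0.40, vest_open = 0.05, vest_closed = 0.45,
    gate_closed = 0.60, gate_open = 0.10, hyoid_int = 0.80, bolus_int = 1.0
  )
}

# draw a filled disc of given intensity onto matrix m (rows x cols)
draw_disc <- function(m, cx, cy, r, val) {
  H <- nrow(m); W <- ncol(m)
  rows <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  if (!length(rows) || !length(cols)) return(m)
  dd <- outer((rows - cy)^2, (cols - cx)^2, "+")
  sub <- m[rows, cols, drop = FALSE]
  sub[dd <= r^2] <- val
  m[rows, cols] <- sub
  m
}

# Bolus state at frame t (0-based): center (col, row) and leading-edge
# column, or NAs once the bolus has passed below the UES. The pharyngeal
# path descends close behind the mandible line, then runs horizontally below
# the vestibule region to the UES gate, so the bolus never enters the
# vestibule rectangle the LVC oracle reads.
bolus_state <- function(t, events, geo) {
  bpm <- events$bolus_past_mandible
  uc <- events$ues_closure
  r <- geo$bolus_r
  if (t >= uc) return(list(center = c(NA_real_, NA_real_), edge = NA_real_))
  if (t < bpm) {
    # oral transit: edge advances linearly, clamped strictly left of the line
    x0 <- geo$oral_x0 + r
    le <- x0 + (geo$mandible_x - x0) * if (bpm > 0) t / bpm else 0
    edge <- min(round(le), geo$mandible_x - 1)
    return(list(center = c(edge - r, geo$oral_y), edge = edge))
  }
  # pharyngeal transit: piecewise path, crossing the line exactly at bpm
  uo <- max(events$ues_opening, bpm + 1L)
  frac <- min(1, (t - bpm) / (uo - bpm))
  y_low <- min(geo$gate_rows) - 4      # travel lane just above the gate rows
  p0 <- c(geo$mandible_x - r, geo$oral_y)
  p1 <- c(geo$mandible_x - r + 3, y_low)
  p2 <- c(mean(geo$gate_cols), y_low)
  cen <- if (frac <= 0.35) {
    p0 + (p1 - p0) * frac / 0.35
  } else {
    p1 + (p2 - p1) * (frac - 0.35) / 0.65
  }
  list(center = cen, edge = round(cen[1] + r))
}

#' Render a synthetic clip for a given event schedule
#'
#' Draws, per frame: the static anatomy (mandible line, pharyngeal wall), the
#' bolus disc whose leading edge crosses the mandible line exactly at
#' `bolus_past_mandible` and which disappears below the UES at `ues_closure`,
#' the hyoid marker (displaced anterosuperiorly from `hyoid_burst`), the
#' vestibule air space (filled during `[lvc_onset, lvc_offset)`), and the UES
#' gate (open during `[ues_opening, ues_closure)`); then the enabled
#' irregularities and additive noise, clamped to `[0, 1]`. Frames are
#' grayscale replicated to 3 channels.
#'
#' @param events a valid [event_set()] with `clip_length`.
#' @param config a [scene_config()].
#' @param seed integer seed for noise/irregularities, or NULL.
#' @return an object of class `"video_clip"`: list with `frames`
#'   (T x H x W x 3 array in `[0,1]`), `fps`, `clip_id`.
#' @export
render_clip <- function(events, config, seed = NULL) {
  validate_event_set(events)
  Tlen <- events$clip_length
  if (is.null(Tlen)) Tlen <- 1L + max(unlist(events[EVENT_NAMES])) + config$rest_margin
  if (Tlen > config$max_frames) {
    stop("events span ", Tlen, " frames, beyond max_frames = ", config$max_frames)
  }
  H <- config$height; W <- config$width
  geo <- scene_geometry(config)

  base <- matrix(geo$bg, H, W)
  base[geo$mandible_rows, geo$mandible_x] <- geo$line
  base[geo$pharynx_rows, geo$pharynx_x] <- geo$line

  with_seed(seed, {
    gray <- array(0, dim = c(Tlen, H, W))
    for (t0 in seq_len(Tlen) - 1L) {
      f <- base
      # vestibule air space: dark when open, filled during closure
      closed <- t0 >= events$lvc_onset && t0 < events$lvc_offset
      f[geo$vest_rows, geo$vest_cols] <- if (closed) geo$vest_closed else geo$vest_open
      # UES gate: bright bar when closed, dark gap while open
      open <- t0 >= events$ues_opening && t0 < events$ues_closure
      f[geo$gate_rows, geo$gate_cols] <- if (open) geo$gate_open else geo$gate_closed
      # hyoid marker
      hxy <- geo$hyoid_xy
      if (t0 >= events$hyoid_burst) {
        k <- min(t0 - events$hyoid_burst + 1L, 2L) / 2
        hxy <- hxy + geo$hyoid_jump * k
      }
      f <- draw_disc(f, hxy[1], hxy[2], geo$hyoid_r, geo$hyoid_int)
      # bolus
      bs <- bolus_state(t0, events, geo)
      if (!is.na(bs$center[1])) {
        f <- draw_disc(f, bs$center[1], bs$center[2], geo$bolus_r, geo$bolus_int)
      }
      gray[t0 + 1L, , ] <- f
    }
    gray <- apply_irregularities(gray, config)
    if (config$noise_sd > 0) {
      gray <- gray + rnorm(length(gray), 0, config$noise_sd)
    }
    gray <- pmin(pmax(gray, 0), 1)
    frames <- array(rep(gray, 3L), dim = c(Tlen, H, W, 3L))
    structure(list(frames = frames, fps = config$fps, clip_id = events$clip_id),
              class = "video_clip")
  })
}

# drift / occluder / hand / contrast jitter, applied to the gray T x H x W stack
apply_irregularities <- function(gray, config) {
  Tlen <- dim(gray)[1]; H <- dim(gray)[2]; W <- dim(gray)[3]
  if (config$occluder) {
    rows <- round(0.45 * H):round(0.75 * H)
    cols <- round(0.50 * W):round(0.60 * W)
    gray[, rows, cols] <- 0.35
  }
  if (config$hand) {
    # blob enters from the bottom-left and sweeps right over the clip
    for (t in seq_len(Tlen)) {
      cx <- round(W * (t / Tlen) * 0.6)
      cy <- round(0.9 * H)
      if (cx >= 1) gray[t, , ] <- draw_disc(gray[t, , ], cx, cy, 4, 0.65)
    }
  }
  if (config$drift) {
    # gradual translation toward the frame edge; vacated columns go dark
    for (t in seq_len(Tlen)) {
      off <- round((t - 1) / max(1, Tlen - 1) * 0.25 * W)
      if (off > 0) {
        fr <- gray[t, , ]
        shifted <- matrix(0.02, H, W)
        shifted[, (off + 1):W] <- fr[, 1:(W - off)]
        gray[t, , ] <- shifted
      }
    }
  }
  if (config$contrast_jitter) {
    fac <- runif(Tlen, 0.7, 1.1)
    gray <- gray * fac[slice.index(gray, 1)]
  }
  gray
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_clip> %s: %d frames, %dx%d, %d channel(s), %g fps\n",
              x$clip_id, d[1], d[2], d[3], d[4], x$fps))
  invisible(x)
}

# ---- read-back oracles -----------------------------------------------------

#' Measure scene state from rendered frames (read-back oracles)
#'
#' Independent measurements on a rendered clip used to verify that the
#' renderer honours its event schedule: the bolus leading-edge column
#' (rightmost near-white pixel), whether the vestibule region is filled,
#' whether the UES gate is open, and the hyoid marker centroid.
#'
#' @param clip a [render_clip()] result.
#' @param config the [scene_config()] used for rendering.
#' @return `measure_scene()`: data.frame with one row per frame and columns
#'   `bolus_edge`, `vest_filled`, `gate_open`, `hyoid_dx` (displacement from
#'   the frame-0 hyoid position, in pixels).
#' @export
measure_scene <- function(clip, config) {
  geo <- scene_geometry(config)
  Tlen <- dim(clip$frames)[1]
  edge <- numeric(Tlen); vest <- logical(Tlen); gate <- logical(Tlen)
  hdx <- numeric(Tlen)
  h0 <- NULL
  for (t in seq_len(Tlen)) {
    f <- clip$frames[t, , , 1]
    bol <- which(f > 0.92, arr.ind = TRUE)
    edge[t] <- if (nrow(bol)) max(bol[, 2]) else NA_real_
    vest[t] <- mean(f[geo$vest_rows, geo$vest_cols]) > (geo$vest_open + geo$vest_closed) / 2
    gate[t] <- mean(f[geo$gate_rows, geo$gate_cols]) < (geo$gate_open + geo$gate_closed) / 2
    hy <- which(f > 0.70 & f < 0.92, arr.ind = TRUE)
    cen <- if (nrow(hy)) c(mean(hy[, 2]), mean(hy[, 1])) else c(NA, NA)
    if (t == 1) h0 <- cen
    hdx[t] <- sqrt(sum((cen - h0)^2))
  }
  data.frame(bolus_edge = edge, vest_filled = vest, gate_open = gate,
             hyoid_dx = hdx)
}

#' @rdname measure_scene
#' @return `recover_events()`: an [event_set()] reconstructed purely from the
#'   pixel measurements.
#' @export
recover_events <- function(clip, config) {
  geo <- scene_geometry(config)
  m <- measure_scene(clip, config)
  t0 <- seq_len(nrow(m)) - 1L
  first <- function(mask) if (any(mask)) min(t0[mask]) else NA_integer_
  bpm <- first(!is.na(m$bolus_edge) & m$bolus_edge >= geo$mandible_x)
  uc <- first(is.na(m$bolus_edge) & t0 > bpm)
  hb <- first(m$hyoid_dx > 1.5)
  lvc_on <- first(m$vest_filled)
  lvc_off <- first(!m$vest_filled & t0 > lvc_on)
  uo <- first(m$gate_open)
  event_set(clip$clip_id, 0L, bpm, hb, lvc_on, uo, uc, lvc_off,
            clip_length = nrow(m))
}

# ---- dataset generation ----------------------------------------------------

#' Generate a labeled synthetic dataset with train/val/test split
#'
#' Samples `n_clips` event schedules, renders each clip, and writes to
#' `out_dir`: one packed clip file per clip (`<id>.rds` holding frames + fps),
#' `annotations.csv` in the standard annotation format, and `manifest.json`
#' recording the per-clip split assignment, the config hash, and the seed.
#' The split is by clip: `floor(0.81 n)` train, `floor(0.09 n)` validation,
#' remainder test, mirroring an 81/9/10 percent division.
#'
#' @param n_clips number of clips (>= 3).
#' @param config a [scene_config()].
#' @param out_dir output directory (created if needed).
#' @param seed root seed; all per-clip randomness derives from it.
#' @param split_fracs train/validation fractions (test takes the remainder).
#' @param write_png also export PNG frames for visual inspection.
#' @return the manifest, invisibly (list with `clips`, `config_hash`, `seed`).
#' @export
generate_dataset <- function(n_clips, config, out_dir, seed,
                             split_fracs = c(train = 0.81, val = 0.09),
                             write_png = FALSE) {
  if (n_clips < 3) stop("n_clips must be >= 3 (need one clip per split)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("clip%04d", seq_len(n_clips))
  events <- vector("list", n_clips)
  for (i in seq_len(n_clips)) {
    events[[i]] <- sample_event_schedule(config, seed = derive_seed(seed, paste0("sched:", ids[i])),
                                         clip_id = ids[i])
    clip <- render_clip(events[[i]], config, seed = derive_seed(seed, paste0("render:", ids[i])))
    saveRDS(list(frames = clip$frames, fps = clip$fps, clip_id = clip$clip_id),
            file.path(out_dir, paste0(ids[i], ".rds")))
    if (write_png) export_png_frames(clip, file.path(out_dir, ids[i]))
  }
  write_annotations(events, file.path(out_dir, "annotations.csv"))

  split <- split_assignment(n_clips, split_fracs)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config[setdiff(names(config), "duration_stats")]),
                       cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    clips = data.frame(id = ids, path = paste0(ids, ".rds"), split = split,
                       stringsAsFactors = FALSE),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = seed
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Train/val/test split assignment by clip
#'
#' `floor(frac_train * n)` clips go to train, `floor(frac_val * n)` to
#' validation, and the remainder to test (so n = 100 under the default 0.81 /
#' 0.09 fractions gives 81 / 9 / 10).
#' @param n number of clips.
#' @param split_fracs named train/val fractions.
#' @export
split_assignment <- function(n, split_fracs = c(train = 0.81, val = 0.09)) {
  n_train <- floor(split_fracs[["train"]] * n)
  n_val <- floor(split_fracs[["val"]] * n)
  c(rep("train", n_train), rep("val", n_val), rep("test", n - n_train - n_val))
}

#' Load a clip written by [generate_dataset()]
#' @param path path to a `<id>.rds` clip file.
#' @export
load_clip <- function(path) {
  x <- readRDS(path)
  structure(x, class = "video_clip")
}

#' Read a dataset manifest and its annotations
#' @param dir dataset directory written by [generate_dataset()].
#' @return list with `clips` (data.frame id/path/split), `events` (named list
#'   of event sets), `config_hash`, `seed`, `dir`.
#' @export
read_manifest <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  events <- read_annotations(file.path(dir, "annotations.csv"))
  names(events) <- vapply(events, `[[`, character(1), "clip_id")
  list(clips = man$clips, events = events, config_hash = man$config_hash,
       seed = man$seed, dir = dir)
}

export_png_frames <- function(clip, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    warning("png package not available; skipping PNG export")
    return(invisible(NULL))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_len(dim(clip$frames)[1])) {
    png::writePNG(clip$frames[t, , , 1],
                  file.path(dir, sprintf("frame%04d.png", t - 1L)))
  }
  invisible(dir)
}
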