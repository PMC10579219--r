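# Per-phase binary training, evaluation over test clips, repeat-experiment
# aggregation, and the bridge from prediction tracks back to phase intervals
# and temporal parameters.

#' Training configuration for one phase detector
#'
#' @param phase one of [PHASE_NAMES].
#' @param model a [model_config()].
#' @param epochs training epochs (the best-validation epoch is kept).
#' @param batch_size windows (or segments) per gradient step.
#' @param learning_rate Adam step size.
#' @param threshold decision cutoff on the positive-class probability.
#' @param n_repeats repeats with fresh training seeds for mean ± SD
#'   aggregation (20 in the source protocol).
#' @param windows_per_clip cap on training windows drawn per clip per epoch
#'   (`Inf` = use every frame); sampling is seeded and re-drawn each epoch.
#' @param seed root seed for initialization and shuffling.
#' @return an object of class `"train_config"`.
#' @export
train_config <- function(phase, model, epochs = 10, batch_size = 16,
                         learning_rate = 1e-3, threshold = 0.5,
                         n_repeats = 20, windows_per_clip = Inf, seed = 1) {
  stopifnot(phase %in% PHASE_NAMES, epochs >= 1, batch_size >= 1,
            threshold > 0, threshold < 1, n_repeats >= 1)
  structure(list(phase = phase, model = model, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = "adam",
                 loss = "weighted_ce", threshold = threshold,
                 n_repeats = as.integer(n_repeats),
                 windows_per_clip = windows_per_clip,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Bundle clips with their event annotations
#'
#' @param clips list of `video_clip` objects.
#' @param events list of [event_set()] objects (matched to clips by
#'   `clip_id`).
#' @return class `"phase_dataset"`.
#' @export
phase_dataset <- function(clips, events) {
  names(clips) <- vapply(clips, `[[`, character(1), "clip_id")
  names(events) <- vapply(events, `[[`, character(1), "clip_id")
  missing <- setdiff(names(clips), names(events))
  if (length(missing)) stop("no annotations for clip(s): ",
                            paste(missing, collapse = ", "))
  structure(list(clips = clips, events = events[names(clips)]),
            class = "phase_dataset")
}

#' Load one split of a generated dataset
#' @param manifest result of [read_manifest()].
#' @param split `"train"`, `"val"`, or `"test"`.
#' @export
load_split <- function(manifest, split) {
  rows <- manifest$clips[manifest$clips$split == split, , drop = FALSE]
  clips <- lapply(file.path(manifest$dir, rows$path), load_clip)
  phase_dataset(clips, manifest$events[rows$id])
}

# window sets + flat sample index for one phase over a dataset
build_windows <- function(data, phase, model_cfg) {
  ws_list <- vector("list", length(data$clips))
  for (i in seq_along(data$clips)) {
    clip <- pool_clip(data$clips[[i]], model_cfg$input_size)
    track <- label_frames(data$events[[i]], phase, clip_T(clip))
    ws_list[[i]] <- switch(model_cfg$variant,
      DEFAULT = make_center_windows(clip, track, model_cfg$window_L, "replicate"),
      BIDIRECTIONAL = make_bidirectional_pairs(clip, track, model_cfg$window_L, "replicate"),
      CONV_SA = make_segment_windows(clip, track, model_cfg$segment_W)
    )
  }
  idx <- do.call(rbind, lapply(seq_along(ws_list), function(i) {
    data.frame(clip = i, win = seq_len(n_windows(ws_list[[i]])))
  }))
  list(sets = ws_list, idx = idx)
}

sample_label <- function(ws, j) {
  if (ws$form == "segment") ws$labels[[j]] else ws$labels[j]
}

#' Fit a phase detector
#'
#' The fitting function of the package: trains one binary frame-level
#' detector for one phase by minimizing class-weighted cross-entropy with
#' Adam over window samples, and keeps the epoch with the best pooled
#' validation F1. Deterministic given `config$seed`.
#'
#' @param train,val `phase_dataset` objects (validation may be `NULL`, in
#'   which case the final epoch is kept).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `"phase_detector"` with components `net`,
#'   `phase`, `config`, `history` (per-epoch loss and validation F1),
#'   `threshold`, `best_epoch`.
#' @export
train_phase_detector <- function(train, val = NULL, config, verbose = FALSE) {
  if (!is.null(val) && length(val$clips) == 0) val <- NULL
  phase <- config$phase
  mcfg <- config$model
  mcfg$seed <- derive_seed(config$seed, "init")
  bw <- build_windows(train, phase, mcfg)
  all_labels <- unlist(lapply(seq_len(nrow(bw$idx)), function(k) {
    sample_label(bw$sets[[bw$idx$clip[k]]], bw$idx$win[k])
  }))
  n_pos <- sum(all_labels == 1); n_neg <- sum(all_labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("training data for phase ", phase, " contains a single class (",
         n_pos, " positive / ", n_neg, " negative frames); cannot train")
  }
  class_w <- length(all_labels) / (2 * c(n_neg, n_pos))   # (neg, pos)

  net <- phase_net(mcfg)
  layers <- net$layers()
  opt <- adam_state(lr = config$learning_rate)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_f1 = numeric(0))
  best <- list(f1 = -Inf, params = NULL, epoch = 0L)

  for (epoch in seq_len(config$epochs)) {
    sel <- with_seed(derive_seed(config$seed, paste0("epoch", epoch)), {
      keep <- epoch_subsample(bw$idx, config$windows_per_clip)
      keep[sample.int(length(keep))]
    })
    losses <- numeric(0)
    for (b in split_batches_idx(sel, config$batch_size)) {
      loss <- train_step(net, layers, opt, bw, b, mcfg, class_w)
      losses <- c(losses, loss)
    }
    vf1 <- if (!is.null(val)) pooled_val_f1(net, val, phase, config$threshold) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_f1 = vf1))
    if (verbose) {
      message(sprintf("[%s] epoch %d  loss %.4f  val F1 %.3f", phase, epoch,
                      mean(losses), vf1))
    }
    if (!is.null(val) && !is.na(vf1) && vf1 > best$f1) {
      best <- list(f1 = vf1, params = get_params(layers), epoch = epoch)
    }
  }
  if (!is.null(best$params)) set_params(layers, best$params)
  structure(list(net = net, phase = phase, config = config,
                 history = history, threshold = config$threshold,
                 best_epoch = if (is.null(best$params)) config$epochs else best$epoch,
                 class_weights = class_w),
            class = "phase_detector")
}

# subsample window indices per clip (seeded by caller)
epoch_subsample <- function(idx, per_clip) {
  if (!is.finite(per_clip)) return(seq_len(nrow(idx)))
  unlist(lapply(split(seq_len(nrow(idx)), idx$clip), function(rows) {
    if (length(rows) <= per_clip) rows else sort(sample(rows, per_clip))
  }), use.names = FALSE)
}

split_batches_idx <- function(sel, size) {
  if (!length(sel)) return(list())
  split(sel, ceiling(seq_along(sel) / size))
}

train_step <- function(net, layers, opt, bw, batch_rows, mcfg, class_w) {
  rows <- bw$idx[batch_rows, , drop = FALSE]
  # gather per source clip, then stack
  xs <- vector("list", nrow(rows)); labs <- vector("list", nrow(rows))
  masks <- vector("list", nrow(rows))
  for (k in seq_len(nrow(rows))) {
    ws <- bw$sets[[rows$clip[k]]]
    xs[[k]] <- gather_batch(ws, rows$win[k], mcfg$input_size)
    labs[[k]] <- sample_label(ws, rows$win[k])
    masks[[k]] <- if (ws$form == "segment") ws$masks[[rows$win[k]]] else TRUE
  }
  join5 <- function(lst) {
    d <- dim(lst[[1]])
    array(unlist(lst, use.names = FALSE), dim = c(d[1:4], length(lst)))
  }
  if (mcfg$variant == "BIDIRECTIONAL") {
    x <- list(m1 = join5(lapply(xs, `[[`, "m1")),
              m2 = join5(lapply(xs, `[[`, "m2")))
  } else {
    x <- join5(xs)
  }
  logits <- net$forward_logits(x, training = TRUE)
  if (mcfg$variant == "CONV_SA") {
    d <- dim(logits)                                   # T x nc x N
    lmat <- matrix(aperm(logits, c(2, 1, 3)), nrow = d[2])
    labels <- unlist(labs) + 1L
    mask <- unlist(masks)
    ce <- weighted_ce(lmat, labels, class_w, mask)
    dl <- array(ce$dlogits, dim = c(d[2], d[1], d[3]))
    net$backward(aperm(dl, c(2, 1, 3)))
  } else {
    labels <- unlist(labs) + 1L
    ce <- weighted_ce(logits, labels, class_w)
    net$backward(ce$dlogits)
  }
  adam_step(opt, layers)
  ce$loss
}

pooled_val_f1 <- function(net, val, phase, threshold) {
  pred <- integer(0); truth <- integer(0)
  for (i in seq_along(val$clips)) {
    clip <- val$clips[[i]]
    tr <- predict_video(net, clip, phase)
    pred <- c(pred, as.integer(tr$probs >= threshold))
    truth <- c(truth, label_frames(val$events[[i]], phase, clip_T(clip)))
  }
  m <- classification_metrics(confusion_counts(pred, truth))
  if (is.na(m$f1)) 0 else m$f1
}

# ---- phase_detector methods ------------------------------------------------

#' @export
print.phase_detector <- function(x, ...) {
  cat(sprintf("<phase_detector> phase %s, variant %s\n", x$phase,
              x$net$config$variant))
  cat(sprintf("  best epoch %d of %d; validation F1 %.3f; threshold %.2f\n",
              x$best_epoch, nrow(x$history),
              max(c(-Inf, x$history$val_f1), na.rm = TRUE), x$threshold))
  invisible(x)
}

#' @export
summary.phase_detector <- function(object, ...) {
  cat(sprintf("Phase detector for %s (%s variant)\n", object$phase,
              object$net$config$variant))
  cat(sprintf("  %d trainable parameters, %d weighted layers\n",
              count_parameters(object$net), n_weight_layers(object$net)))
  cat(sprintf("  class weights (neg, pos): %.3f, %.3f\n",
              object$class_weights[1], object$class_weights[2]))
  cat("Training history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' @export
coef.phase_detector <- function(object, ...) {
  get_params(object$net$layers())
}

#' @export
predict.phase_detector <- function(object, newdata,
                                   type = c("prob", "label", "interval"),
                                   ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "video_clip")
  clips <- if (single) list(newdata) else newdata
  out <- lapply(clips, function(clip) {
    tr <- predict_video(object$net, clip, object$phase)
    switch(type,
           prob = tr,
           label = as.integer(tr$probs >= object$threshold),
           interval = track_to_interval(tr, object$threshold,
                                        smoothing = "longest_run"))
  })
  if (single) out[[1]] else out
}

#' @export
plot.phase_detector <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = paste(x$phase, "loss"))
  graphics::plot(h$epoch, h$val_f1, type = "b", xlab = "epoch",
                 ylab = "validation F1", main = paste(x$phase, "val F1"),
                 ylim = c(0, 1))
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}

# ---- evaluation ------------------------------------------------------------

#' Evaluate a trained detector on labeled test clips
#'
#' Predicts every frame of every test clip, pools the frames into a single
#' confusion table at the decision threshold (per-clip averaging available as
#' a switch), and computes accuracy, precision, recall, F1 and AP.
#'
#' @param detector a fitted `phase_detector`.
#' @param test a `phase_dataset`.
#' @param pooled pool frames across clips (default) or average metrics per
#'   clip.
#' @return list with `metrics`, `counts`, `tracks` (per-clip prediction
#'   tracks), `pooled`.
#' @export
evaluate_detector <- function(detector, test, pooled = TRUE) {
  phase <- detector$phase
  tracks <- vector("list", length(test$clips))
  scores <- numeric(0); truth <- integer(0)
  per_clip <- vector("list", length(test$clips))
  for (i in seq_along(test$clips)) {
    clip <- test$clips[[i]]
    tr <- predict_video(detector$net, clip, phase)
    tracks[[i]] <- tr
    y <- label_frames(test$events[[i]], phase, clip_T(clip))
    scores <- c(scores, tr$probs); truth <- c(truth, y)
    per_clip[[i]] <- list(scores = tr$probs, truth = y)
  }
  pred <- as.integer(scores >= detector$threshold)
  if (pooled) {
    cc <- confusion_counts(pred, truth)
    m <- classification_metrics(cc)
    m$ap <- if (sum(truth) > 0) average_precision(scores, truth) else NA_real_
  } else {
    ms <- lapply(per_clip, function(pc) {
      mm <- classification_metrics(confusion_counts(
        as.integer(pc$scores >= detector$threshold), pc$truth))
      mm$ap <- if (sum(pc$truth) > 0) average_precision(pc$scores, pc$truth) else NA_real_
      mm
    })
    m <- list(accuracy = mean(sapply(ms, `[[`, "accuracy"), na.rm = TRUE),
              precision = mean(sapply(ms, `[[`, "precision"), na.rm = TRUE),
              recall = mean(sapply(ms, `[[`, "recall"), na.rm = TRUE),
              f1 = mean(sapply(ms, `[[`, "f1"), na.rm = TRUE),
              ap = mean(sapply(ms, `[[`, "ap"), na.rm = TRUE),
              undefined = character(0))
    cc <- confusion_counts(pred, truth)
  }
  list(metrics = m, counts = cc, tracks = tracks, pooled = pooled)
}

#' Repeat train + evaluate with fresh seeds and aggregate mean ± SD
#'
#' Runs the training/evaluation cycle `config$n_repeats` times with derived
#' seeds, pools test frames each time, and aggregates each metric as mean and
#' sample standard deviation (rounded to 3 decimals for presentation).
#'
#' @param train,val,test `phase_dataset` objects.
#' @param config a [train_config()].
#' @return class `"metrics_report"`: list with `phase`, `records` (one row
#'   per repeat), `aggregate`.
#' @export
repeat_experiment <- function(train, val, test, config, verbose = FALSE) {
  records <- NULL
  for (r in seq_len(config$n_repeats)) {
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, paste0("repeat", r))
    det <- train_phase_detector(train, val, cfg_r, verbose = verbose)
    ev <- evaluate_detector(det, test)
    records <- rbind(records, data.frame(
      repeat_id = r, accuracy = ev$metrics$accuracy,
      precision = ev$metrics$precision, recall = ev$metrics$recall,
      f1 = ev$metrics$f1, ap = ev$metrics$ap))
  }
  agg <- lapply(records[, -1, drop = FALSE], aggregate_metric)
  structure(list(phase = config$phase, records = records, aggregate = agg,
                 n_repeats = config$n_repeats),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> phase %s over %d repeat(s)\n", x$phase,
              x$n_repeats))
  for (m in names(x$aggregate)) {
    a <- x$aggregate[[m]]
    cat(sprintf("  %-9s %.3f ± %.3f\n", m, a$mean_rounded, a$sd_rounded))
  }
  invisible(x)
}

# ---- from prediction tracks back to intervals and durations ----------------

#' Binarize a prediction track into a phase interval
#'
#' Thresholds the per-frame probabilities and extracts one half-open
#' interval. `smoothing = "none"` returns the span from the first to the last
#' positive frame; `"longest_run"` the longest contiguous positive run;
#' `"close_gaps"` first fills negative gaps shorter than `k` frames, then
#' takes the longest run. An all-negative track yields the empty interval
#' `[0, 0)`.
#'
#' @param track a `prediction_track` (or plain probability vector).
#' @param threshold decision cutoff.
#' @param smoothing `"none"`, `"longest_run"`, or `"close_gaps"`.
#' @param k gap length for `"close_gaps"`.
#' @return list with `phase`, `start`, `end`, `empty`.
#' @export
track_to_interval <- function(track, threshold = 0.5,
                              smoothing = c("none", "longest_run", "close_gaps"),
                              k = 2) {
  smoothing <- match.arg(smoothing)
  probs <- if (inherits(track, "prediction_track")) track$probs else track
  phase <- if (inherits(track, "prediction_track")) track$phase else NA_character_
  pos <- probs >= threshold
  if (smoothing == "close_gaps") pos <- close_gaps(pos, k)
  if (!any(pos)) return(list(phase = phase, start = 0L, end = 0L, empty = TRUE))
  if (smoothing == "none") {
    idx <- which(pos)
    return(list(phase = phase, start = min(idx) - 1L, end = max(idx),
                empty = FALSE))
  }
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  list(phase = phase, start = starts[best] - 1L, end = ends[best],
       empty = FALSE)
}

close_gaps <- function(pos, k) {
  r <- rle(pos)
  if (length(r$values) > 2) {
    interior <- 2:(length(r$values) - 1)
    flip <- interior[!r$values[interior] & r$lengths[interior] < k]
    r$values[flip] <- TRUE
  }
  inverse.rle(r)
}

#' Durations from predicted phase intervals
#'
#' Converts each phase's predicted interval length to milliseconds and, when
#' ground-truth events are supplied, reports the signed delta to the true
#' (absolute) duration. Missing phases are reported as absent rows, not
#' fabricated.
#'
#' @param intervals named list of intervals (from [track_to_interval()]),
#'   names in [PHASE_NAMES].
#' @param fps frames per second.
#' @param truth optional [event_set()] with the ground-truth events.
#' @return data.frame with one row per phase: `pred_frames`, `pred_ms`,
#'   `empty`, and (with truth) `true_ms`, `delta_ms`.
#' @export
measure_from_predictions <- function(intervals, fps, truth = NULL) {
  rows <- lapply(PHASE_NAMES, function(ph) {
    iv <- intervals[[ph]]
    if (is.null(iv)) {
      return(data.frame(phase = ph, pred_frames = NA_integer_,
                        pred_ms = NA_real_, empty = NA))
    }
    nf <- iv$end - iv$start
    data.frame(phase = ph, pred_frames = nf,
               pred_ms = frames_to_duration(nf, fps), empty = isTRUE(iv$empty))
  })
  out <- do.call(rbind, rows)
  if (!is.null(truth)) {
    tf <- abs(phase_frame_counts(truth))
    out$true_ms <- frames_to_duration(unname(tf[out$phase]), fps)
    out$delta_ms <- out$pred_ms - out$true_ms
  }
  out
}
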