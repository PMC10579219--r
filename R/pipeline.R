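# End-to-end orchestration: generate -> train -> evaluate -> measure, with a
# reproducible experiment directory and a manifest tying outputs to the
# resolved config and root seed.

#' Per-phase best-variant preset
#'
#' The mapping of architectural variant to phase that performed best in the
#' source evaluation: CONV-SA for OPD, PDT, PTT and UESOD; DEFAULT for PRT;
#' BIDIRECTIONAL for LVCRT and LVC duration.
#' @export
paper_best_variants <- function() {
  c(OPD = "CONV_SA", PDT = "CONV_SA", PRT = "DEFAULT", PTT = "CONV_SA",
    LVCRT = "BIDIRECTIONAL", LVC_DURATION = "BIDIRECTIONAL", UESOD = "CONV_SA")
}

resolve_variants <- function(variant, phases) {
  if (identical(variant, "paper_best")) {
    return(paper_best_variants()[phases])
  }
  stats::setNames(rep(variant, length(phases)), phases)
}

#' Default experiment configuration
#'
#' A plain list a user can modify and pass to [run_experiment()]; the smoke
#' values (few clips, tiny widths, two epochs) exercise the whole pipeline in
#' minutes on a CPU.
#' @export
default_experiment_config <- function() {
  list(
    data = list(n_clips = 30, dir = NULL, height = 64, width = 64,
                noise_sd = 0.01),
    model = list(variant = "DEFAULT", stage_widths = c(2, 4, 8, 16),
                 window_L = 7, segment_W = 50, input_size = c(16, 16),
                 attention_heads = 4),
    train = list(epochs = 2, batch_size = 16, learning_rate = 1e-3,
                 windows_per_clip = 30, n_repeats = 1, threshold = 0.5),
    phases = PHASE_NAMES,
    seed = 1
  )
}

#' Run a full experiment: generate, train, evaluate, measure
#'
#' Executes the pipeline for every requested phase: dataset generation (or
#' reuse of an existing dataset directory), per-phase training of the mapped
#' variant, pooled test evaluation, and temporal-parameter measurement from
#' the predicted tracks. Every stage is seeded from the root seed through
#' named sub-seeds, so a rerun with the same config writes identical
#' annotation and metric CSVs.
#'
#' @param config list as in [default_experiment_config()]; `model$variant`
#'   may be a single variant or `"paper_best"`.
#' @param out_dir experiment directory to create.
#' @return class `"experiment_manifest"` (invisibly): per-phase run records
#'   with metric and checkpoint paths.
#' @export
run_experiment <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "generate"
  res <- tryCatch({
    data_dir <- config$data$dir
    if (is.null(data_dir)) {
      data_dir <- file.path(out_dir, "data")
      sc <- scene_config(height = config$data$height,
                         width = config$data$width,
                         noise_sd = config$data$noise_sd)
      generate_dataset(config$data$n_clips, sc, data_dir,
                       seed = derive_seed(config$seed, "data"))
    }
    man <- read_manifest(data_dir)
    train <- load_split(man, "train")
    val <- load_split(man, "val")
    test <- load_split(man, "test")
    fps <- train$clips[[1]]$fps

    variants <- resolve_variants(config$model$variant, config$phases)
    runs <- list()
    for (ph in config$phases) {
      stage <- paste0("train:", ph)
      mcfg <- model_config(
        variant = variants[[ph]],
        window_L = config$model$window_L,
        segment_W = config$model$segment_W,
        stage_widths = config$model$stage_widths,
        attention_heads = config$model$attention_heads,
        input_size = config$model$input_size
      )
      tcfg <- train_config(
        phase = ph, model = mcfg, epochs = config$train$epochs,
        batch_size = config$train$batch_size,
        learning_rate = config$train$learning_rate,
        threshold = config$train$threshold,
        n_repeats = config$train$n_repeats,
        windows_per_clip = config$train$windows_per_clip,
        seed = derive_seed(config$seed, paste0("train:", ph))
      )
      det <- train_phase_detector(train, val, tcfg)
      stage <- paste0("evaluate:", ph)
      ev <- evaluate_detector(det, test)
      metrics_path <- file.path(out_dir, paste0("metrics_", ph, ".csv"))
      write.csv(data.frame(
        phase = ph, variant = variants[[ph]],
        accuracy = ev$metrics$accuracy, precision = ev$metrics$precision,
        recall = ev$metrics$recall, f1 = ev$metrics$f1, ap = ev$metrics$ap
      ), metrics_path, row.names = FALSE, quote = FALSE)
      pred_path <- file.path(out_dir, paste0("predictions_", ph, ".csv"))
      pred_df <- do.call(rbind, lapply(ev$tracks, function(tr) {
        data.frame(clip_id = tr$clip_id, frame = seq_along(tr$probs) - 1L,
                   prob = tr$probs)
      }))
      write.csv(pred_df, pred_path, row.names = FALSE, quote = FALSE)
      ckpt_path <- file.path(out_dir, paste0("model_", ph, ".ckpt"))
      save_checkpoint(det, ckpt_path)

      stage <- paste0("measure:", ph)
      meas <- do.call(rbind, lapply(seq_along(test$clips), function(i) {
        iv <- track_to_interval(ev$tracks[[i]], det$threshold, "longest_run")
        ivs <- stats::setNames(list(iv), ph)
        df <- measure_from_predictions(ivs, fps, truth = test$events[[i]])
        df <- df[df$phase == ph, , drop = FALSE]
        df$clip_id <- test$clips[[i]]$clip_id
        df
      }))
      write.csv(meas, file.path(out_dir, paste0("durations_", ph, ".csv")),
                row.names = FALSE, quote = FALSE)

      runs[[ph]] <- list(phase = ph, variant = unname(variants[[ph]]),
                         seed = tcfg$seed,
                         checkpoint = basename(ckpt_path),
                         metrics = basename(metrics_path))
    }
    stage <- "manifest"
    cfg_path <- file.path(out_dir, "resolved_config.json")
    jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    manifest <- list(dataset_dir = data_dir,
                     dataset_hash = man$config_hash,
                     runs = runs, seed = config$seed,
                     config_hash = unname(tools::md5sum(cfg_path)),
                     version = as.character(utils::packageVersion("swallowphase")))
    jsonlite::write_json(manifest, file.path(out_dir, "experiment.json"),
                         auto_unbox = TRUE, digits = NA)
    structure(manifest, class = "experiment_manifest")
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Compare completed runs side by side
#'
#' Reads the per-phase metric files of two or more experiment directories and
#' builds a phase x (run, metric) comparison table. Runs over different
#' datasets (mismatched dataset hashes) are refused.
#'
#' @param run_dirs character vector of experiment directories (>= 2, or 1 to
#'   compare a run with itself).
#' @param labels column labels, default the directory basenames.
#' @return data.frame with one row per phase and accuracy/f1/ap columns per
#'   run.
#' @export
compare_variants <- function(run_dirs, labels = basename(run_dirs)) {
  mans <- lapply(run_dirs, function(d)
    jsonlite::fromJSON(file.path(d, "experiment.json")))
  hashes <- vapply(mans, `[[`, character(1), "dataset_hash")
  if (length(unique(hashes)) > 1) {
    stop("refusing to compare runs over different datasets (hashes: ",
         paste(unique(hashes), collapse = ", "), ")")
  }
  phases <- names(mans[[1]]$runs)
  out <- data.frame(phase = phases, stringsAsFactors = FALSE)
  for (j in seq_along(run_dirs)) {
    rows <- do.call(rbind, lapply(phases, function(ph) {
      read.csv(file.path(run_dirs[j], paste0("metrics_", ph, ".csv")))
    }))
    for (m in c("accuracy", "f1", "ap")) {
      out[[paste(labels[j], m, sep = ".")]] <- rows[[m]]
    }
  }
  out
}
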