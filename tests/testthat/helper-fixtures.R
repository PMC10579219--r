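# Shared fixtures: tiny configs and a small cached easy dataset so that the
# training tests do not regenerate clips per test.

tiny_model <- function(variant = "DEFAULT", L = 7, W = 10, widths = c(2, 4, 8, 16),
                       input = c(16, 16), heads = 4, seed = 1) {
  model_config(variant, window_L = L, segment_W = W, stage_widths = widths,
               attention_heads = heads, input_size = input, seed = seed)
}

# a valid event set with all orderings "typical"
ref_events <- function(clip_id = "ref", clip_length = 30L) {
  event_set(clip_id, 0, 10, 13, 15, 16, 22, 24, clip_length = clip_length)
}

# random valid event set (may have reversed PDT / LVCRT)
random_events <- function(id = "r") {
  opd <- sample(1:40, 1)
  pdt <- sample(-3:30, 1)
  prt <- sample(max(1, 1 - pdt):20, 1)        # keep ptt >= 0 and hyoid valid
  if (opd + pdt < 0) pdt <- -opd
  hyoid <- opd + pdt
  ues_closure <- hyoid + prt
  uesod <- sample(1:min(10, ues_closure), 1)
  lvcrt <- sample(max(-2, -hyoid):8, 1)
  lvcd <- sample(1:12, 1)
  lvc_onset <- hyoid + lvcrt
  event_set(id, 0, opd, hyoid, lvc_onset, ues_closure - uesod, ues_closure,
            lvc_onset + lvcd,
            clip_length = max(opd, hyoid, lvc_onset + lvcd, ues_closure) + 3L)
}

# small in-memory dataset of easy clips, cached across tests
.fixture_env <- new.env(parent = emptyenv())

easy_dataset <- function(n = 14, seed = 7) {
  key <- paste0("easy", n, "_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cfg <- scene_config(noise_sd = 0.01, negative_pdt_prob = 0,
                      negative_lvcrt_prob = 0)
  clips <- list(); events <- list()
  for (i in seq_len(n)) {
    id <- sprintf("easy%02d", i)
    ev <- sample_event_schedule(cfg, seed = seed * 1000 + i, clip_id = id)
    clips[[i]] <- render_clip(ev, cfg, seed = seed * 2000 + i)
    events[[i]] <- ev
  }
  ds <- list(
    train = phase_dataset(clips[1:(n - 4)], events[1:(n - 4)]),
    val = phase_dataset(clips[(n - 3):(n - 2)], events[(n - 3):(n - 2)]),
    test = phase_dataset(clips[(n - 1):n], events[(n - 1):n]),
    config = cfg
  )
  .fixture_env[[key]] <- ds
  ds
}

# one trained easy-set detector, cached (used by several training tests)
easy_detector <- function() {
  if (!is.null(.fixture_env$detector)) return(.fixture_env$detector)
  ds <- easy_dataset()
  tcfg <- train_config("PTT", tiny_model(), epochs = 3, batch_size = 16,
                       learning_rate = 1e-3, windows_per_clip = 25, seed = 11)
  .fixture_env$detector <- train_phase_detector(ds$train, ds$val, tcfg)
  .fixture_env$detector
}
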