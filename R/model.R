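# The ResNet3D-18 backbone and its three architectural variants:
#   DEFAULT       — center-labeled L-frame window -> one 2-class probability
#   BIDIRECTIONAL — two backbones over the forward / backward L-frame streams
#                   of a 2L-1 receptive field, features concatenated -> FC
#   CONV-SA       — temporal-stride-1 backbone over a W-frame segment, frame
#                   features + sinusoidal positional encoding -> multi-head
#                   self-attention -> shared per-frame FC -> W probabilities

#' Model configuration for a phase-localization network
#'
#' @param variant `"DEFAULT"`, `"BIDIRECTIONAL"`, or `"CONV_SA"`.
#' @param window_L input window length for DEFAULT/BIDIRECTIONAL (odd; the
#'   source configuration uses 7, with 13 also studied).
#' @param segment_W segment length for CONV_SA (50 in the source
#'   configuration).
#' @param stage_widths channel counts of the four residual stages; the
#'   full-size network is `c(64, 128, 256, 512)`, scaled-down widths such as
#'   `c(8, 16, 32, 64)` give desk-scale models with the same topology.
#' @param blocks_per_stage residual blocks per stage (2 = the 18-layer
#'   configuration).
#' @param attention_heads number of self-attention heads (CONV_SA; default 4);
#'   must divide `stage_widths[4]`.
#' @param n_classes output classes (2: not-phase / phase).
#' @param input_size spatial H, W the network consumes; clip frames are
#'   average-pooled to this size. The source setting is 224, desk-scale
#'   models use less.
#' @param temporal_stride_one keep temporal stride 1 in every stage so the
#'   feature sequence is as long as the input; forced `TRUE` for CONV_SA
#'   (spatial strides keep the standard schedule either way).
#' @param seed seed used for weight initialization.
#' @return an object of class `"model_config"`.
#' @export
model_config <- function(variant = c("DEFAULT", "BIDIRECTIONAL", "CONV_SA"),
                         window_L = 7, segment_W = 50,
                         stage_widths = c(64, 128, 256, 512),
                         blocks_per_stage = 2, attention_heads = 4,
                         n_classes = 2, input_size = c(64, 64),
                         temporal_stride_one = NULL, seed = 1) {
  variant <- match.arg(variant)
  if (length(stage_widths) != 4) stop("stage_widths must have length 4")
  if (is.null(temporal_stride_one)) temporal_stride_one <- variant == "CONV_SA"
  if (variant == "CONV_SA") {
    temporal_stride_one <- TRUE
    if (stage_widths[4] %% attention_heads != 0) {
      stop("attention_heads (", attention_heads,
           ") must divide the final stage width (", stage_widths[4], ")")
    }
  }
  if (variant != "CONV_SA" && window_L %% 2 == 0) {
    stop("window_L must be odd so the center frame is unambiguous")
  }
  if (length(input_size) == 1) input_size <- rep(input_size, 2)
  structure(list(
    variant = variant, window_L = as.integer(window_L),
    segment_W = as.integer(segment_W),
    stage_widths = as.integer(stage_widths),
    blocks_per_stage = as.integer(blocks_per_stage),
    attention_heads = as.integer(attention_heads),
    n_classes = as.integer(n_classes),
    input_size = as.integer(input_size),
    temporal_stride_one = temporal_stride_one,
    seed = as.integer(seed)
  ), class = "model_config")
}

#' Build the ResNet3D-18 backbone
#'
#' Stem convolution (3x7x7, spatial stride 2) followed by four stages of
#' residual blocks (two 3x3x3 convolutions with batch normalization and a
#' skip connection each; 1x1x1 convolution on the skip where the shape
#' changes). With `temporal_stride_one` all temporal strides are 1 so the
#' temporal axis is preserved end to end; otherwise stages 2-4 downsample
#' time and space by 2.
#'
#' @param config a [model_config()].
#' @return a backbone module (environment with `$forward` / `$backward`).
#' @export
build_backbone <- function(config) {
  w <- config$stage_widths
  bps <- config$blocks_per_stage
  ts <- if (config$temporal_stride_one) 1L else 2L
  layers <- list(
    nn_conv3d(3L, w[1], kernel = c(3, 7, 7), stride = c(1, 2, 2),
              pad = c(1, 3, 3)),
    nn_batchnorm(w[1]),
    nn_relu()
  )
  c_in <- w[1]
  for (s in 1:4) {
    for (b in seq_len(bps)) {
      stride <- if (s > 1 && b == 1) c(ts, 2L, 2L) else c(1L, 1L, 1L)
      layers <- c(layers, list(nn_resblock(c_in, w[s], stride)))
      c_in <- w[s]
    }
  }
  layers[[1]]$need_dx <- FALSE
  bk <- do.call(nn_sequential, layers)
  bk$out_width <- w[4]
  bk$temporal_stride_one <- config$temporal_stride_one
  bk
}

# per-frame FC over a [T, C, N] sequence -> [T, n_classes, N]
nn_framewise_fc <- function(d_in, d_out) {
  l <- new_layer("framewise_fc", c("W", "b"))
  l$fc <- nn_fc(d_in, d_out)
  l$param_names <- character(0)          # params live on the inner fc
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (training) l$shape <- d
    q <- aperm(x, c(2, 1, 3)); dim(q) <- c(d[2], d[1] * d[3])
    y <- l$fc$forward(q, training)
    dim(y) <- c(nrow(y), d[1], d[3])
    aperm(y, c(2, 1, 3))
  }
  l$backward <- function(dy) {
    d <- l$shape
    q <- aperm(dy, c(2, 1, 3)); dim(q) <- c(dim(dy)[2], d[1] * d[3])
    dx <- l$fc$backward(q)
    dim(dx) <- c(d[2], d[1], d[3])
    aperm(dx, c(2, 1, 3))
  }
  l
}

#' Assemble a phase-localization network
#'
#' Builds the variant named in the config, with weights initialized (He
#' scheme) under the config seed. Both BIDIRECTIONAL backbones are separate
#' models (no weight sharing) initialized identically from the seed.
#'
#' @param config a [model_config()].
#' @return an object of class `"phase_net"`.
#' @export
phase_net <- function(config) {
  net <- new.env(parent = emptyenv())
  net$config <- config
  nc <- config$n_classes
  w4 <- config$stage_widths[4]
  if (config$variant == "DEFAULT") {
    with_seed(config$seed, {
      net$backbone <- build_backbone(config)
      net$pool <- nn_gap()
      net$head <- nn_fc(w4, nc)
    })
    net$forward_logits <- function(x, training = FALSE) {
      net$head$forward(net$pool$forward(
        net$backbone$forward(x, training), training), training)
    }
    net$backward <- function(dlogits) {
      net$backbone$backward(net$pool$backward(net$head$backward(dlogits)))
    }
    net$modules <- function() list(net$backbone, net$pool, net$head)
  } else if (config$variant == "BIDIRECTIONAL") {
    with_seed(config$seed, net$m1 <- build_backbone(config))
    with_seed(config$seed, net$m2 <- build_backbone(config))
    with_seed(derive_seed(config$seed, "bidir_head"), {
      net$pool1 <- nn_gap(); net$pool2 <- nn_gap()
      net$head <- nn_fc(2L * w4, nc)
    })
    net$forward_logits <- function(x, training = FALSE) {
      f1 <- net$pool1$forward(net$m1$forward(x$m1, training), training)
      f2 <- net$pool2$forward(net$m2$forward(x$m2, training), training)
      net$feat_dim <- nrow(f1)
      net$head$forward(rbind(f1, f2), training)
    }
    net$backward <- function(dlogits) {
      dcat <- net$head$backward(dlogits)
      d1 <- dcat[seq_len(net$feat_dim), , drop = FALSE]
      d2 <- dcat[net$feat_dim + seq_len(net$feat_dim), , drop = FALSE]
      list(m1 = net$m1$backward(net$pool1$backward(d1)),
           m2 = net$m2$backward(net$pool2$backward(d2)))
    }
    net$modules <- function() list(net$m1, net$m2, net$pool1, net$pool2, net$head)
  } else { # CONV_SA
    with_seed(config$seed, {
      net$backbone <- build_backbone(config)
      net$pool <- nn_spatial_gap()
      net$posenc <- nn_posenc()
      net$attn <- nn_attention(w4, config$attention_heads)
      net$head <- nn_framewise_fc(w4, nc)
    })
    net$forward_logits <- function(x, training = FALSE) {
      f <- net$pool$forward(net$backbone$forward(x, training), training)
      f <- net$posenc$forward(f, training)
      f <- net$attn$forward(f, training)
      net$head$forward(f, training)                   # T x nc x N
    }
    net$backward <- function(dlogits) {
      df <- net$attn$backward(net$head$backward(dlogits))
      net$backbone$backward(net$pool$backward(net$posenc$backward(df)))
    }
    net$modules <- function() list(net$backbone, net$pool, net$attn, net$head)
  }
  net$layers <- function() {
    out <- list()
    for (m in net$modules()) out <- c(out, collect_layers(m))
    # framewise head keeps its fc nested
    if (config$variant == "CONV_SA") out <- c(out, list(net$head$fc))
    out
  }
  class(net) <- "phase_net"
  net
}

#' @export
print.phase_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<phase_net> %s  widths [%s]  %s\n", cfg$variant,
              paste(cfg$stage_widths, collapse = ","),
              if (cfg$variant == "CONV_SA") paste0("W=", cfg$segment_W)
              else paste0("L=", cfg$window_L)))
  cat(sprintf("  %d parameters in %d weighted layers\n",
              count_parameters(x), n_weight_layers(x)))
  invisible(x)
}

#' Total number of trainable parameters in a network
#' @param net a `phase_net`.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$layers(), function(l) {
    sum(vapply(l$param_names, function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
}

#' Weighted-layer count in the ResNet naming convention
#'
#' Counts the stem convolution, the residual-block convolutions and the final
#' FC layer(s); 1x1x1 downsampling convolutions on skip paths are excluded,
#' as in the standard "18-layer" naming.
#' @param net a `phase_net`.
#' @export
n_weight_layers <- function(net) {
  n <- 0L
  count_mod <- function(m, in_downsample = FALSE) {
    if (inherits(m, "nn_conv3d") && !in_downsample) n <<- n + 1L
    if (inherits(m, "nn_fc")) n <<- n + 1L
    if (!is.null(m$layers)) for (k in m$layers) count_mod(k, in_downsample)
    for (nm in c("conv1", "conv2")) if (!is.null(m[[nm]])) count_mod(m[[nm]])
    if (!is.null(m$downsample)) count_mod(m$downsample, in_downsample = TRUE)
    if (!is.null(m$bn1)) { count_mod(m$bn1); count_mod(m$bn2); }
    if (!is.null(m$fc)) count_mod(m$fc)
  }
  for (m in net$modules()) count_mod(m)
  n
}

# ---- forward wrappers (shape-checked, single or batched input) -------------

# ensure [T,H,W,C,N]; a 4D input becomes a batch of one
as_batch5 <- function(x) {
  d <- dim(x)
  if (length(d) == 4) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 5) stop("expected a T x H x W x C (x N) array")
  x
}

#' Forward pass of the DEFAULT variant on an L-frame window
#'
#' @param net a `phase_net` with variant DEFAULT.
#' @param window `L x H x W x C` array (or a 5D batch).
#' @return class-probability matrix, `n_classes x N` (columns sum to 1).
#' @export
forward_default <- function(net, window) {
  stopifnot(net$config$variant == "DEFAULT")
  x <- as_batch5(window)
  if (dim(x)[1] != net$config$window_L) {
    stop("window has ", dim(x)[1], " frames; model expects L = ",
         net$config$window_L)
  }
  softmax_cols(net$forward_logits(x, training = FALSE))
}

#' Forward pass of the BIDIRECTIONAL variant on a forward/backward pair
#'
#' @param net a `phase_net` with variant BIDIRECTIONAL.
#' @param m1_input,m2_input the first / last `L` frames of the 2L-1 span
#'   (each `L x H x W x C`, or 5D batches).
#' @return class-probability matrix `n_classes x N`.
#' @export
forward_bidirectional <- function(net, m1_input, m2_input) {
  stopifnot(net$config$variant == "BIDIRECTIONAL")
  x1 <- as_batch5(m1_input); x2 <- as_batch5(m2_input)
  L <- net$config$window_L
  if (dim(x1)[1] != L || dim(x2)[1] != L) {
    stop("both streams must have L = ", L, " frames")
  }
  softmax_cols(net$forward_logits(list(m1 = x1, m2 = x2), training = FALSE))
}

#' Forward pass of the CONV-SA variant on a W-frame segment
#'
#' @param net a `phase_net` with variant CONV_SA.
#' @param segment `W x H x W x C` array (or a 5D batch).
#' @return per-frame probability array `W x n_classes (x N)`; each frame's
#'   probabilities sum to 1.
#' @export
forward_conv_sa <- function(net, segment) {
  stopifnot(net$config$variant == "CONV_SA")
  x <- as_batch5(segment)
  if (dim(x)[1] != net$config$segment_W) {
    stop("segment has ", dim(x)[1], " frames; model expects W = ",
         net$config$segment_W)
  }
  logits <- net$forward_logits(x, training = FALSE)   # T x nc x N
  d <- dim(logits)
  out <- array(0, dim = d)
  for (n in seq_len(d[3])) {
    lmat <- logits[, , n, drop = FALSE]
    dim(lmat) <- d[1:2]
    out[, , n] <- t(softmax_cols(t(lmat)))
  }
  if (d[3] == 1L) { dim(out) <- d[1:2] }
  out
}

# ---- spatial pooling of frames to the model input size ---------------------

#' Average-pool clip frames to a target spatial size
#'
#' @param frames `T x H x W x C` array.
#' @param size target `c(h, w)`; must divide the source size.
#' @export
pool_frames <- function(frames, size) {
  d <- dim(frames)
  if (d[2] == size[1] && d[3] == size[2]) return(frames)
  fh <- d[2] / size[1]; fw <- d[3] / size[2]
  if (fh != round(fh) || fw != round(fw)) {
    stop("frame size ", d[2], "x", d[3], " is not a multiple of the model ",
         "input size ", size[1], "x", size[2])
  }
  a <- frames
  dim(a) <- c(d[1], fh, size[1], fw, size[2], d[4])
  a <- aperm(a, c(2, 4, 1, 3, 5, 6))
  dim(a) <- c(fh * fw, d[1] * size[1] * size[2] * d[4])
  y <- colMeans(a)
  dim(y) <- c(d[1], size[1], size[2], d[4])
  y
}

# gather a batch of window samples into the 5D layout at the model input size
gather_batch <- function(ws, idx, input_size) {
  stack5 <- function(lst) {
    d <- dim(lst[[1]])
    array(unlist(lst, use.names = FALSE), dim = c(d, length(lst)))
  }
  if (ws$form == "bidirectional") {
    fr <- lapply(idx, function(i) {
      p <- window_frames(ws, i)
      list(m1 = pool_frames(p$m1, input_size), m2 = pool_frames(p$m2, input_size))
    })
    list(m1 = stack5(lapply(fr, `[[`, "m1")),
         m2 = stack5(lapply(fr, `[[`, "m2")))
  } else if (ws$form == "segment") {
    stack5(lapply(idx, function(i)
      pool_frames(window_frames(ws, i)$frames, input_size)))
  } else {
    stack5(lapply(idx, function(i) pool_frames(window_frames(ws, i), input_size)))
  }
}

# pool a clip's frames to the model input size once, so window extraction
# slices the already-pooled stack
pool_clip <- function(clip, size) {
  d <- dim(clip$frames)
  if (d[2] == size[1] && d[3] == size[2]) return(clip)
  clip$frames <- pool_frames(clip$frames, size)
  clip
}

#' Per-frame phase probabilities for a whole clip
#'
#' Slides the variant's window/segment form over the clip with the replicate
#' edge policy and assembles one positive-class probability per frame; frames
#' are average-pooled to the model input size first.
#'
#' @param net a `phase_net` (or a fitted `phase_detector`).
#' @param clip a `video_clip`.
#' @param phase phase name recorded on the returned track.
#' @param batch_size windows per forward pass.
#' @return class `"prediction_track"`: list with `clip_id`, `phase`, `probs`
#'   (length-T vector in `[0,1]`), `model_id`.
#' @export
predict_video <- function(net, clip, phase = NA_character_, batch_size = 64) {
  if (inherits(net, "phase_detector")) net <- net$net
  cfg <- net$config
  clip <- pool_clip(clip, cfg$input_size)
  Tn <- clip_T(clip)
  dummy <- integer(Tn)
  probs <- numeric(Tn)
  if (cfg$variant == "CONV_SA") {
    ws <- make_segment_windows(clip, dummy, W = cfg$segment_W)
    for (i in seq_len(n_windows(ws))) {
      x <- gather_batch(ws, i, cfg$input_size)
      p <- forward_conv_sa(net, x)                    # W x nc
      keep <- ws$masks[[i]]
      probs[ws$starts[i] + which(keep)] <- p[which(keep), 2]
    }
  } else if (cfg$variant == "BIDIRECTIONAL") {
    ws <- make_bidirectional_pairs(clip, dummy, cfg$window_L, "replicate")
    for (b in split_batches(n_windows(ws), batch_size)) {
      x <- gather_batch(ws, b, cfg$input_size)
      p <- forward_bidirectional(net, x$m1, x$m2)
      probs[ws$centers[b] + 1L] <- p[2, ]
    }
  } else {
    ws <- make_center_windows(clip, dummy, cfg$window_L, "replicate")
    for (b in split_batches(n_windows(ws), batch_size)) {
      x <- gather_batch(ws, b, cfg$input_size)
      p <- forward_default(net, x)
      probs[ws$centers[b] + 1L] <- p[2, ]
    }
  }
  structure(list(clip_id = clip$clip_id, phase = phase, probs = probs,
                 model_id = paste0(cfg$variant, "_seed", cfg$seed)),
            class = "prediction_track")
}

split_batches <- function(n, size) {
  if (n == 0) return(list())
  split(seq_len(n), ceiling(seq_len(n) / size))
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the weights, the full model config
#' and the training seed. Loading into a mismatched config is refused.
#'
#' @param net a `phase_net` or fitted `phase_detector`.
#' @param path file path.
#' @export
save_checkpoint <- function(net, path) {
  extra <- NULL
  if (inherits(net, "phase_detector")) { extra <- net[c("phase", "history", "threshold")]; net <- net$net }
  saveRDS(list(config = unclass(net$config), params = get_params(net$layers()),
               detector = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param config optional [model_config()] the checkpoint must match.
#' @export
load_checkpoint <- function(path, config = NULL) {
  ck <- readRDS(path)
  ck_cfg <- do.call(model_config, ck$config[setdiff(names(ck$config), character(0))])
  if (!is.null(config) && !identical(unclass(config), unclass(ck_cfg))) {
    stop("checkpoint config does not match the requested config")
  }
  net <- phase_net(ck_cfg)
  set_params(net$layers(), ck$params)
  net
}
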