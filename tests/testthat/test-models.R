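# Architecture contracts of the backbone and the three variants, gradient
# correctness, determinism, and checkpointing.

test_that("model_config validates its invariants", {
  expect_error(model_config("DEFAULT", stage_widths = c(8, 16, 32)), "length 4")
  expect_error(model_config("DEFAULT", window_L = 6), "odd")
  expect_error(model_config("CONV_SA", stage_widths = c(2, 4, 8, 10),
                            attention_heads = 4), "divide")
  cfg <- model_config("CONV_SA", stage_widths = c(2, 4, 8, 16),
                      temporal_stride_one = FALSE)
  expect_true(cfg$temporal_stride_one)               # forced for CONV_SA
})

test_that("the 18-layer configuration has 18 weighted layers", {
  net <- phase_net(tiny_model())
  expect_equal(n_weight_layers(net), 18)             # stem + 16 block convs + FC
})

test_that("halving all stage widths shrinks the parameter count about 4-fold", {
  n_big <- count_parameters(phase_net(tiny_model(widths = c(8, 16, 32, 64))))
  n_small <- count_parameters(phase_net(tiny_model(widths = c(4, 8, 16, 32))))
  ratio <- n_big / n_small
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 4.5)
})

test_that("DEFAULT outputs a 2-class probability vector summing to 1", {
  net <- phase_net(tiny_model())
  set.seed(1)
  x <- array(runif(7 * 16 * 16 * 3), c(7, 16, 16, 3))
  p <- forward_default(net, x)
  expect_equal(dim(p), c(2L, 1L))
  expect_equal(colSums(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  # inference determinism
  expect_identical(p, forward_default(net, x))
  # zero input is finite (batch norm in inference mode)
  p0 <- forward_default(net, array(0, c(7, 16, 16, 3)))
  expect_true(all(is.finite(p0)))
  # shape error
  expect_error(forward_default(net, array(0, c(5, 16, 16, 3))), "expects L")
})

test_that("BIDIRECTIONAL concatenates two live feature streams", {
  net <- phase_net(tiny_model("BIDIRECTIONAL", widths = c(2, 4, 8, 16)))
  expect_equal(ncol(net$head$W), 2 * 16)             # 2 x final stage width
  set.seed(2)
  m1 <- array(runif(7 * 16 * 16 * 3), c(7, 16, 16, 3))
  m2 <- array(runif(7 * 16 * 16 * 3), c(7, 16, 16, 3))
  p <- forward_bidirectional(net, m1, m2)
  expect_equal(colSums(p), 1, tolerance = 1e-6)
  # no dead branch: zeroing M2's input must change the output
  p0 <- forward_bidirectional(net, m1, array(0, dim(m2)))
  expect_false(isTRUE(all.equal(p, p0)))
  expect_error(forward_bidirectional(net, m1, m2[1:5, , , , drop = FALSE]),
               "L = 7")
})

test_that("CONV-SA preserves temporal length for any segment length", {
  for (W in c(1, 7, 50)) {
    net <- phase_net(tiny_model("CONV_SA", W = W, widths = c(2, 2, 4, 8),
                                heads = 2))
    set.seed(3)
    x <- array(runif(W * 16 * 16 * 3), c(W, 16, 16, 3))
    p <- forward_conv_sa(net, x)
    if (W == 1) expect_equal(dim(p), c(1L, 2L)) else expect_equal(dim(p), c(W, 2L))
    expect_equal(rowSums(p), rep(1, W), tolerance = 1e-6)
  }
})

test_that("positional encoding breaks frame-permutation invariance", {
  W <- 8
  net <- phase_net(tiny_model("CONV_SA", W = W, widths = c(2, 2, 4, 8),
                              heads = 2))
  set.seed(4)
  x <- array(runif(W * 16 * 16 * 3), c(W, 16, 16, 3))
  perm <- c(2, 1, 4, 3, 6, 5, 8, 7)
  p1 <- forward_conv_sa(net, x)
  p2 <- forward_conv_sa(net, x[perm, , , , drop = FALSE])
  # probabilities of the same source frame differ once reordered
  expect_false(isTRUE(all.equal(p1[perm, ], p2, tolerance = 1e-8)))
})

test_that("sinusoidal positional encoding has the expected structure", {
  pe <- positional_encoding(20, 8)
  expect_equal(pe[1, ], rep(c(0, 1), 4))             # sin(0), cos(0) pairs
  expect_equal(pe[5, 1], sin(4), tolerance = 1e-12)
  expect_true(all(abs(pe) <= 1))
})

test_that("gradients agree with finite differences through a whole network", {
  cfg <- tiny_model("DEFAULT", L = 5, widths = c(2, 3, 4, 4), seed = 7)
  net <- phase_net(cfg)
  set.seed(1)
  x <- array(runif(5 * 16 * 16 * 3 * 2), c(5, 16, 16, 3, 2))
  labels <- c(1L, 2L)
  loss_of <- function() {
    ce <- swallowphase:::weighted_ce(net$forward_logits(x, training = TRUE),
                                     labels, c(1, 1.5))
    ce
  }
  ce <- loss_of()
  net$backward(ce$dlogits)
  layers <- net$layers()
  set.seed(2)
  checked <- 0
  for (li in unique(round(seq(1, length(layers), length.out = 6)))) {
    lay <- layers[[li]]
    for (p in lay$param_names) {
      g <- lay[[paste0("d", p)]]
      if (is.null(g)) next
      i <- sample(length(g), 1)
      eps <- 1e-5
      old <- lay[[p]]
      v <- old; v[i] <- v[i] + eps; lay[[p]] <- v
      l1 <- loss_of()$loss
      v[i] <- v[i] - 2 * eps; lay[[p]] <- v
      l0 <- loss_of()$loss
      lay[[p]] <- old
      num <- (l1 - l0) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-3)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 8)
})

test_that("attention backward matches finite differences", {
  set.seed(5)
  att <- swallowphase:::nn_attention(8, 2)
  x <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  R <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  y <- att$forward(x, training = TRUE)
  dx <- att$backward(R)
  eps <- 1e-6
  for (k in sample(length(x), 5)) {
    x2 <- x; x2[k] <- x2[k] + eps
    num <- sum((att$forward(x2, training = TRUE) - y) * R) / eps
    expect_equal(dx[k], num, tolerance = 1e-3)
  }
  for (k in sample(length(att$Wq), 3)) {
    old <- att$Wq
    W2 <- old; W2[k] <- W2[k] + eps; att$Wq <- W2
    num <- sum((att$forward(x, training = TRUE) - y) * R) / eps
    att$Wq <- old
    expect_equal(att$dWq[k], num, tolerance = 1e-3)
  }
})

test_that("predict_video yields one probability per frame for all variants", {
  ds <- easy_dataset()
  clip <- ds$test$clips[[1]]
  for (variant in c("DEFAULT", "BIDIRECTIONAL", "CONV_SA")) {
    net <- phase_net(tiny_model(variant, widths = c(2, 2, 4, 8), heads = 2,
                                W = 20))
    tr <- predict_video(net, clip, "PTT")
    expect_length(tr$probs, dim(clip$frames)[1])
    expect_true(all(tr$probs >= 0 & tr$probs <= 1))
  }
})

test_that("an untrained net on a constant clip gives a near-constant track", {
  net <- phase_net(tiny_model())
  fr <- array(0.5, dim = c(24, 16, 16, 3))
  clip <- structure(list(frames = fr, fps = 15, clip_id = "const"),
                    class = "video_clip")
  tr <- predict_video(net, clip, "PTT")
  # interior windows are identical; only edge-replicated windows may differ
  expect_lt(diff(range(tr$probs[4:21])), 1e-10)
})

test_that("checkpoints round trip and refuse a mismatched config", {
  cfg <- tiny_model(seed = 3)
  net <- phase_net(cfg)
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  set.seed(6)
  x <- array(runif(7 * 16 * 16 * 3), c(7, 16, 16, 3))
  expect_identical(forward_default(net, x), forward_default(net2, x))
  other <- tiny_model(widths = c(4, 8, 16, 32))
  expect_error(load_checkpoint(path, other), "does not match")
})

test_that("pool_frames averages blocks and validates divisibility", {
  fr <- array(seq_len(4 * 4 * 4 * 1) / 64, c(4, 4, 4, 1))
  p <- pool_frames(fr, c(2, 2))
  expect_equal(dim(p), c(4, 2, 2, 1))
  expect_equal(p[1, 1, 1, 1], mean(fr[1, 1:2, 1:2, 1]))
  expect_error(pool_frames(fr, c(3, 3)), "not a multiple")
})
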