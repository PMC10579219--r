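# Minimal neural-network engine: layers as environments holding parameters,
# cached activations and gradients, with hand-written backpropagation. The 3D
# convolutions run through the compiled im2col kernels; everything else is
# base R matrix code. Activation layout throughout: [T, H, W, C, N].

new_layer <- function(type, param_names = character(0)) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$param_names <- param_names
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

# ---- conv3d ----------------------------------------------------------------

nn_conv3d <- function(c_in, c_out, kernel = c(3, 3, 3), stride = c(1, 1, 1),
                      pad = (kernel - 1) %/% 2, bias = TRUE) {
  l <- new_layer("conv3d", c("W", "b"))
  l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$W <- he_init(c(kernel, c_in, c_out), fan_in = prod(kernel) * c_in)
  l$b <- numeric(c_out)
  l$use_bias <- bias
  l$need_dx <- TRUE   # FALSE for the stem, whose input has no upstream layer
  l$forward <- function(x, training = FALSE) {
    if (training) l$x <- x
    .conv3d_fwd(x, l$W, l$b, l$stride, l$pad)
  }
  l$backward <- function(dy) {
    r <- .conv3d_bwd(l$x, l$W, dy, l$stride, l$pad, l$need_dx)
    l$dW <- r$dw
    l$db <- if (l$use_bias) r$db else numeric(length(l$b))
    if (l$need_dx) r$dx else NULL
  }
  l
}

# ---- batch norm over channels of [T,H,W,C,N] -------------------------------

nn_batchnorm <- function(c_ch, eps = 1e-5, momentum = 0.1) {
  l <- new_layer("batchnorm", c("gamma", "beta"))
  l$gamma <- rep(1, c_ch); l$beta <- rep(0, c_ch)
  l$run_mean <- rep(0, c_ch); l$run_var <- rep(1, c_ch)
  l$eps <- eps; l$momentum <- momentum
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    C <- d[4]; S <- prod(d[1:3]); N <- d[5]
    q <- x; dim(q) <- c(S, C, N)
    if (training) {
      mu <- rowMeans(colMeans(q))                     # per-channel mean
      q2 <- colMeans(q * q)
      v <- rowMeans(q2) - mu^2
      v <- pmax(v, 0)
      l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
      m <- S * N
      l$run_var <- (1 - l$momentum) * l$run_var +
        l$momentum * v * (if (m > 1) m / (m - 1) else 1)
    } else {
      mu <- l$run_mean; v <- l$run_var
    }
    invstd <- 1 / sqrt(v + l$eps)
    xhat <- sweep(sweep(q, 2, mu, "-"), 2, invstd, "*")
    y <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
    if (training) { l$xhat <- xhat; l$invstd <- invstd; l$shape <- d }
    dim(y) <- d
    y
  }
  l$backward <- function(dy) {
    d <- l$shape
    C <- d[4]; S <- prod(d[1:3]); N <- d[5]; m <- S * N
    dq <- dy; dim(dq) <- c(S, C, N)
    sum_c <- function(a) rowSums(colSums(a))          # sum over S and N per C
    l$dgamma <- sum_c(dq * l$xhat)
    l$dbeta <- sum_c(dq)
    # dx = invstd/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    g <- l$gamma
    dxhat <- sweep(dq, 2, g, "*")
    s1 <- sum_c(dxhat)
    s2 <- sum_c(dxhat * l$xhat)
    dx <- sweep(dxhat, 2, s1 / m, "-") -
      sweep(l$xhat, 2, s2 / m, "*")
    dx <- sweep(dx, 2, l$invstd, "*")
    dim(dx) <- d
    dx
  }
  l
}

# ---- relu ------------------------------------------------------------------

nn_relu <- function() {
  l <- new_layer("relu")
  l$forward <- function(x, training = FALSE) {
    if (training) l$mask <- x > 0
    x * (x > 0)
  }
  l$backward <- function(dy) dy * l$mask
  l
}

# ---- pooling ---------------------------------------------------------------

# global average pool over T,H,W -> C x N matrix
nn_gap <- function() {
  l <- new_layer("gap")
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (training) l$shape <- d
    q <- x; dim(q) <- c(prod(d[1:3]), d[4], d[5])
    colMeans(q)                                       # C x N
  }
  l$backward <- function(dy) {
    d <- l$shape; S <- prod(d[1:3])
    dx <- array(rep(dy, each = S) / S, dim = d)
    dx
  }
  l
}

# spatial-only average pool: [T,H,W,C,N] -> [T,C,N] feature sequence
nn_spatial_gap <- function() {
  l <- new_layer("spatial_gap")
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (training) l$shape <- d
    # mean over H,W: permute so (H,W) lead, then column means
    q <- aperm(x, c(2, 3, 1, 4, 5))
    dim(q) <- c(d[2] * d[3], d[1] * d[4] * d[5])
    y <- colMeans(q)
    dim(y) <- c(d[1], d[4], d[5])                     # T x C x N
    y
  }
  l$backward <- function(dy) {
    d <- l$shape; S <- d[2] * d[3]
    dq <- matrix(rep(as.numeric(dy), each = S) / S, nrow = S)
    dim(dq) <- c(d[2], d[3], d[1], d[4], d[5])
    aperm(dq, c(3, 1, 2, 4, 5))
  }
  l
}

# ---- fully connected (input d_in x N matrix) -------------------------------

nn_fc <- function(d_in, d_out) {
  l <- new_layer("fc", c("W", "b"))
  l$W <- matrix(rnorm(d_out * d_in, 0, sqrt(2 / d_in)), d_out, d_in)
  l$b <- numeric(d_out)
  l$forward <- function(x, training = FALSE) {
    if (training) l$x <- x
    l$W %*% x + l$b
  }
  l$backward <- function(dy) {
    l$dW <- dy %*% t(l$x)
    l$db <- rowSums(dy)
    t(l$W) %*% dy
  }
  l
}

# ---- sequential container --------------------------------------------------

nn_sequential <- function(...) {
  l <- new_layer("sequential")
  l$layers <- list(...)
  l$forward <- function(x, training = FALSE) {
    for (m in l$layers) x <- m$forward(x, training)
    x
  }
  l$backward <- function(dy) {
    for (m in rev(l$layers)) dy <- m$backward(dy)
    dy
  }
  l
}

# ---- residual block --------------------------------------------------------

# conv(3x3x3)-BN-ReLU-conv(3x3x3)-BN, plus skip (1x1x1 conv + BN when the
# shape changes), then ReLU
nn_resblock <- function(c_in, c_out, stride = c(1, 1, 1)) {
  l <- new_layer("resblock")
  l$conv1 <- nn_conv3d(c_in, c_out, stride = stride)
  l$bn1 <- nn_batchnorm(c_out)
  l$relu1 <- nn_relu()
  l$conv2 <- nn_conv3d(c_out, c_out)
  l$bn2 <- nn_batchnorm(c_out)
  l$downsample <- if (c_in != c_out || any(stride != 1L)) {
    nn_sequential(nn_conv3d(c_in, c_out, kernel = c(1, 1, 1), stride = stride,
                            pad = c(0, 0, 0)),
                  nn_batchnorm(c_out))
  } else NULL
  l$relu_out <- nn_relu()
  l$forward <- function(x, training = FALSE) {
    y <- l$bn2$forward(l$conv2$forward(
      l$relu1$forward(l$bn1$forward(l$conv1$forward(x, training), training), training),
      training), training)
    skip <- if (is.null(l$downsample)) x else l$downsample$forward(x, training)
    l$relu_out$forward(y + skip, training)
  }
  l$backward <- function(dy) {
    dy <- l$relu_out$backward(dy)
    dskip <- if (is.null(l$downsample)) dy else l$downsample$backward(dy)
    dx <- l$conv1$backward(l$bn1$backward(l$relu1$backward(
      l$conv2$backward(l$bn2$backward(dy)))))
    dx + dskip
  }
  l
}

# ---- sinusoidal positional encoding + multi-head self-attention ------------

#' Sinusoidal positional encoding matrix
#'
#' Transformer-style encoding of the frame index: position `pos` (0-based)
#' and feature `2i`/`2i+1` get `sin`/`cos` of `pos / 10000^(2i/d)`.
#' @param n_pos number of positions (frames).
#' @param d feature dimension.
#' @return an `n_pos x d` matrix.
#' @export
positional_encoding <- function(n_pos, d) {
  pos <- seq_len(n_pos) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 1 / 10000^((i %/% 2 * 2) / d))
  pe <- matrix(0, n_pos, d)
  even <- i %% 2 == 0
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

# adds the positional encoding to a [T, C, N] feature sequence
nn_posenc <- function() {
  l <- new_layer("posenc")
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    pe <- positional_encoding(d[1], d[2])
    x + array(pe, dim = d)                            # recycled over N
  }
  l$backward <- function(dy) dy
  l
}

# multi-head self-attention over a [T, C, N] feature sequence (per sample)
nn_attention <- function(d_model, n_heads) {
  if (d_model %% n_heads != 0) {
    stop("attention feature width ", d_model,
         " is not divisible by n_heads = ", n_heads)
  }
  l <- new_layer("attention", c("Wq", "Wk", "Wv", "Wo"))
  s <- sqrt(1 / d_model)
  l$Wq <- matrix(rnorm(d_model^2, 0, s), d_model, d_model)
  l$Wk <- matrix(rnorm(d_model^2, 0, s), d_model, d_model)
  l$Wv <- matrix(rnorm(d_model^2, 0, s), d_model, d_model)
  l$Wo <- matrix(rnorm(d_model^2, 0, s), d_model, d_model)
  l$h <- n_heads; l$dk <- d_model %/% n_heads
  softmax_rows <- function(m) {
    e <- exp(m - apply(m, 1, max))
    e / rowSums(e)
  }
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)                                       # T x C x N
    y <- array(0, dim = d)
    if (training) { l$cache <- vector("list", d[3]); l$shape <- d }
    for (n in seq_len(d[3])) {
      X <- x[, , n, drop = FALSE]; dim(X) <- d[1:2]   # T x C
      Q <- X %*% l$Wq; K <- X %*% l$Wk; V <- X %*% l$Wv
      O <- matrix(0, d[1], d[2])
      A_list <- vector("list", l$h)
      for (hh in seq_len(l$h)) {
        cols <- ((hh - 1) * l$dk + 1):(hh * l$dk)
        A <- softmax_rows(Q[, cols, drop = FALSE] %*%
                            t(K[, cols, drop = FALSE]) / sqrt(l$dk))
        O[, cols] <- A %*% V[, cols, drop = FALSE]
        A_list[[hh]] <- A
      }
      y[, , n] <- O %*% l$Wo
      if (training) l$cache[[n]] <- list(X = X, Q = Q, K = K, V = V, O = O,
                                         A = A_list)
    }
    y
  }
  l$backward <- function(dy) {
    d <- l$shape
    dx <- array(0, dim = d)
    dWq <- 0 * l$Wq; dWk <- 0 * l$Wk; dWv <- 0 * l$Wv; dWo <- 0 * l$Wo
    for (n in seq_len(d[3])) {
      cc <- l$cache[[n]]
      dY <- dy[, , n, drop = FALSE]; dim(dY) <- d[1:2]
      dWo <- dWo + t(cc$O) %*% dY
      dO <- dY %*% t(l$Wo)
      dQ <- matrix(0, d[1], d[2]); dK <- dQ; dV <- dQ
      for (hh in seq_len(l$h)) {
        cols <- ((hh - 1) * l$dk + 1):(hh * l$dk)
        A <- cc$A[[hh]]
        Vh <- cc$V[, cols, drop = FALSE]
        dOh <- dO[, cols, drop = FALSE]
        dV[, cols] <- t(A) %*% dOh
        dA <- dOh %*% t(Vh)
        # softmax backward, row-wise
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(l$dk)
        dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE]
        dK[, cols] <- t(dS) %*% cc$Q[, cols, drop = FALSE]
      }
      dWq <- dWq + t(cc$X) %*% dQ
      dWk <- dWk + t(cc$X) %*% dK
      dWv <- dWv + t(cc$X) %*% dV
      dx[, , n] <- dQ %*% t(l$Wq) + dK %*% t(l$Wk) + dV %*% t(l$Wv)
    }
    l$dWq <- dWq; l$dWk <- dWk; l$dWv <- dWv; l$dWo <- dWo
    dx
  }
  l
}

# ---- parameter traversal and optimizer -------------------------------------

# depth-first collection of all parameterised layer environments
collect_layers <- function(m) {
  out <- list()
  if (length(m$param_names)) out <- list(m)
  kids <- list()
  if (!is.null(m$layers)) kids <- m$layers
  for (nm in c("conv1", "bn1", "conv2", "bn2", "downsample")) {
    if (!is.null(m[[nm]])) kids <- c(kids, list(m[[nm]]))
  }
  for (k in kids) out <- c(out, collect_layers(k))
  out
}

get_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    lay <- layers[[i]]
    for (p in lay$param_names) out[[paste0("L", i, ".", p)]] <- lay[[p]]
    for (p in c("run_mean", "run_var")) {
      if (!is.null(lay[[p]])) out[[paste0("L", i, ".", p)]] <- lay[[p]]
    }
  }
  out
}

set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    lay <- layers[[i]]
    for (p in lay$param_names) lay[[p]] <- params[[paste0("L", i, ".", p)]]
    for (p in c("run_mean", "run_var")) {
      key <- paste0("L", i, ".", p)
      if (!is.null(params[[key]])) lay[[p]] <- params[[key]]
    }
  }
  invisible(layers)
}

adam_state <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$b1 <- beta1; e$b2 <- beta2; e$eps <- eps
  e$t <- 0; e$m <- list(); e$v <- list()
  e
}

adam_step <- function(opt, layers) {
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(layers)) {
    lay <- layers[[i]]
    for (p in lay$param_names) {
      g <- lay[[paste0("d", p)]]
      if (is.null(g)) next
      key <- paste0("L", i, ".", p)
      if (is.null(opt$m[[key]])) { opt$m[[key]] <- 0 * g; opt$v[[key]] <- 0 * g }
      opt$m[[key]] <- opt$b1 * opt$m[[key]] + (1 - opt$b1) * g
      opt$v[[key]] <- opt$b2 * opt$v[[key]] + (1 - opt$b2) * g^2
      lay[[p]] <- lay[[p]] - opt$lr * (opt$m[[key]] / bc1) /
        (sqrt(opt$v[[key]] / bc2) + opt$eps)
    }
  }
  invisible(opt)
}

# ---- softmax + weighted cross-entropy --------------------------------------

# logits: n_classes x N; labels in 1..n_classes; class_w length n_classes
softmax_cols <- function(logits) {
  e <- exp(sweep(logits, 2, apply(logits, 2, max), "-"))
  sweep(e, 2, colSums(e), "/")
}

weighted_ce <- function(logits, labels, class_w = NULL, sample_mask = NULL) {
  nc <- nrow(logits); N <- ncol(logits)
  if (is.null(class_w)) class_w <- rep(1, nc)
  if (is.null(sample_mask)) sample_mask <- rep(TRUE, N)
  p <- softmax_cols(logits)
  w <- class_w[labels] * sample_mask
  wsum <- sum(w)
  if (wsum == 0) return(list(loss = 0, dlogits = 0 * logits, probs = p))
  py <- p[cbind(labels, seq_len(N))]
  loss <- sum(w * (-log(pmax(py, 1e-12)))) / wsum
  onehot <- matrix(0, nc, N)
  onehot[cbind(labels, seq_len(N))] <- 1
  dlogits <- sweep(p - onehot, 2, w / wsum, "*")
  list(loss = loss, dlogits = dlogits, probs = p)
}
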