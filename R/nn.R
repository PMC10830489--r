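# Minimal seeded neural-network engine backing the tile classifier and the
# EBL regressor. Feature maps are arrays with layout (H, W, B, C); dense
# activations are (B, D) matrices. 3x3 same-padding convolutions are computed
# as nine shifted matrix multiplies, which keeps everything in BLAS.
#
# Layer constructors return lists with $type, $params, and training state.
# seq_forward / seq_backward run a list of layers; adam_step updates every
# parameter. All randomness goes through R's RNG, so fits are reproducible
# under a fixed seed.

conv_offsets <- expand.grid(di = -1:1, dj = -1:1)

# weights stored im2col-style: one (9 * c_in) x c_out matrix, kernel-offset
# blocks stacked row-wise, so the whole convolution is a single matmul
nn_conv3 <- function(c_in, c_out) {
  list(type = "conv3", c_in = c_in, c_out = c_out,
       params = list(W = matrix(rnorm(9 * c_in * c_out, sd = sqrt(2 / (9 * c_in))),
                                9 * c_in, c_out),
                     b = numeric(c_out)))
}

nn_dense <- function(d_in, d_out) {
  list(type = "dense", d_in = d_in, d_out = d_out,
       params = list(W = matrix(rnorm(d_in * d_out, sd = sqrt(2 / d_in)),
                                d_in, d_out),
                     b = numeric(d_out)))
}

nn_act <- function(kind = c("relu", "swish", "linear")) {
  list(type = "act", kind = match.arg(kind), params = list())
}

nn_pool2 <- function() list(type = "pool2", params = list())
nn_gpool <- function() list(type = "gpool", params = list())

shift4 <- function(x, di, dj) {
  d <- dim(x)
  out <- array(0, d)
  rd <- max(1, 1 - di):min(d[1], d[1] - di)
  cd <- max(1, 1 - dj):min(d[2], d[2] - dj)
  out[rd, cd, , ] <- x[rd + di, cd + dj, , , drop = FALSE]
  out
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv3 = {
      d <- dim(x)  # (H, W, B, Cin)
      n <- d[1] * d[2] * d[3]
      ci <- layer$c_in
      cols <- matrix(0, n, 9 * ci)
      for (k in 1:9) {
        xs <- shift4(x, conv_offsets$di[k], conv_offsets$dj[k])
        dim(xs) <- c(n, ci)
        cols[, ((k - 1) * ci + 1):(k * ci)] <- xs
      }
      y2 <- cols %*% layer$params$W
      y2 <- y2 + rep(layer$params$b, each = n)
      layer$cache <- list(dim = d, cols = cols)
      dim(y2) <- c(d[1], d[2], d[3], layer$c_out)
      list(layer = layer, out = y2)
    },
    dense = {
      layer$cache <- x
      list(layer = layer,
           out = sweep(x %*% layer$params$W, 2, layer$params$b, "+"))
    },
    act = {
      layer$cache <- x
      out <- switch(layer$kind,
        relu = pmax(x, 0),
        swish = x / (1 + exp(-x)),
        linear = x)
      list(layer = layer, out = out)
    },
    pool2 = {
      d <- dim(x)
      o <- seq(1, d[1], 2); e <- o + 1
      oc <- seq(1, d[2], 2); ec <- oc + 1
      out <- (x[o, oc, , , drop = FALSE] + x[e, oc, , , drop = FALSE] +
              x[o, ec, , , drop = FALSE] + x[e, ec, , , drop = FALSE]) / 4
      layer$cache <- d
      list(layer = layer, out = out)
    },
    gpool = {
      d <- dim(x)
      m <- x; dim(m) <- c(d[1] * d[2], d[3] * d[4])
      out <- matrix(colSums(m) / (d[1] * d[2]), d[3], d[4])
      layer$cache <- d
      list(layer = layer, out = out)
    })
}

layer_backward <- function(layer, dy, need_dx = TRUE) {
  switch(layer$type,
    conv3 = {
      d <- layer$cache$dim
      n <- d[1] * d[2] * d[3]
      ci <- layer$c_in
      dy2 <- dy; dim(dy2) <- c(n, layer$c_out)
      layer$grads <- list(W = crossprod(layer$cache$cols, dy2),
                          b = colSums(dy2))
      dx <- NULL
      if (need_dx) {
        dcols <- tcrossprod(dy2, layer$params$W)
        dx <- array(0, d)
        for (k in 1:9) {
          dxs <- dcols[, ((k - 1) * ci + 1):(k * ci), drop = FALSE]
          dim(dxs) <- c(d[1], d[2], d[3], ci)
          dx <- dx + shift4(dxs, -conv_offsets$di[k], -conv_offsets$dj[k])
        }
      }
      list(layer = layer, dx = dx)
    },
    dense = {
      layer$grads <- list(W = crossprod(layer$cache, dy), b = colSums(dy))
      list(layer = layer, dx = tcrossprod(dy, layer$params$W))
    },
    act = {
      x <- layer$cache
      dx <- switch(layer$kind,
        relu = dy * (x > 0),
        swish = {
          s <- 1 / (1 + exp(-x))
          dy * (s * (1 + x * (1 - s)))
        },
        linear = dy)
      list(layer = layer, dx = dx)
    },
    pool2 = {
      d <- layer$cache
      dx <- array(0, d)
      o <- seq(1, d[1], 2); e <- o + 1
      oc <- seq(1, d[2], 2); ec <- oc + 1
      q <- dy / 4
      dx[o, oc, , ] <- q; dx[e, oc, , ] <- q
      dx[o, ec, , ] <- q; dx[e, ec, , ] <- q
      list(layer = layer, dx = dx)
    },
    gpool = {
      d <- layer$cache
      dx <- array(rep(as.vector(dy) / (d[1] * d[2]), each = d[1] * d[2]), d)
      list(layer = layer, dx = dx)
    })
}

seq_forward <- function(layers, x) {
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x)
    layers[[i]] <- r$layer
    x <- r$out
  }
  list(layers = layers, out = x)
}

seq_backward <- function(layers, dy, need_input_grad = FALSE) {
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], dy, need_dx = need_input_grad || i > 1)
    layers[[i]] <- r$layer
    dy <- r$dx
  }
  list(layers = layers, dx = dy)
}

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    if (length(L$params) == 0) next
    if (is.null(L$m)) {
      L$m <- lapply(L$params, function(p) p * 0)
      L$v <- lapply(L$params, function(p) p * 0)
    }
    for (nm in names(L$params)) {
      g <- L$grads[[nm]]
      L$m[[nm]] <- beta1 * L$m[[nm]] + (1 - beta1) * g
      L$v[[nm]] <- beta2 * L$v[[nm]] + (1 - beta2) * g^2
      mhat <- L$m[[nm]] / (1 - beta1^t)
      vhat <- L$v[[nm]] / (1 - beta2^t)
      L$params[[nm]] <- L$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    layers[[i]] <- L
  }
  layers
}

# global gradient-norm clipping across a set of layer stacks; returns the
# stacks with gradients rescaled so their joint L2 norm is at most max_norm
clip_grad_norm <- function(stacks, max_norm = 5) {
  total <- 0
  for (layers in stacks) {
    for (L in layers) {
      if (!is.null(L$grads)) {
        total <- total + sum(vapply(L$grads, function(g) sum(g^2), 0))
      }
    }
  }
  total <- sqrt(total)
  if (total <= max_norm) return(stacks)
  sc <- max_norm / total
  lapply(stacks, function(layers) {
    lapply(layers, function(L) {
      if (!is.null(L$grads)) L$grads <- lapply(L$grads, function(g) g * sc)
      L
    })
  })
}

strip_training_state <- function(layers) {
  lapply(layers, function(L) { L$cache <- L$grads <- L$m <- L$v <- NULL; L })
}

n_params <- function(layers) {
  sum(vapply(layers, function(L) sum(vapply(L$params, length, 0L)), 0))
}

# ---- losses -----------------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy for classification; labels are 1-based class indices
loss_xent <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  onehot <- matrix(0, n, ncol(logits))
  onehot[cbind(seq_len(n), labels)] <- 1
  list(loss = -mean(log(pmax(p[cbind(seq_len(n), labels)], 1e-12))),
       grad = (p - onehot) / n)
}

#' Mean absolute error and mean squared error regression losses
#'
#' These are the training losses of the EBL regressor:
#' MAE = (1/n) sum |y_i - yhat_i| and MSE = (1/n) sum (y_i - yhat_i)^2.
#' Exposed (with their gradients) so recorded training losses can be checked
#' against hand computation.
#'
#' @param pred,truth numeric vectors of equal length.
#' @return list with `loss` (scalar) and `grad` (d loss / d pred).
#' @export
loss_mae <- function(pred, truth) {
  n <- length(pred)
  list(loss = mean(abs(truth - pred)), grad = sign(pred - truth) / n)
}

#' @rdname loss_mae
#' @export
loss_mse <- function(pred, truth) {
  n <- length(pred)
  list(loss = mean((truth - pred)^2), grad = 2 * (pred - truth) / n)
}

# ---- backbones --------------------------------------------------------------

# Conv stacks: "small_cnn" is the desk-scale default. The *_style variants
# are width/depth-scaled stacks standing in for the named families (swish
# activation for the EfficientNet-style ones); they are architectural
# gestures, not reproductions.
backbone_plan <- function(backbone) {
  switch(backbone,
    small_cnn = list(widths = c(8, 16, 32), act = "relu"),
    vgg16_style = list(widths = c(16, 32, 64), act = "relu"),
    googlenet_style = list(widths = c(12, 24, 48), act = "relu"),
    efficientnet_b3_style = list(widths = c(12, 24, 40), act = "swish"),
    efficientnet_b5_style = list(widths = c(16, 32, 64), act = "swish"),
    abort(sprintf("unknown backbone '%s'", backbone)))
}

build_conv_stack <- function(backbone, c_in = 3L) {
  plan <- backbone_plan(backbone)
  layers <- list()
  prev <- c_in
  for (wd in plan$widths) {
    layers <- c(layers, list(nn_conv3(prev, wd), nn_act(plan$act), nn_pool2()))
    prev <- wd
  }
  c(layers, list(nn_gpool()))
}

backbone_out_width <- function(backbone) {
  plan <- backbone_plan(backbone)
  plan$widths[length(plan$widths)]
}

build_mlp <- function(d_in, hidden, act = "relu") {
  layers <- list()
  prev <- d_in
  for (hd in hidden) {
    layers <- c(layers, list(nn_dense(prev, hd), nn_act(act)))
    prev <- hd
  }
  layers
}

# ---- batching helpers -------------------------------------------------------

# stack a list of H x W x C images (0..255) into the (H, W, B, C) layout,
# normalised per channel
stack_images <- function(imgs, norm) {
  d <- dim(imgs[[1]])
  B <- length(imgs)
  x <- array(0, c(d[1], d[2], B, d[3]))
  for (b in seq_len(B)) x[, , b, ] <- imgs[[b]] / 255
  for (ch in seq_len(d[3])) {
    x[, , , ch] <- (x[, , , ch] - norm$mean[ch]) / norm$sd[ch]
  }
  x
}

channel_norm <- function(imgs) {
  v <- vapply(imgs, function(im) apply(im / 255, 3, mean), numeric(dim(imgs[[1]])[3]))
  mu <- rowMeans(v)
  s <- vapply(imgs, function(im) apply(im / 255, 3, sd), numeric(dim(imgs[[1]])[3]))
  list(mean = mu, sd = pmax(rowMeans(s), 1e-3))
}
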