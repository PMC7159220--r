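# Minimal dense/convolutional network engine.
#
# Layer types: conv (3x3, valid), relu, maxpool (2x2 stride 2), flatten,
# dense. The final dense layer emits logits; softmax is applied by the loss
# and by predict. Convolution runs as im2col + single-precision GEMM in
# src/convnet.cpp; spatial activations travel in "matrix form" — an
# (h*w*n) x channels matrix — so no 4-D permutations happen in the hot
# path. All stochastic steps (weight init, per-epoch shuffling) run on
# derived seeds.

# Class order everywhere: column 1 = "effect", column 2 = "no_effect".
nn_classes <- c("effect", "no_effect")

conv_layer <- function(in_shape, filters, kh = 3, kw = 3) {
  out_shape <- c(in_shape[1] - kh + 1, in_shape[2] - kw + 1, filters)
  if (any(out_shape[1:2] < 1))
    stop("input ", in_shape[1], "x", in_shape[2],
         " smaller than the receptive-field minimum of this architecture",
         call. = FALSE)
  list(type = "conv", kh = kh, kw = kw, in_shape = in_shape,
       out_shape = out_shape,
       W = matrix(0, kh * kw * in_shape[3], filters),
       b = numeric(filters))
}

pool_layer <- function(in_shape) {
  out_shape <- c(in_shape[1] %/% 2, in_shape[2] %/% 2, in_shape[3])
  if (any(out_shape[1:2] < 1))
    stop("input ", in_shape[1], "x", in_shape[2],
         " smaller than the receptive-field minimum of this architecture",
         call. = FALSE)
  list(type = "maxpool", in_shape = in_shape, out_shape = out_shape)
}

dense_layer <- function(n_in, n_out) {
  list(type = "dense", in_shape = n_in, out_shape = n_out,
       W = matrix(0, n_in, n_out), b = numeric(n_out))
}

# He-style initialization, seeded.
nn_init <- function(model, seed = 1) {
  with_seed(seed, {
    model$layers <- lapply(model$layers, function(l) {
      if (l$type %in% c("conv", "dense")) {
        fan_in <- nrow(l$W)
        l$W <- matrix(rnorm(length(l$W), 0, sqrt(2 / fan_in)),
                      nrow(l$W), ncol(l$W))
        l$b <- numeric(length(l$b))
      }
      l
    })
  })
  model
}

# Convert an (H, W, C, N) array to matrix form: (H*W*N) x C with row index
# hh + H*ww + H*W*nn. Returns list(a, hwn).
array_to_matform <- function(x) {
  d <- dim(x)
  a <- if (d[3] == 1) {
    m <- x; dim(m) <- c(d[1] * d[2] * d[4], 1); m
  } else {
    m <- aperm(x, c(1, 2, 4, 3)); dim(m) <- c(d[1] * d[2] * d[4], d[3]); m
  }
  list(a = a, hwn = c(d[1], d[2], d[4]))
}

# Forward pass. x: array (H, W, C, N), or matrix (N x D) for dense-only
# models. keep = TRUE retains per-layer caches for backward.
nn_forward <- function(model, x, keep = FALSE) {
  if (is.array(x) && length(dim(x)) == 4) {
    mf <- array_to_matform(x); a <- mf$a; hwn <- mf$hwn
  } else { a <- x; hwn <- NULL }
  cache <- if (keep) vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "conv") {
      if (keep) cache[[li]] <- list(a = a, hwn = hwn)
      a <- cpp_conv_fwd(a, as.integer(hwn), l$W, l$b, l$kh, l$kw)
      hwn <- c(l$out_shape[1:2], hwn[3])
    } else if (l$type == "relu") {
      a <- cpp_relu(a)
      if (keep) cache[[li]] <- list(y = a)
    } else if (l$type == "maxpool") {
      p <- cpp_maxpool_fwd(a, as.integer(hwn))
      if (keep) cache[[li]] <- list(idx = p$idx, hwn = hwn, C = ncol(a))
      a <- p$y
      hwn <- c(hwn[1] %/% 2, hwn[2] %/% 2, hwn[3])
    } else if (l$type == "flatten") {
      if (keep) cache[[li]] <- list(hwn = hwn, C = ncol(a))
      a <- cpp_flatten_mat(a, as.integer(hwn))
      hwn <- NULL
    } else if (l$type == "dense") {
      if (keep) cache[[li]] <- list(x = a)
      a <- sweep(a %*% l$W, 2, l$b, "+")
    } else stop("unsupported layer type: ", l$type, call. = FALSE)
  }
  list(logits = a, cache = cache)
}

# Backward pass from d(loss)/d(logits); returns per-layer gradient list.
nn_backward <- function(model, cache, dlogits) {
  grads <- vector("list", length(model$layers))
  g <- dlogits
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]; cc <- cache[[li]]
    if (l$type == "dense") {
      grads[[li]] <- list(W = crossprod(cc$x, g), b = colSums(g))
      g <- g %*% t(l$W)
    } else if (l$type == "flatten") {
      g <- cpp_unflatten_mat(g, as.integer(cc$hwn), cc$C)
    } else if (l$type == "maxpool") {
      g <- cpp_maxpool_bwd(g, cc$idx, as.integer(cc$hwn), cc$C)
    } else if (l$type == "relu") {
      g <- cpp_relu_bwd(g, cc$y)
    } else if (l$type == "conv") {
      bw <- cpp_conv_bwd(cc$a, as.integer(cc$hwn), l$W, g, l$kh, l$kw,
                         li > 1)  # the input layer needs no activation grad
      grads[[li]] <- list(W = bw$dW, b = bw$db)
      g <- bw$dA
    }
  }
  grads
}

softmax <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

# Mean categorical cross-entropy and its logit gradient.
ce_loss <- function(logits, y_onehot) {
  p <- softmax(logits)
  eps <- 1e-12
  list(loss = -mean(rowSums(y_onehot * log(p + eps))),
       dlogits = (p - y_onehot) / nrow(logits))
}

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    if (l$type %in% c("conv", "dense"))
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(model, grads, state, t, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; lr <- cfg$learning_rate; eps <- cfg$epsilon
  for (li in seq_along(model$layers)) {
    if (is.null(grads[[li]])) next
    s <- state[[li]]; g <- grads[[li]]; l <- model$layers[[li]]
    s$mW <- b1 * s$mW + (1 - b1) * g$W
    s$vW <- b2 * s$vW + (1 - b2) * g$W^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    mWh <- s$mW / (1 - b1^t); vWh <- s$vW / (1 - b2^t)
    mbh <- s$mb / (1 - b1^t); vbh <- s$vb / (1 - b2^t)
    l$W <- l$W - lr * mWh / (sqrt(vWh) + eps)
    l$b <- l$b - lr * mbh / (sqrt(vbh) + eps)
    model$layers[[li]] <- l; state[[li]] <- s
  }
  list(model = model, state = state)
}

slice_batch <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE]
  else x[, , , idx, drop = FALSE]
}

labels_to_onehot <- function(labels) {
  stopifnot(all(labels %in% nn_classes))
  y <- matrix(0, length(labels), 2, dimnames = list(NULL, nn_classes))
  y[cbind(seq_along(labels), match(labels, nn_classes))] <- 1
  y
}

#' Train a network with Adam on categorical cross-entropy
#'
#' Runs exactly `config$epochs` passes over the training set; each epoch
#' visits every example once in a fresh seeded permutation (reshuffled every
#' epoch). No early stopping: the epoch budget is the stopping rule.
#'
#' @param model A model from [build_own_cnn()] or [build_head()].
#' @param x Input batch: array `(H, W, C, N)` or feature matrix `(N x D)`.
#' @param labels Character vector in `{"effect", "no_effect"}`.
#' @param config A [train_config()].
#' @return List with the trained `model` and `loss_trace` (mean loss per
#'   epoch, length `config$epochs`).
#' @export
nn_train <- function(model, x, labels, config = train_config()) {
  n <- if (is.matrix(x)) nrow(x) else dim(x)[4]
  if (n == 0) stop("empty training set", call. = FALSE)
  stopifnot(length(labels) == n)
  y <- labels_to_onehot(labels)
  model <- nn_init(model, seed = derive_seed(config$seed, "init"))
  state <- adam_init(model)
  trace <- numeric(config$epochs)
  t <- 0
  for (ep in seq_len(config$epochs)) {
    perm <- with_seed(derive_seed(config$seed, "epoch", ep), sample(n))
    ep_loss <- 0; n_b <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1, n)]
      fw <- nn_forward(model, slice_batch(x, idx), keep = TRUE)
      ls <- ce_loss(fw$logits, y[idx, , drop = FALSE])
      grads <- nn_backward(model, fw$cache, ls$dlogits)
      t <- t + 1
      st <- adam_step(model, grads, state, t, config)
      model <- st$model; state <- st$state
      ep_loss <- ep_loss + ls$loss; n_b <- n_b + 1
    }
    trace[ep] <- ep_loss / n_b
  }
  list(model = model, loss_trace = trace)
}
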