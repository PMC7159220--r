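# Deep Taylor decomposition: backward relevance propagation decomposing a
# network's pre-softmax class activation into per-pixel contributions.
#
# Hidden layers use the positive-share (z+) rule: each input neuron receives
# relevance proportional to its positive contribution (activation x positive
# weight part) to each output it feeds, normalized per output neuron. The
# input layer uses the box rule for the declared input range [0, 1].
# Max-downsampling routes relevance to the winning location; rectifiers pass
# relevance through unchanged. Conservation (layer sums equal the explained
# score) is exact for bias-free networks.

#' Collect per-layer activations for one input
#'
#' @param model An `nn_model` with supported layer types (dense, conv,
#'   maxpool, relu, flatten).
#' @param input Single input: matrix `H x W` (or array `(H, W, C)`) for
#'   convolutional models, numeric vector for dense models.
#' @return List with `acts` (per-layer input activations in matrix form,
#'   each a list `a`, `hwn`), `logits`, and `depth`.
#' @export
forward_collect <- function(model, input) {
  bad <- setdiff(vapply(model$layers, `[[`, "", "type"),
                 c("dense", "conv", "maxpool", "relu", "flatten"))
  if (length(bad))
    stop("unsupported layer type: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  st <- prep_single_input(model, input)
  acts <- vector("list", length(model$layers) + 1)
  acts[[1]] <- st
  a <- st$a; hwn <- st$hwn
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "conv") {
      a <- cpp_conv_fwd(a, as.integer(hwn), l$W, l$b, l$kh, l$kw)
      hwn <- c(l$out_shape[1:2], hwn[3])
    } else if (l$type == "relu") {
      a <- cpp_relu(a)
    } else if (l$type == "maxpool") {
      a <- cpp_maxpool_fwd(a, as.integer(hwn))$y
      hwn <- c(hwn[1] %/% 2, hwn[2] %/% 2, hwn[3])
    } else if (l$type == "flatten") {
      a <- cpp_flatten_mat(a, as.integer(hwn)); hwn <- NULL
    } else if (l$type == "dense") {
      a <- sweep(a %*% l$W, 2, l$b, "+")
    }
    acts[[li + 1]] <- list(a = a, hwn = hwn)
  }
  list(acts = acts, logits = acts[[length(acts)]]$a,
       depth = length(model$layers))
}

prep_single_input <- function(model, input) {
  if (is.numeric(model$input_shape) && length(model$input_shape) == 1) {
    list(a = matrix(as.numeric(input), nrow = 1), hwn = NULL)
  } else {
    if (is.matrix(input)) input <- array(input, c(dim(input), 1))
    d <- dim(input)
    list(a = matrix(as.numeric(input), d[1] * d[2], d[3]),
         hwn = c(d[1], d[2], 1L))
  }
}

#' Deep Taylor relevance map for one input
#'
#' Decomposes the target class's pre-softmax activation into non-negative
#' per-pixel relevances. Output neurons other than the target start with
#' zero relevance. Neurons whose positive-contribution denominator falls
#' below `1e-12` have their relevance dropped with a conservation warning
#' (division guard); biases likewise absorb relevance, so conservation is
#' exact only for bias-free networks.
#'
#' @param model A trained `nn_model`.
#' @param input A single input (see [forward_collect()]).
#' @param target_class `"effect"`, `"no_effect"`, or `NULL` for the
#'   predicted class.
#' @param input_range `c(low, high)` box constraints of the input layer.
#' @return A `relevance_map`: `relevance` (input-shaped, channel-summed for
#'   display), `explained_class`, `explained_score`, `layer_sums` (total
#'   relevance entering each layer, input layer first, output last).
#' @export
dtd_relevance <- function(model, input, target_class = NULL,
                          input_range = c(0, 1)) {
  fc <- forward_collect(model, input)
  logits <- as.numeric(fc$logits)
  if (is.null(target_class))
    target_class <- nn_classes[which.max(logits)]
  k <- match(target_class, nn_classes)
  if (is.na(k)) stop("unknown class: ", target_class, call. = FALSE)
  score <- logits[k]
  if (score < 0)
    stop("target pre-softmax activation is negative (", signif(score, 4),
         "); deep Taylor decomposition explains non-negative scores",
         call. = FALSE)
  R <- matrix(0, 1, length(logits)); R[1, k] <- score
  layer_sums <- sum(R)
  dropped <- 0
  guard <- function(z) {
    bad <- abs(z) < 1e-12
    dropped <<- dropped + sum(bad)
    z[bad] <- Inf  # relevance flowing through these neurons is dropped
    z
  }
  first_weighted <- min(which(vapply(model$layers, function(l)
    l$type %in% c("dense", "conv"), logical(1))))
  lo <- input_range[1]; hi <- input_range[2]
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    ain <- fc$acts[[li]]
    if (l$type == "dense") {
      if (li == first_weighted) {
        Wp <- pmax(l$W, 0); Wm <- pmin(l$W, 0)
        z <- ain$a %*% l$W - lo * colSums(Wp) - hi * colSums(Wm)
        s <- R / guard(z)
        R <- ain$a * (s %*% t(l$W)) - lo * (s %*% t(Wp)) - hi * (s %*% t(Wm))
      } else {
        Wp <- pmax(l$W, 0)
        z <- ain$a %*% Wp
        s <- R / guard(z)
        R <- ain$a * (s %*% t(Wp))
      }
    } else if (l$type == "flatten") {
      R <- cpp_unflatten_mat(R, as.integer(ain$hwn), ncol(ain$a))
    } else if (l$type == "relu") {
      # identity on relevance
    } else if (l$type == "maxpool") {
      p <- cpp_maxpool_fwd(ain$a, as.integer(ain$hwn))
      R <- cpp_maxpool_bwd(R, p$idx, as.integer(ain$hwn), ncol(ain$a))
    } else if (l$type == "conv") {
      xc <- cpp_im2col_mat(ain$a, as.integer(ain$hwn), l$kh, l$kw)
      if (li == first_weighted) {
        Wp <- pmax(l$W, 0); Wm <- pmin(l$W, 0)
        z <- xc %*% l$W
        z <- sweep(z, 2, lo * colSums(Wp) + hi * colSums(Wm), "-")
        s <- R / guard(z)
        M <- xc * (s %*% t(l$W)) - lo * (s %*% t(Wp)) - hi * (s %*% t(Wm))
      } else {
        Wp <- pmax(l$W, 0)
        z <- xc %*% Wp
        s <- R / guard(z)
        M <- xc * (s %*% t(Wp))
      }
      R <- cpp_col2im_mat(M, as.integer(ain$hwn), l$kh, l$kw)
    }
    layer_sums <- c(sum(R), layer_sums)
  }
  if (dropped > 0)
    warning(dropped,
            " neuron(s) dropped relevance (zero positive contribution)",
            call. = FALSE)
  rel <- if (!is.null(fc$acts[[1]]$hwn)) {
    hwn <- fc$acts[[1]]$hwn
    matrix(rowSums(matrix(R, hwn[1] * hwn[2], ncol(R))), hwn[1], hwn[2])
  } else as.numeric(R)
  structure(list(relevance = rel, explained_class = target_class,
                 explained_score = score, layer_sums = layer_sums),
            class = "relevance_map")
}

#' Per-layer relevance-conservation report
#'
#' Runs the decomposition for each input (explaining the predicted class)
#' and reports the per-layer relevance sums and the maximum relative
#' deviation from the explained score. For networks with biases the
#' deviation is reported, not asserted: biases absorb relevance.
#'
#' @param model A trained `nn_model`.
#' @param inputs Non-empty list of single inputs.
#' @param ... Passed to [dtd_relevance()].
#' @return List: `sums` (matrix, one row per input), `scores`,
#'   `max_rel_deviation`.
#' @export
conservation_report <- function(model, inputs, ...) {
  if (length(inputs) == 0) stop("empty input batch", call. = FALSE)
  maps <- lapply(inputs, function(x) dtd_relevance(model, x, ...))
  sums <- do.call(rbind, lapply(maps, `[[`, "layer_sums"))
  scores <- vapply(maps, `[[`, numeric(1), "explained_score")
  dev <- abs(sums - scores) / pmax(abs(scores), 1e-12)
  list(sums = sums, scores = scores, max_rel_deviation = max(dev))
}

#' Render a relevance heatmap
#'
#' Relevance is normalized to `[0, 1]` by its maximum (an all-zero map stays
#' zero) and drawn on a red scale; `overlay` alpha-blends the heat onto the
#' original image, `side_by_side` concatenates original, overlay, and heat
#' panels (width = 3 x input width).
#'
#' @param relevance_map A `relevance_map` (or plain relevance matrix).
#' @param original_image Grayscale matrix (0..255 or 0..1) of matching size.
#' @param mode `"heat"`, `"overlay"`, or `"side_by_side"`.
#' @param alpha Overlay blend strength in `(0, 1]`.
#' @return RGB array `H x W' x 3` with values in `[0, 1]`.
#' @export
render_heatmap <- function(relevance_map, original_image,
                           mode = c("heat", "overlay", "side_by_side"),
                           alpha = 0.6) {
  mode <- match.arg(mode)
  r <- if (inherits(relevance_map, "relevance_map")) relevance_map$relevance
       else relevance_map
  stopifnot(is.matrix(r), all(dim(r) == dim(original_image)))
  mx <- max(r)
  rn <- if (mx > 0) pmax(r, 0) / mx else r * 0
  img <- if (max(original_image) > 1) original_image / 255 else original_image
  heat <- array(0, c(dim(r), 3)); heat[, , 1] <- rn
  ov <- array(rep(img, 3), c(dim(r), 3))
  a <- alpha * rn
  ov[, , 1] <- (1 - a) * img + a        # blend toward pure red
  ov[, , 2] <- (1 - a) * img
  ov[, , 3] <- (1 - a) * img
  switch(mode,
         heat = heat,
         overlay = ov,
         side_by_side = {
           orig <- array(rep(img, 3), c(dim(r), 3))
           out <- array(0, c(nrow(r), 3 * ncol(r), 3))
           out[, seq_len(ncol(r)), ] <- orig
           out[, ncol(r) + seq_len(ncol(r)), ] <- ov
           out[, 2 * ncol(r) + seq_len(ncol(r)), ] <- heat
           out
         })
}
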