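# Facial-expression classifier: preprocessing, the small trained-from-scratch
# CNN, the frozen-backbone + softmax-head path, prediction, and per-group
# confidence averaging.

#' Training configuration
#'
#' Defaults are the study regime: Adam (learning rate 0.001, beta1 0.9,
#' beta2 0.999, epsilon 1e-07, decay 0), categorical cross-entropy, batch
#' size 100, a fixed budget of 50 epochs with a new random permutation of
#' the training set each epoch, and bilinear resizing of all images to
#' 224 x 224. Tests and scaled-down runs may lower `input_size` (e.g. 64);
#' such runs are flagged as scaled-down in reports.
#'
#' @param learning_rate,beta1,beta2,epsilon,decay Adam parameters.
#' @param batch_size,epochs Training regime.
#' @param input_size `c(height, width)` after resizing (single value is
#'   recycled).
#' @param seed Seed for weight init and epoch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-07, decay = 0, batch_size = 100,
                         epochs = 50, input_size = c(224, 224), seed = 1) {
  if (length(input_size) == 1) input_size <- rep(input_size, 2)
  stopifnot(learning_rate >= 0, batch_size >= 1, epochs >= 1,
            all(input_size >= 1), decay == 0)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, decay = decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 input_size = as.integer(input_size),
                 resize_method = "bilinear", seed = as.integer(seed)),
            class = "train_config")
}

#' Preprocess an image for the network
#'
#' Bilinear resize to `config$input_size` and rescaling of pixel values to
#' `[0, 1]` (the own-CNN convention; stub backbones use the same range).
#' Inputs already at the target size are passed through without resampling.
#'
#' @param image Numeric matrix (grayscale, values in 0..255 or 0..1) or a
#'   file path to a PNG.
#' @param config A [train_config()].
#' @return Matrix `input_size[1] x input_size[2]` with values in `[0, 1]`.
#' @export
preprocess <- function(image, config = train_config()) {
  if (is.character(image)) {
    if (!file.exists(image))
      stop("cannot read image file: ", image, call. = FALSE)
    image <- png::readPNG(image)
    if (length(dim(image)) == 3) image <- image[, , 1]
    image <- image * 255
  }
  stopifnot(is.matrix(image))
  img <- image / if (max(image) > 1) 255 else 1
  hw <- config$input_size
  if (!all(dim(img) == hw))
    img <- as.matrix(EBImage::resize(img, w = hw[1], h = hw[2],
                                     filter = "bilinear"))
  img
}

# Stack preprocessed images into the (H, W, 1, N) batch array.
images_to_array <- function(images, config) {
  hw <- config$input_size
  n <- length(images)
  x <- array(0, dim = c(hw[1], hw[2], 1, n))
  for (i in seq_len(n)) x[, , 1, i] <- preprocess(images[[i]], config)
  x
}

#' Build the small trained-from-scratch CNN
#'
#' Three 3x3 convolutional layers with 32, 32, and 64 filters, each followed
#' by a rectifier and 2x2 max-downsampling, then two fully connected layers
#' of 128 rectified units and a 2-way softmax output.
#'
#' @param input_size `c(height, width)` of the (grayscale) input.
#' @param channels Input channel count.
#' @return An untrained model (initialize and fit with [nn_train()]).
#' @export
build_own_cnn <- function(input_size = c(224, 224), channels = 1) {
  if (length(input_size) == 1) input_size <- rep(input_size, 2)
  shape <- c(input_size, channels)
  layers <- list()
  for (f in c(32, 32, 64)) {
    l <- conv_layer(shape, f); layers <- c(layers, list(l, list(type = "relu")))
    shape <- l$out_shape
    l <- pool_layer(shape); layers <- c(layers, list(l))
    shape <- l$out_shape
  }
  layers <- c(layers, list(list(type = "flatten")))
  d <- prod(shape)
  for (w in c(128, 128)) {
    layers <- c(layers, list(dense_layer(d, w), list(type = "relu")))
    d <- w
  }
  layers <- c(layers, list(dense_layer(d, 2)))
  structure(list(layers = layers, input_shape = c(input_size, channels),
                 arch = "own_cnn"), class = "nn_model")
}

#' Build the softmax head for a frozen backbone
#'
#' A single fully connected layer with two output neurons and softmax: the
#' only trainable part of the transfer-learning path
#' (`2 * feature_dim + 2` parameters).
#'
#' @param feature_dim Width of the backbone's pooled feature vector.
#' @return An untrained head model.
#' @export
build_head <- function(feature_dim) {
  structure(list(layers = list(dense_layer(feature_dim, 2)),
                 input_shape = feature_dim, arch = "head"),
            class = "nn_model")
}

#' Number of trainable parameters of a model
#' @param model An `nn_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l)
    if (l$type %in% c("conv", "dense")) length(l$W) + length(l$b) else 0,
    numeric(1)))
}

#' Construct a frozen stub backbone
#'
#' Published ImageNet backbone weights are an external artifact; for
#' self-contained runs this builds a small convolutional network with
#' random, frozen, seed-reproducible weights and the declared feature width
#' of the named architecture (2048 for both ResNet50 and InceptionV3 pooled
#' outputs). Real pre-trained weights can be substituted by supplying any
#' object with the same `$model` / `$feature_dim` fields.
#'
#' @param name `"resnet50"` or `"inceptionv3"`.
#' @param input_size Input `c(height, width)` the stub accepts.
#' @param seed Seed for the frozen random weights.
#' @return A `backbone` object.
#' @export
stub_backbone <- function(name = c("resnet50", "inceptionv3"),
                          input_size = c(64, 64), seed = 17) {
  name <- match.arg(name)
  if (length(input_size) == 1) input_size <- rep(input_size, 2)
  feature_dim <- 2048L
  shape <- c(input_size, 1)
  layers <- list()
  filters <- if (name == "resnet50") c(16, 32) else c(24, 24)
  for (f in filters) {
    l <- conv_layer(shape, f); layers <- c(layers, list(l, list(type = "relu")))
    shape <- l$out_shape
    l <- pool_layer(shape); layers <- c(layers, list(l))
    shape <- l$out_shape
  }
  model <- structure(list(layers = layers, input_shape = c(input_size, 1),
                          arch = name), class = "nn_model")
  model <- nn_init(model, seed = derive_seed(seed, "backbone", name))
  # the last convolutional representation is average-pooled onto a coarse
  # spatial grid (keeping layout information), then projected to the
  # declared feature width by a fixed random matrix
  grid <- 6L
  proj <- with_seed(derive_seed(seed, "proj", name),
                    matrix(rnorm(shape[3] * grid^2 * feature_dim, 0,
                                 sqrt(2 / (shape[3] * grid^2))),
                           shape[3] * grid^2, feature_dim))
  structure(list(name = name, model = model, proj = proj, grid = grid,
                 feature_dim = feature_dim, input_size = input_size),
            class = "backbone")
}

#' Extract frozen-backbone features
#'
#' Deterministic per image: forward pass through the frozen convolutional
#' base, global average pooling over space, and projection to the declared
#' feature width. Backbone weights are never updated.
#'
#' @param images List of images (matrices or paths).
#' @param backbone A [stub_backbone()] (or compatible) object, or a backbone
#'   name, in which case the stub is built.
#' @param config Preprocessing config; `input_size` is overridden by the
#'   backbone's.
#' @return Matrix `n_images x feature_dim`.
#' @export
extract_features <- function(images, backbone = "resnet50",
                             config = train_config()) {
  if (is.character(backbone)) {
    if (!backbone %in% c("resnet50", "inceptionv3"))
      stop("unknown backbone '", backbone,
           "'; options: resnet50, inceptionv3", call. = FALSE)
    backbone <- stub_backbone(backbone)
  }
  config$input_size <- backbone$input_size
  x <- images_to_array(images, config)
  n <- dim(x)[4]
  a <- nn_forward(backbone$model, x)$logits  # matrix form (h*w*n) x C
  last <- backbone$model$layers[[length(backbone$model$layers)]]
  h <- last$out_shape[1]; w <- last$out_shape[2]; C <- last$out_shape[3]
  g <- backbone$grid
  # average-pool each channel onto a g x g grid, keeping spatial layout
  gi <- pmin(ceiling(seq_len(h) / (h / g)), g)
  gj <- pmin(ceiling(seq_len(w) / (w / g)), g)
  cell <- gi[rep(seq_len(h), w)] + g * (rep(gj, each = h) - 1)  # h*w cells
  pooled <- matrix(0, n, C * g^2)
  for (c in seq_len(C)) {
    ch <- matrix(a[, c], h * w, n)
    pc <- rowsum(ch, cell) / as.vector(table(cell))    # g^2 x n
    pooled[, (c - 1) * g^2 + seq_len(g^2)] <- t(pc)
  }
  relu <- function(m) m * (m > 0)
  relu(pooled %*% backbone$proj)
}

#' Predict class confidences for images
#'
#' Softmax activations of the two output neurons are reported as the
#' confidence for "effect" and "no_effect"; the hard label is the class
#' with the larger activation, with exact ties resolved to "effect" (for a
#' welfare monitor the conservative error is a false alarm).
#'
#' @param model A trained model.
#' @param images List of images, a prebuilt input array, or a feature
#'   matrix (for head models).
#' @param config A [train_config()].
#' @return Data frame with `conf_effect`, `conf_no_effect`, `hard_label`.
#' @export
predict_images <- function(model, images, config = train_config()) {
  x <- if (is.list(images)) images_to_array(images, config) else images
  # chunked forward pass to bound im2col memory on large image sets
  if (!is.matrix(x) && dim(x)[4] > 128) {
    n <- dim(x)[4]
    p <- do.call(rbind, lapply(split(seq_len(n), ceiling(seq_len(n) / 128)),
                               function(idx)
                                 softmax(nn_forward(model,
                                                    slice_batch(x, idx))$logits)))
  } else p <- softmax(nn_forward(model, x)$logits)
  data.frame(conf_effect = p[, 1], conf_no_effect = p[, 2],
             hard_label = ifelse(p[, 1] >= p[, 2], "effect", "no_effect"),
             stringsAsFactors = FALSE)
}

#' Average confidences over image groups
#'
#' Classifies an (animal, time point) group by the arithmetic mean of its
#' images' confidence vectors; the hard label follows the averaged vector
#' (not the majority vote). Singleton groups pass through unchanged.
#'
#' @param predictions Data frame from [predict_images()], one row per image.
#' @param records Metadata rows aligned with `predictions`.
#' @param group_keys Metadata columns defining the groups.
#' @return Data frame with one row per group: the key columns, averaged
#'   confidences, `hard_label`, and `n_images`.
#' @export
average_group_confidence <- function(predictions, records,
                                     group_keys = c("animal_id", "time_label")) {
  if (nrow(predictions) != nrow(records))
    stop("every prediction must join to a record (",
         nrow(predictions), " predictions vs ", nrow(records), " records)",
         call. = FALSE)
  stopifnot(all(group_keys %in% names(records)))
  key <- interaction(records[group_keys], drop = TRUE, lex.order = TRUE)
  agg <- function(v) tapply(v, key, mean)
  ce <- agg(predictions$conf_effect); cn <- agg(predictions$conf_no_effect)
  first <- !duplicated(key)
  out <- records[first, group_keys, drop = FALSE]
  ord <- match(levels(key), key[first])
  out <- out[ord, , drop = FALSE]
  out$conf_effect <- as.numeric(ce)
  out$conf_no_effect <- as.numeric(cn)
  out$hard_label <- ifelse(out$conf_effect >= out$conf_no_effect,
                           "effect", "no_effect")
  out$n_images <- as.integer(table(key))
  rownames(out) <- NULL
  out
}

#' Train a classifier on image records
#'
#' Convenience wrapper: preprocesses the images of `records`, trains either
#' the small CNN or a softmax head on frozen-backbone features, and returns
#' the fitted model with its loss trace.
#'
#' @param records Metadata rows with `binary_label`.
#' @param images Named list of images (names matching
#'   `records$image_path`), or `NULL` to read from the paths.
#' @param arch `"own_cnn"`, `"resnet50"`, or `"inceptionv3"`.
#' @param config A [train_config()].
#' @return List: `model`, `loss_trace`, `arch`, `backbone` (for head paths),
#'   `config`.
#' @export
train_classifier <- function(records, images = NULL, arch = "own_cnn",
                             config = train_config()) {
  if (nrow(records) == 0) stop("empty training set", call. = FALSE)
  imgs <- fetch_images(records, images)
  if (arch == "own_cnn") {
    model <- build_own_cnn(config$input_size)
    fit <- nn_train(model, images_to_array(imgs, config),
                    records$binary_label, config)
    c(fit, list(arch = arch, config = config))
  } else {
    bb <- stub_backbone(arch, input_size = config$input_size)
    feats <- extract_features(imgs, bb, config)
    fit <- nn_train(build_head(bb$feature_dim), feats,
                    records$binary_label, config)
    c(fit, list(arch = arch, backbone = bb, config = config))
  }
}

# Resolve record image references against an in-memory list or disk.
fetch_images <- function(records, images = NULL) {
  if (is.null(images)) return(as.list(records$image_path))
  key <- basename(records$image_path)
  miss <- setdiff(key, names(images))
  if (length(miss))
    stop("images missing for records: ", paste(head(miss, 3), collapse = ", "),
         call. = FALSE)
  images[key]
}

# Predict for records through a train_classifier() fit.
predict_records <- function(fit, records, images = NULL) {
  imgs <- fetch_images(records, images)
  if (fit$arch == "own_cnn") {
    predict_images(fit$model, imgs, fit$config)
  } else {
    feats <- extract_features(imgs, fit$backbone, fit$config)
    predict_images(fit$model, feats, fit$config)
  }
}
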