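# Deep Taylor decomposition and heatmap rendering.

gs <- asNamespace("grimscan")

test_that("forward collection reproduces the model output and depth", {
  m <- random_biasfree_cnn(4)
  x <- matrix(runif(32 * 32), 32, 32)
  fc <- forward_collect(m, x)
  expect_length(fc$acts, length(m$layers) + 1)
  expect_equal(fc$depth, length(m$layers))
  direct <- gs$nn_forward(m, array(x, c(32, 32, 1, 1)))$logits
  expect_identical(as.numeric(fc$logits), as.numeric(direct))
  # zero input through a bias-free network gives all-zero activations
  fc0 <- forward_collect(m, matrix(0, 32, 32))
  expect_equal(max(abs(fc0$logits)), 0)

  bad <- m; bad$layers[[2]] <- list(type = "tanh")
  expect_error(forward_collect(bad, x), "tanh")
})

test_that("a one-hot input through a single positive dense layer keeps all relevance", {
  W <- matrix(c(0.5, 0.2, 0.1, 0.7, 0.3, 0.9), 3, 2)
  m <- structure(list(layers = list(
    list(type = "dense", W = W, b = numeric(2), in_shape = 3, out_shape = 2)),
    input_shape = 3), class = "nn_model")
  x <- c(0, 2, 0)
  map <- dtd_relevance(m, x, "effect", input_range = c(0, 2))
  expect_equal(map$explained_score, 2 * W[2, 1])
  expect_equal(map$relevance, c(0, map$explained_score, 0))
})

test_that("zero inputs produce zero maps and negative scores are refused", {
  m <- random_biasfree_cnn(6)
  map0 <- suppressWarnings(dtd_relevance(m, matrix(0, 32, 32), "effect"))
  expect_equal(max(abs(map0$relevance)), 0)

  neg <- m
  nl <- length(neg$layers)
  neg$layers[[nl]]$W <- -abs(neg$layers[[nl]]$W)
  expect_error(dtd_relevance(neg, matrix(runif(1024), 32, 32), "effect"),
               "negative")
  expect_error(dtd_relevance(m, matrix(runif(1024), 32, 32), "sadness"),
               "unknown class")
})

test_that("relevance is conserved per layer on bias-free networks", {
  for (sd in 1:5) {
    m <- random_biasfree_cnn(sd)
    x <- grimscan:::with_seed(sd, matrix(runif(1024), 32, 32))
    map <- dtd_relevance(m, x)
    expect_gt(map$explained_score, 0)
    dev <- abs(map$layer_sums - map$explained_score) / map$explained_score
    expect_lt(max(dev), 1e-4)
    expect_gte(min(map$relevance), 0)
  }
  # conservation_report aggregates the same quantity
  m <- random_biasfree_cnn(11)
  rep <- conservation_report(m, list(matrix(runif(1024), 32, 32),
                                     matrix(runif(1024), 32, 32)))
  expect_lt(rep$max_rel_deviation, 1e-4)
  expect_error(conservation_report(m, list()), "empty")
})

test_that("propagation equals the brute-force share formula on small nets", {
  for (sd in 1:5) {
    set.seed(sd)
    d_in <- 6; d_h <- 4
    W1 <- matrix(rnorm(d_in * d_h), d_in, d_h)
    W2 <- matrix(abs(rnorm(d_h * 2)), d_h, 2)
    m <- structure(list(layers = list(
      list(type = "dense", W = W1, b = numeric(d_h), in_shape = d_in,
           out_shape = d_h),
      list(type = "relu"),
      list(type = "dense", W = W2, b = numeric(2), in_shape = d_h,
           out_shape = 2)), input_shape = d_in), class = "nn_model")
    x <- abs(rnorm(d_in))
    lo <- 0; hi <- max(x)
    map <- dtd_relevance(m, x, "effect", input_range = c(lo, hi))

    # brute force: z+ on the hidden layer, box rule on the input layer
    h <- pmax(as.numeric(x %*% W1), 0)
    logit <- as.numeric(h %*% W2)[1]
    Rh <- numeric(d_h)
    zpos <- as.numeric(h %*% pmax(W2, 0))
    for (j in seq_len(d_h)) for (k in 1:1)
      if (zpos[k] > 0) Rh[j] <- Rh[j] + h[j] * pmax(W2, 0)[j, k] * logit / zpos[k]
    Wp <- pmax(W1, 0); Wm <- pmin(W1, 0)
    zz <- as.numeric(x %*% W1) - lo * colSums(Wp) - hi * colSums(Wm)
    Rx <- numeric(d_in)
    for (i in seq_len(d_in)) for (j in seq_len(d_h))
      if (abs(zz[j]) > 1e-12)
        Rx[i] <- Rx[i] + (x[i] * W1[i, j] - lo * Wp[i, j] - hi * Wm[i, j]) *
          Rh[j] / zz[j]
    expect_equal(map$relevance, Rx, tolerance = 1e-8)
    expect_equal(map$explained_score, logit, tolerance = 1e-12)
  }
})

test_that("heatmap rendering normalizes, overlays, and tiles panels", {
  img <- matrix(runif(100), 10, 10)
  zero <- matrix(0, 10, 10)
  expect_equal(render_heatmap(zero, img, mode = "overlay"),
               array(rep(img, 3), c(10, 10, 3)))   # zero map: image unchanged
  hot <- zero; hot[3, 7] <- 5
  h <- render_heatmap(hot, img, mode = "heat")
  expect_equal(h[3, 7, 1], 1)                       # maximum red at the peak
  expect_equal(sum(h[, , 1] == 1), 1)
  expect_equal(max(h[, , 2:3]), 0)
  sbs <- render_heatmap(hot, img, mode = "side_by_side")
  expect_equal(dim(sbs), c(10, 30, 3))              # three panels wide
  expect_equal(sbs[, 1:10, 1], img)                 # original panel first
})

test_that("relevance on a trained eye-cue classifier concentrates on the eyes", {
  # tiny training set where only orbital tightening separates the classes
  imgs <- list(); labs <- c(); boxes <- list()
  for (k in 1:30) {
    id <- animal_identity(sprintf("e%d", k), "male", "KXN",
                          seed = derive_seed(7, k))
    eff <- k %% 2 == 0
    st <- action_unit_state(orbital_tightening = if (eff) 1.8 else 0.1)
    r <- render_face(id, st, scene_params(pellet_count = 0),
                     rng_seed = derive_seed(31, k))
    imgs[[k]] <- r$image
    labs[k] <- if (eff) "effect" else "no_effect"
    boxes[[k]] <- r$geometry
  }
  cfg <- train_config(input_size = 64, epochs = 60, batch_size = 10,
                      seed = 5)
  fit <- nn_train(build_own_cnn(c(64, 64)),
                  grimscan:::images_to_array(imgs, cfg), labs, cfg)
  # open eyes (with their bright glints) are the positive evidence for the
  # "no_effect" class, so relevance should pile up inside the eye boxes
  ratios <- c()
  for (k in seq(1, 29, by = 2)) {
    x <- preprocess(imgs[[k]], cfg)
    map <- try(dtd_relevance(fit$model, x), silent = TRUE)
    if (inherits(map, "try-error")) next
    sc <- 64 / 96
    mask <- matrix(FALSE, 64, 64)
    for (p in c("left_eye", "right_eye")) {
      b <- boxes[[k]][[p]]
      rr <- max(1, floor(b$y0 * sc) - 1):min(64, ceiling(b$y1 * sc) + 1)
      cc <- max(1, floor(b$x0 * sc) - 1):min(64, ceiling(b$x1 * sc) + 1)
      mask[rr, cc] <- TRUE
    }
    ratios <- c(ratios, mean(map$relevance[mask]) /
                  max(mean(map$relevance[!mask]), 1e-12))
  }
  expect_gte(length(ratios), 10)
  expect_gt(median(ratios), 2)
})
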