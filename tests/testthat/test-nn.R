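# Network engine: architectures, gradients, training regime.

gs <- asNamespace("grimscan")

test_that("the small CNN has the declared architecture", {
  m <- build_own_cnn(c(64, 64))
  convs <- Filter(function(l) l$type == "conv", m$layers)
  expect_length(convs, 3)
  expect_equal(vapply(convs, function(l) ncol(l$W), numeric(1)), c(32, 32, 64))
  expect_true(all(vapply(convs, function(l) l$kh == 3 && l$kw == 3,
                         logical(1))))
  denses <- Filter(function(l) l$type == "dense", m$layers)
  expect_equal(vapply(denses, function(l) l$out_shape, numeric(1)),
               c(128, 128, 2))
  # forward pass on a batch of 5 gives 5 probability pairs summing to 1
  m <- gs$nn_init(m, 1)
  p <- predict_images(m, array(runif(64 * 64 * 5), c(64, 64, 1, 5)),
                      train_config(input_size = 64))
  expect_equal(p$conf_effect + p$conf_no_effect, rep(1, 5), tolerance = 1e-9)
  expect_error(build_own_cnn(c(16, 16)), "receptive-field")
})

test_that("the softmax head has 2 * feature_dim + 2 parameters", {
  expect_equal(n_parameters(build_head(2048)), 4098)
  expect_equal(n_parameters(build_head(10)), 22)
  # equal logits give (0.5, 0.5)
  h <- build_head(4)
  h$layers[[1]]$W <- matrix(0, 4, 2)
  p <- predict_images(h, matrix(runif(8), 2, 4))
  expect_equal(p$conf_effect, c(0.5, 0.5))
  expect_identical(p$hard_label, c("effect", "effect"))  # tie -> effect
})

test_that("backpropagated gradients match finite differences", {
  set.seed(42)
  model <- gs$nn_init(structure(list(layers = list(
    gs$conv_layer(c(10, 10, 1), 4), list(type = "relu"),
    gs$pool_layer(c(8, 8, 4)), list(type = "flatten"),
    gs$dense_layer(64, 5), list(type = "relu"),
    gs$dense_layer(5, 2)), input_shape = c(10, 10, 1)),
    class = "nn_model"), seed = 2)
  x <- array(runif(10 * 10 * 3), c(10, 10, 1, 3))
  y <- gs$labels_to_onehot(c("effect", "no_effect", "effect"))
  fw <- gs$nn_forward(model, x, keep = TRUE)
  ls <- gs$ce_loss(fw$logits, y)
  gr <- gs$nn_backward(model, fw$cache, ls$dlogits)
  loss_at <- function(m) gs$ce_loss(gs$nn_forward(m, x)$logits, y)$loss
  eps <- 1e-3   # forward pass uses single-precision GEMMs
  for (li in c(1, 5, 7)) {
    for (k in 1:5) {
      i <- sample(length(model$layers[[li]]$W), 1)
      m2 <- model
      m2$layers[[li]]$W[i] <- m2$layers[[li]]$W[i] + eps
      num <- (loss_at(m2) - ls$loss) / eps
      expect_equal(num, gr[[li]]$W[i], tolerance = 2e-2, ignore_attr = TRUE)
    }
    m2 <- model
    m2$layers[[li]]$b[1] <- m2$layers[[li]]$b[1] + eps
    expect_equal((loss_at(m2) - ls$loss) / eps, gr[[li]]$b[1],
                 tolerance = 2e-2, ignore_attr = TRUE)
  }
})

test_that("training runs the stated regime", {
  set.seed(1)
  x <- matrix(runif(40 * 6), 40, 6)
  labels <- rep(c("effect", "no_effect"), 20)
  cfg <- train_config(input_size = 1, epochs = 7, batch_size = 16, seed = 3)

  # learning rate 0 leaves the weights unchanged after a full epoch
  cfg0 <- cfg; cfg0$learning_rate <- 0; cfg0$epochs <- 1
  m0 <- gs$nn_init(build_head(6), seed = derive_seed(cfg0$seed, "init"))
  fit0 <- nn_train(build_head(6), x, labels, cfg0)
  expect_equal(fit0$model$layers[[1]]$W, m0$layers[[1]]$W,
               ignore_attr = TRUE)

  # loss trace has one entry per epoch; permutations differ across epochs
  fit <- nn_train(build_head(6), x, labels, cfg)
  expect_length(fit$loss_trace, 7)
  perms <- lapply(1:3, function(ep)
    grimscan:::with_seed(derive_seed(cfg$seed, "epoch", ep), sample(40)))
  expect_false(identical(perms[[1]], perms[[2]]))
  expect_false(identical(perms[[2]], perms[[3]]))

  # reproducible given the seed
  fit2 <- nn_train(build_head(6), x, labels, cfg)
  expect_identical(fit$model$layers[[1]]$W, fit2$model$layers[[1]]$W)
  expect_identical(fit$loss_trace, fit2$loss_trace)

  expect_error(nn_train(build_head(6), x[0, , drop = FALSE], character(0),
                        cfg), "empty")
})

test_that("training reduces the loss on separable features", {
  set.seed(5)
  n <- 60
  labels <- rep(c("effect", "no_effect"), each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4)
  x[, 1] <- x[, 1] + ifelse(labels == "effect", 3, -3)
  fit <- nn_train(build_head(4), x, labels,
                  train_config(epochs = 200, batch_size = 10, seed = 2))
  expect_lt(tail(fit$loss_trace, 1), 0.5 * fit$loss_trace[1])
  # non-increasing trend over the last 10 epochs (small tolerance)
  last10 <- tail(fit$loss_trace, 10)
  expect_true(all(diff(last10) < 0.02))
  # the separable direction is learned
  p <- predict_images(fit$model, x)
  expect_equal(mean(p$hard_label == labels), 1)
})

test_that("hard labels follow the larger activation with ties to effect", {
  h <- build_head(2)
  h$layers[[1]]$W <- matrix(c(1, 0, 0, 1), 2, 2)
  p <- predict_images(h, matrix(c(3, 1, 1, 3, 2, 2), 3, 2, byrow = TRUE))
  expect_identical(p$hard_label, c("effect", "no_effect", "effect"))
})
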