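# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# Small KXN dataset: 10 animals x {baseline, 30min} x 3 images = 60 images.
fx_small_ds <- function() fx("small_ds", function() {
  generate_dataset(
    synth_config(animals = c(KXN = 10),
                 times = list(KXN = c("baseline", "30min")),
                 images_per_group = 3, margin = 1.0),
    seed = 11)
})

# Cascades trained on the first 40 images of the small dataset.
fx_detectors <- function() fx("detectors", function() {
  train_face_detectors(fx_small_ds(), n_train = 40, seed = 2)
})

# Independent quantile/metric helpers used as test oracles.
oracle_confusion <- function(pred, lab) {
  c(tp = sum(pred == "effect" & lab == "effect"),
    tn = sum(pred == "no_effect" & lab == "no_effect"),
    fp = sum(pred == "effect" & lab == "no_effect"),
    fn = sum(pred == "no_effect" & lab == "effect"))
}

# A bias-free own-architecture CNN with non-negative output weights (so the
# explained pre-softmax score is non-negative for non-negative inputs).
random_biasfree_cnn <- function(seed, input_size = c(32, 32)) {
  gs <- asNamespace("grimscan")
  m <- gs$nn_init(build_own_cnn(input_size), seed)
  nl <- length(m$layers)
  m$layers <- lapply(seq_along(m$layers), function(i) {
    l <- m$layers[[i]]
    if (!is.null(l$b)) l$b[] <- 0
    if (i == nl) l$W <- abs(l$W)
    l
  })
  m
}
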