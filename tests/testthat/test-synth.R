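# Synthetic face generator: profiles, rendering, dataset assembly.

test_that("time profiles separate effect from no-effect by the margin", {
  eff <- sample_time_profile("KXN", "150min", margin = 1.0)
  base <- sample_time_profile("KXN", "baseline", margin = 1.0)
  expect_true(eff$effect)
  expect_false(base$effect)
  expect_true(all(eff$mean - base$mean >= 1.0 - 1e-12))
  # implied binary label of the (KXN, 150min) profile is "effect"
  expect_identical(assign_binary_label("KXN", "150min"), "effect")

  # untreated animals follow the baseline profile at every time point
  for (tl in treatment_time_grid$untreated) {
    p <- sample_time_profile("untreated", tl, margin = 1.0)
    expect_false(p$effect)
    expect_equal(p$mean, base$mean)
  }

  # margin 0 collapses the two distributions
  e0 <- sample_time_profile("C", "30min", margin = 0)
  b0 <- sample_time_profile("C", "baseline", margin = 0)
  expect_equal(e0$mean, b0$mean)
})

test_that("unknown treatment/time pairs are rejected by name", {
  expect_error(sample_time_profile("IN", "day2"), "IN.*day2")
  expect_error(sample_time_profile("volcano", "30min"), "volcano")
  expect_error(assign_binary_label("KXN", "day99"), "KXN.*day99")
})

test_that("rendering is deterministic and monotone in the action units", {
  id <- animal_identity("m1", "female", "KXN", seed = 3)
  st <- action_unit_state(1, 1, 1, 1, 1)
  r1 <- render_face(id, st, rng_seed = 5)
  r2 <- render_face(id, st, rng_seed = 5)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$geometry, r2$geometry)

  # orbital tightening shrinks the drawn eye opening
  h_at <- function(ot) {
    g <- render_face(id, action_unit_state(orbital_tightening = ot),
                     rng_seed = 5)$geometry
    g$left_eye$y1 - g$left_eye$y0
  }
  expect_lt(h_at(2), h_at(0))

  # ear position displaces the ear boxes
  e_at <- function(ep) {
    render_face(id, action_unit_state(ear_position = ep),
                rng_seed = 5)$geometry$left_ear$y0
  }
  expect_gt(e_at(2), e_at(0))

  # whisker change alters the rendered pixels (strokes rotate)
  w0 <- render_face(id, action_unit_state(whisker_change = 0), rng_seed = 5)
  w2 <- render_face(id, action_unit_state(whisker_change = 2), rng_seed = 5)
  expect_gt(sum(w0$image != w2$image), 0)
})

test_that("every part box is contained in the face box over random renders", {
  for (k in 1:100) {
    id <- animal_identity(sprintf("r%d", k), "male", "C",
                          seed = derive_seed(99, k))
    st <- grimscan:::sample_au_state(
      sample_time_profile("C", "30min"), derive_seed(17, k))
    g <- render_face(id, st, rng_seed = derive_seed(5, k))$geometry
    for (part in c("left_eye", "right_eye", "left_ear", "right_ear", "nose")) {
      b <- g[[part]]
      expect_true(b$x0 >= g$face$x0 && b$x1 <= g$face$x1 &&
                    b$y0 >= g$face$y0 && b$y1 <= g$face$y1,
                  label = sprintf("render %d: %s inside face", k, part))
    }
    # ears above eyes in the rendered pose (centers, y down)
    expect_lt(min((g$left_ear$y0 + g$left_ear$y1) / 2,
                  (g$right_ear$y0 + g$right_ear$y1) / 2),
              min((g$left_eye$y0 + g$left_eye$y1) / 2,
                  (g$right_eye$y0 + g$right_eye$y1) / 2))
  }
})

test_that("a face larger than the frame is rejected with the constraint named", {
  big <- animal_identity("big", "male", "KXN", seed = 1)
  big$identity_params$face_size <- 200
  big$identity_params$ear_size <- 50
  expect_error(render_face(big, action_unit_state()), "does not fit")
})

test_that("generated datasets have the declared shape and determinism", {
  cfg <- synth_config(animals = c(KXN = 4),
                      times = list(KXN = c("baseline", "30min")),
                      images_per_group = 3)
  ds <- generate_dataset(cfg, seed = 7)
  expect_equal(nrow(ds$metadata), 4 * 2 * 3)
  expect_equal(length(unique(ds$metadata$animal_id)), 4)
  expect_equal(nrow(ds$geometry), nrow(ds$metadata))

  ds2 <- generate_dataset(cfg, seed = 7)
  expect_identical(ds$metadata, ds2$metadata)
  expect_identical(ds$images, ds2$images)

  # label column agrees with re-applying the label rule row-wise
  expect_identical(ds$metadata$binary_label,
                   assign_binary_label(ds$metadata$treatment,
                                       ds$metadata$time_label))
})

test_that("identity nuisance persists when the effect margin is zero", {
  cfg <- synth_config(animals = c(KXN = 6),
                      times = list(KXN = c("baseline", "30min")),
                      images_per_group = 3, margin = 0)
  ds <- generate_dataset(cfg, seed = 13)
  mean_int <- tapply(vapply(ds$images, mean, numeric(1))[
    basename(ds$metadata$image_path)], ds$metadata$animal_id, mean)
  # animals differ in overall brightness (fur darkness is per-animal)
  expect_gt(max(mean_int) - min(mean_int), 1)
})

test_that("a larger margin separates classes on drawn eye-opening height", {
  bayes_err <- function(margin) {
    cfg <- synth_config(animals = c(KXN = 8),
                        times = list(KXN = c("baseline", "30min")),
                        images_per_group = 3, margin = margin)
    ds <- generate_dataset(cfg, seed = 29)
    eh <- ds$geometry$left_eye_y1 - ds$geometry$left_eye_y0
    lab <- ds$metadata$binary_label
    # best single threshold on eye height
    thr <- sort(unique(eh))
    errs <- vapply(thr, function(t)
      min(mean((eh <= t) != (lab == "effect")),
          mean((eh > t) != (lab == "effect"))), numeric(1))
    min(errs)
  }
  e0 <- bayes_err(0.2)
  e2 <- bayes_err(1.8)
  expect_lte(e2, e0)
  expect_lt(e2, 0.1)
})

test_that("dataset files round-trip through disk", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(animals = c(IN = 2),
                      times = list(IN = c("baseline", "30min")),
                      images_per_group = 2)
  ds <- generate_dataset(cfg, seed = 3, out_dir = dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "geometry.csv")))
  expect_true(all(file.exists(ds$metadata$image_path)))
  meta <- read_metadata(file.path(dir, "metadata.csv"))
  expect_equal(nrow(meta), 8)
  img <- png::readPNG(ds$metadata$image_path[1])
  expect_equal(dim(img), c(96, 96))
})
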