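# Cascade detection, geometric filtering, two-stage logic, cropping.

test_that("blank images yield no detections and an unaccepted hypothesis", {
  models <- fx_detectors()
  blank <- matrix(200, 96, 96)
  expect_equal(nrow(detect_whole_face(blank, models$face)), 0)
  parts <- detect_parts(blank, models$eye, models$ear)
  expect_equal(nrow(parts$eye_boxes), 0)
  expect_equal(nrow(parts$ear_boxes), 0)
  hyp <- two_stage_detect(blank, models)
  expect_false(hyp$accepted)
})

test_that("detection is deterministic and boxes are ranked with tie-breaks", {
  ds <- fx_small_ds()
  models <- fx_detectors()
  img <- ds$images[[basename(ds$metadata$image_path[45])]]
  b1 <- detect_whole_face(img, models$face)
  b2 <- detect_whole_face(img, models$face)
  expect_identical(b1, b2)
  if (nrow(b1) > 1) expect_true(all(diff(b1$score) <= 1e-12))
})

test_that("part detections overlap the ground-truth geometry", {
  ds <- fx_small_ds()
  models <- fx_detectors()
  hits <- 0
  for (i in 41:50) {
    img <- ds$images[[basename(ds$metadata$image_path[i])]]
    parts <- detect_parts(img, models$eye, models$ear)
    g <- ds$geometry[i, ]
    eye_gt <- list(grimscan:::geometry_box(g, "left_eye"),
                   grimscan:::geometry_box(g, "right_eye"))
    found <- FALSE
    for (k in seq_len(nrow(parts$eye_boxes)))
      for (gt in eye_gt)
        if (box_iou(parts$eye_boxes[k, ], gt) >= 0.3) found <- TRUE
    hits <- hits + found
  }
  expect_gte(hits, 8)
})

test_that("the geometric filter implements R1-R3 with named rejections", {
  rules <- detect_rules()
  eye <- function(cx, cy) bbox(cx - 3, cy - 2, cx + 3, cy + 2, score = 1)
  ear <- function(cx, cy) bbox(cx - 4, cy - 4, cx + 4, cy + 4, score = 1)

  ok <- geometric_filter(rbind(eye(40, 50), eye(60, 50)),
                         rbind(ear(35, 30), ear(65, 30)), rules, 100)
  expect_true(ok$accepted)

  # ears below the eyes violate R1
  r1 <- geometric_filter(rbind(eye(40, 30), eye(60, 30)),
                         rbind(ear(35, 60), ear(65, 60)), rules, 100)
  expect_false(r1$accepted); expect_identical(r1$reason, "R1")

  # far-apart parts violate R2
  r2 <- geometric_filter(eye(50, 95), ear(50, 5), rules, 100)
  expect_false(r2$accepted); expect_identical(r2$reason, "R2")

  # strongly tilted eye pair violates R3
  r3 <- geometric_filter(rbind(eye(40, 50), eye(60, 80)),
                         rbind(ear(35, 30), ear(65, 30)), rules, 100)
  expect_false(r3$accepted); expect_identical(r3$reason, "R3")

  none <- geometric_filter(empty_boxes <- bbox(0, 0, 1, 1)[0, ],
                           bbox(0, 0, 1, 1)[0, ], rules, 100)
  expect_false(none$accepted); expect_identical(none$reason, "no parts")
})

test_that("filter decisions match brute force over a placement grid and mirror", {
  rules <- detect_rules()
  H <- 100
  centers <- expand.grid(ex = seq(10, 90, 20), ey = seq(5, 95, 10),
                         ax = seq(10, 90, 20), ay = seq(5, 95, 10))
  for (i in seq_len(nrow(centers))) {
    p <- centers[i, ]
    eyes <- bbox(p$ex - 3, p$ey - 2, p$ex + 3, p$ey + 2, score = 1)
    ears <- bbox(p$ax - 4, p$ay - 4, p$ax + 4, p$ay + 4, score = 1)
    got <- geometric_filter(eyes, ears, rules, H)$accepted
    # independent brute-force evaluation of R1-R3 on the centers
    d <- sqrt((p$ex - p$ax)^2 + (p$ey - p$ay)^2)
    want <- (p$ay < p$ey) && d >= rules$d_min * H && d <= rules$d_max * H
    expect_identical(got, want,
                     label = sprintf("grid cell %d (eye %d,%d ear %d,%d)",
                                     i, p$ex, p$ey, p$ax, p$ay))
    # mirror invariance: flip x of every box
    meyes <- bbox(100 - (p$ex + 3), p$ey - 2, 100 - (p$ex - 3), p$ey + 2,
                  score = 1)
    mears <- bbox(100 - (p$ax + 4), p$ay - 4, 100 - (p$ax - 4), p$ay + 4,
                  score = 1)
    expect_identical(geometric_filter(meyes, mears, rules, H)$accepted, got)
  }
})

test_that("two-stage detection short-circuits and falls back correctly", {
  ds <- fx_small_ds()
  models <- fx_detectors()
  # an image where stage 1 fires
  img <- ds$images[[basename(ds$metadata$image_path[42])]]
  hyp <- two_stage_detect(img, models)
  expect_true(hyp$accepted)
  if (hyp$source == "whole_face") {
    expect_equal(nrow(hyp$eye_boxes), 0)  # stage 2 never invoked
  }
  # occluded muzzle: stage 1 misses, parts accept
  id <- animal_identity("occ", "male", "KXN", seed = 77)
  st <- action_unit_state(0.5, 0.5, 0.5, 0.5, 0.5)
  r <- render_face(id, st, scene_params(occlusion = 1), rng_seed = 3)
  hyp2 <- two_stage_detect(r$image, models)
  expect_identical(hyp2$source, "parts_fallback")
})

test_that("cropping expands, clips, and is monotone in the margin", {
  img <- matrix(seq_len(100 * 80) / 8000, 100, 80)  # 80 wide, 100 tall
  hyp <- structure(list(accepted = TRUE, face_box = bbox(0, 0, 80, 100)),
                   class = "face_hypothesis")
  expect_identical(crop_to_hypothesis(img, hyp, 0), img)  # identity crop

  corner <- structure(list(accepted = TRUE, face_box = bbox(0, 0, 20, 20)),
                      class = "face_hypothesis")
  cr <- crop_to_hypothesis(img, corner, 0.5)
  expect_lte(nrow(cr), 100); expect_lte(ncol(cr), 80)  # clipped in bounds

  inner <- structure(list(accepted = TRUE, face_box = bbox(30, 30, 50, 50)),
                     class = "face_hypothesis")
  sizes <- vapply(c(0, 0.1, 0.25, 0.5), function(m)
    prod(dim(crop_to_hypothesis(img, inner, m))), numeric(1))
  expect_true(all(diff(sizes) >= 0))  # larger margin never shrinks the crop

  bad <- structure(list(accepted = FALSE, face_box = NULL),
                   class = "face_hypothesis")
  expect_error(crop_to_hypothesis(img, bad), "no face to crop")
})

test_that("crops at moderate margins contain all ground-truth parts", {
  ds <- fx_small_ds()
  for (i in c(5, 25, 50)) {
    g <- ds$geometry[i, ]
    img <- ds$images[[basename(ds$metadata$image_path[i])]]
    hyp <- structure(list(accepted = TRUE,
                          face_box = grimscan:::geometry_box(g, "face")),
                     class = "face_hypothesis")
    cr <- crop_to_hypothesis(img, hyp, 0.1)
    fw <- g$face_x1 - g$face_x0; fh <- g$face_y1 - g$face_y0
    expect_gte(nrow(cr), fh); expect_gte(ncol(cr), fw)
  }
})

test_that("cascade models survive an XML round-trip", {
  models <- fx_detectors()
  path <- withr::local_tempfile(fileext = ".xml")
  write_cascade_xml(models$face, path)
  back <- read_cascade_xml(path)
  expect_equal(back$window, models$face$window)
  expect_equal(back$ncc_threshold, models$face$ncc_threshold)
  expect_equal(back$template, models$face$template, tolerance = 1e-8)
  # identical detections through the reloaded model
  ds <- fx_small_ds()
  img <- ds$images[[basename(ds$metadata$image_path[7])]]
  expect_equal(detect_whole_face(img, models$face),
               detect_whole_face(img, back), tolerance = 1e-8)
  expect_error(read_cascade_xml("missing/cascade.xml"), "missing/cascade.xml")
})
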