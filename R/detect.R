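# Two-stage face localization: whole-face cascade detection with an eye/ear
# part-detection fall-back filtered by geometric plausibility heuristics.

#' Detection heuristic rules
#'
#' R1: the ears must be above the eyes (box center-y, y increasing
#' downward). R2: the closest ear-eye center distance must lie within
#' `[d_min, d_max]` fractions of image height. R3: if two eyes are present,
#' their center-y difference must not exceed `tol` of image height. Only R1
#' is dictated by the underlying heuristic literature; R2/R3 defaults are
#' conservative completions and fully configurable.
#'
#' @param d_min,d_max,tol Fractions of image height.
#' @param fallback_expand Width/height expansion applied to the tight box
#'   around accepted parts when synthesizing a face box in the fall-back
#'   path (`h` extends downward over the unobserved muzzle).
#' @return A `detect_rules` list.
#' @export
detect_rules <- function(d_min = 0.05, d_max = 0.6, tol = 0.15,
                         fallback_expand = list(w = 1.2, h = 2.0)) {
  structure(list(d_min = d_min, d_max = d_max, tol = tol,
                 fallback_expand = fallback_expand), class = "detect_rules")
}

#' Whole-face cascade detection
#'
#' Multi-scale sliding-window detection with the whole-face cascade; boxes
#' come back sorted by score descending (ties: larger area, then smaller
#' `(x0, y0)`), possibly empty.
#'
#' @param image Grayscale matrix.
#' @param cascade_model A `haar_cascade` or path to its XML file.
#' @param ... Passed to [detect_cascade()].
#' @return Box data frame.
#' @export
detect_whole_face <- function(image, cascade_model, ...) {
  detect_cascade(image, cascade_model, ...)
}

#' Eye and ear part detection
#'
#' Runs the two part detectors independently; occlusion of one part class
#' never affects the other's detections.
#'
#' @param image Grayscale matrix.
#' @param eye_model,ear_model Cascades or XML paths.
#' @param eye_sizes,ear_sizes `c(min, max)` object sizes in px.
#' @return List with `eye_boxes` and `ear_boxes`.
#' @export
detect_parts <- function(image, eye_model, ear_model,
                         eye_sizes = c(6, 14), ear_sizes = c(8, 18)) {
  list(eye_boxes = detect_cascade(image, eye_model, min_size = eye_sizes[1],
                                  max_size = eye_sizes[2], stride = 1),
       ear_boxes = detect_cascade(image, ear_model, min_size = ear_sizes[1],
                                  max_size = ear_sizes[2], stride = 1))
}

#' Geometric plausibility filter for part groups
#'
#' Selects up to the two highest-scoring eye boxes and two highest-scoring
#' ear boxes, then applies rules R1-R3 (see [detect_rules()]). The result
#' names the first violated rule; with neither eyes nor ears the reason is
#' `"no parts"`.
#'
#' @param eye_boxes,ear_boxes Box data frames in the same image frame.
#' @param rules A [detect_rules()].
#' @param image_height Image height in px (reference for the fractions).
#' @return List: `accepted` (logical), `reason` (`NA` if accepted),
#'   `eyes`, `ears` (the boxes the decision used).
#' @export
geometric_filter <- function(eye_boxes, ear_boxes, rules = detect_rules(),
                             image_height) {
  if (nrow(eye_boxes) == 0 && nrow(ear_boxes) == 0)
    return(list(accepted = FALSE, reason = "no parts",
                eyes = eye_boxes, ears = ear_boxes))
  top <- function(b, n) {
    if (nrow(b) == 0) return(b)
    b[order(-ifelse(is.na(b$score), 0, b$score), b$x0, b$y0), ][
      seq_len(min(n, nrow(b))), , drop = FALSE]
  }
  eyes <- top(eye_boxes, 2); ears <- top(ear_boxes, 2)
  reject <- function(r) list(accepted = FALSE, reason = r,
                             eyes = eyes, ears = ears)
  if (nrow(eyes) == 0 || nrow(ears) == 0) return(reject("R1"))
  eye_cy <- (eyes$y0 + eyes$y1) / 2; ear_cy <- (ears$y0 + ears$y1) / 2
  if (!(min(ear_cy) < min(eye_cy))) return(reject("R1"))
  eye_cx <- (eyes$x0 + eyes$x1) / 2; ear_cx <- (ears$x0 + ears$x1) / 2
  d <- sqrt(outer(ear_cx, eye_cx, "-")^2 + outer(ear_cy, eye_cy, "-")^2)
  dmin <- min(d)
  if (dmin < rules$d_min * image_height || dmin > rules$d_max * image_height)
    return(reject("R2"))
  if (nrow(eyes) == 2 && abs(eye_cy[1] - eye_cy[2]) > rules$tol * image_height)
    return(reject("R3"))
  list(accepted = TRUE, reason = NA_character_, eyes = eyes, ears = ears)
}

#' Two-stage face detection
#'
#' Stage 1 runs the whole-face cascade; if it yields any box, the
#' top-scoring one becomes the hypothesis and stage 2 is never invoked.
#' Otherwise the eye/ear part detectors run and the geometric filter
#' decides; an accepted part group is converted to a face box by expanding
#' the tight box around the parts (see [detect_rules()]).
#'
#' @param image Grayscale matrix.
#' @param models List with `face`, `eye`, `ear` cascades (or XML paths).
#' @param rules A [detect_rules()].
#' @param face_sizes `c(min, max)` face sizes for stage 1.
#' @return A `face_hypothesis`: `face_box` (or `NULL`), `eye_boxes`,
#'   `ear_boxes`, `source` (`"whole_face"`/`"parts_fallback"`), `accepted`,
#'   `reason`.
#' @export
two_stage_detect <- function(image, models, rules = detect_rules(),
                             face_sizes = c(28, 72)) {
  faces <- detect_whole_face(image, models$face, min_size = face_sizes[1],
                             max_size = face_sizes[2])
  if (nrow(faces) > 0) {
    return(structure(list(face_box = faces[1, , drop = FALSE],
                          eye_boxes = empty_boxes(), ear_boxes = empty_boxes(),
                          source = "whole_face", accepted = TRUE,
                          reason = NA_character_), class = "face_hypothesis"))
  }
  parts <- detect_parts(image, models$eye, models$ear)
  gf <- geometric_filter(parts$eye_boxes, parts$ear_boxes, rules,
                         image_height = nrow(image))
  face_box <- NULL
  if (gf$accepted) {
    px0 <- min(gf$eyes$x0, gf$ears$x0); px1 <- max(gf$eyes$x1, gf$ears$x1)
    py0 <- min(gf$eyes$y0, gf$ears$y0); py1 <- max(gf$eyes$y1, gf$ears$y1)
    cx <- (px0 + px1) / 2
    w <- (px1 - px0) * rules$fallback_expand$w
    h <- (py1 - py0) * rules$fallback_expand$h
    face_box <- clip_box(bbox(cx - w / 2, py0, cx + w / 2, py0 + h),
                         ncol(image), nrow(image))
  }
  structure(list(face_box = face_box, eye_boxes = parts$eye_boxes,
                 ear_boxes = parts$ear_boxes, source = "parts_fallback",
                 accepted = gf$accepted, reason = gf$reason),
            class = "face_hypothesis")
}

#' Crop an image to an accepted face hypothesis
#'
#' The face box is expanded by `margin_frac` of its width/height on each
#' side and clipped to the image; enlarging the margin never shrinks the
#' crop.
#'
#' @param image Grayscale matrix.
#' @param hypothesis A `face_hypothesis` from [two_stage_detect()].
#' @param margin_frac Non-negative expansion fraction.
#' @return The cropped matrix.
#' @export
crop_to_hypothesis <- function(image, hypothesis, margin_frac = 0.1) {
  if (!isTRUE(hypothesis$accepted) || is.null(hypothesis$face_box))
    stop("no face to crop", call. = FALSE)
  stopifnot(margin_frac >= 0)
  b <- hypothesis$face_box
  mw <- margin_frac * (b$x1 - b$x0); mh <- margin_frac * (b$y1 - b$y0)
  b <- clip_box(bbox(b$x0 - mw, b$y0 - mh, b$x1 + mw, b$y1 + mh),
                ncol(image), nrow(image))
  crop_box(image, b)
}

# Extract the pixels of a (half-open, 0-based) box.
crop_box <- function(image, b) {
  rows <- (floor(b$y0) + 1):ceiling(b$y1)
  cols <- (floor(b$x0) + 1):ceiling(b$x1)
  image[rows[rows >= 1 & rows <= nrow(image)],
        cols[cols >= 1 & cols <= ncol(image)], drop = FALSE]
}

# ---- training-data preparation on synthetic renders ------------------------

geometry_box <- function(geometry_row, part) {
  bbox(geometry_row[[paste0(part, "_x0")]], geometry_row[[paste0(part, "_y0")]],
       geometry_row[[paste0(part, "_x1")]], geometry_row[[paste0(part, "_y1")]])
}

# Positive and negative crops for one part class from generated images.
# Negatives mix random background windows with hard off-center crops
# (shifted copies of the part box), which teaches the boosted stages to
# prefer centered detections instead of firing on any dark blob.
prepare_part_crops <- function(images, geometry, parts, n_neg = 3, seed = 1,
                               context = 0.1) {
  pos <- list(); neg <- list()
  for (i in seq_len(nrow(geometry))) {
    img <- images[[basename(geometry$image_path[i])]]
    H <- nrow(img); W <- ncol(img)
    part_boxes <- lapply(parts, function(p) geometry_box(geometry[i, ], p))
    for (b in part_boxes) {
      mw <- context * (b$x1 - b$x0); mh <- context * (b$y1 - b$y0)
      bb <- clip_box(bbox(b$x0 - mw, b$y0 - mh, b$x1 + mw, b$y1 + mh), W, H)
      pos[[length(pos) + 1L]] <- crop_box(img, bb)
    }
    sz0 <- mean(vapply(part_boxes, function(b)
      mean(c(b$x1 - b$x0, b$y1 - b$y0)), numeric(1)))
    negs <- with_seed(derive_seed(seed, "neg", i), {
      out <- list()
      # hard negatives: the part box shifted by half to one box size
      for (b in part_boxes) {
        for (k in 1:2) {
          ang <- runif(1, 0, 2 * pi); shift <- sz0 * runif(1, 0.5, 1.0)
          cand <- clip_box(bbox(b$x0 + shift * cos(ang),
                                b$y0 + shift * sin(ang),
                                b$x1 + shift * cos(ang),
                                b$y1 + shift * sin(ang)), W, H)
          if (cand$x1 - cand$x0 >= 4 && cand$y1 - cand$y0 >= 4 &&
              all(vapply(part_boxes, function(pb) box_iou(cand, pb) < 0.35,
                         logical(1))))
            out[[length(out) + 1L]] <- crop_box(img, cand)
        }
      }
      tries <- 0
      while (length(out) < n_neg && tries < 50) {
        tries <- tries + 1
        sz <- sz0 * runif(1, 0.7, 1.4)
        x0 <- runif(1, 0, W - sz); y0 <- runif(1, 0, H - sz)
        cand <- bbox(x0, y0, x0 + sz, y0 + sz)
        if (all(vapply(part_boxes, function(b) box_iou(cand, b) < 0.05,
                       logical(1))))
          out[[length(out) + 1L]] <- crop_box(img, cand)
      }
      out
    })
    neg <- c(neg, negs)
  }
  list(positives = pos, negatives = neg)
}

#' Train the whole-face, eye, and ear cascades on synthetic renders
#'
#' Convenience wrapper over [train_cascade()]: crops positives from the
#' generator's ground-truth geometry and negatives from non-overlapping
#' random windows of the same images.
#'
#' @param dataset A [generate_dataset()] result with in-memory images.
#' @param n_train Number of images used for crop extraction.
#' @param seed Integer seed.
#' @return List of cascades: `face`, `eye`, `ear`.
#' @export
train_face_detectors <- function(dataset, n_train = 60, seed = 1) {
  idx <- seq_len(min(n_train, nrow(dataset$geometry)))
  geo <- dataset$geometry[idx, , drop = FALSE]
  face <- prepare_part_crops(dataset$images, geo, "face", n_neg = 6,
                             seed = derive_seed(seed, "face"))
  eye <- prepare_part_crops(dataset$images, geo, c("left_eye", "right_eye"),
                            n_neg = 6, seed = derive_seed(seed, "eye"))
  ear <- prepare_part_crops(dataset$images, geo, c("left_ear", "right_ear"),
                            n_neg = 6, seed = derive_seed(seed, "ear"))
  list(face = train_cascade(face$positives, face$negatives, window = 24,
                            stumps = c(10, 40), seed = derive_seed(seed, "cf")),
       eye = train_cascade(eye$positives, eye$negatives, window = 8,
                           stumps = c(8, 25), seed = derive_seed(seed, "ce")),
       ear = train_cascade(ear$positives, ear$negatives, window = 12,
                           stumps = c(8, 25), seed = derive_seed(seed, "cr")))
}

#' Run two-stage detection over a dataset
#'
#' Appends detection results (`face_x0..face_y1`, `source`, `accepted`) to
#' the metadata table.
#'
#' @param dataset A [generate_dataset()] result (in-memory images) or a
#'   list with `metadata` plus readable `image_path`s.
#' @param models Cascades from [train_face_detectors()].
#' @param rules A [detect_rules()].
#' @param ... Passed to [two_stage_detect()].
#' @return The metadata data frame with detection columns added.
#' @export
detect_dataset <- function(dataset, models, rules = detect_rules(), ...) {
  meta <- dataset$metadata
  res <- lapply(seq_len(nrow(meta)), function(i) {
    img <- if (!is.null(dataset$images))
      dataset$images[[basename(meta$image_path[i])]]
    else {
      m <- png::readPNG(meta$image_path[i]); m * 255
    }
    hyp <- two_stage_detect(img, models, rules, ...)
    data.frame(face_x0 = if (is.null(hyp$face_box)) NA_real_ else hyp$face_box$x0,
               face_y0 = if (is.null(hyp$face_box)) NA_real_ else hyp$face_box$y0,
               face_x1 = if (is.null(hyp$face_box)) NA_real_ else hyp$face_box$x1,
               face_y1 = if (is.null(hyp$face_box)) NA_real_ else hyp$face_box$y1,
               source = hyp$source, accepted = hyp$accepted,
               stringsAsFactors = FALSE)
  })
  cbind(meta, do.call(rbind, res))
}
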