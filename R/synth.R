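# Synthetic mouse-face image generator.
#
# Emulates the structure of the study data: dark-furred faces on a light cage
# background, per-animal image series over a treatment-specific grid of
# acquisition time points, and treatment/time-dependent latent intensities of
# the five grimace-scale action units. Rendering is primitive-based (filled
# ellipses, line strokes, blur, noise); photorealism is a non-goal — the
# generator exists so every downstream stage is testable with known ground
# truth geometry and labels.

#' Names of the five grimace-scale action units
#' @export
mgs_action_units <- c("orbital_tightening", "nose_bulge", "cheek_bulge",
                      "ear_position", "whisker_change")

#' Acquisition time grid per treatment
#'
#' Baseline plus the post-procedure points at which each treatment group was
#' imaged. Untreated animals share the union grid of the treated groups.
#' @export
treatment_time_grid <- list(
  IN  = c("baseline", "30min", "150min"),
  KXN = c("baseline", "30min", "150min", "day2", "day9"),
  C   = c("baseline", "30min", "150min", "300min", "day2", "day3", "day7"),
  untreated = c("baseline", "30min", "150min", "300min", "day2", "day3",
                "day7", "day9")
)

# Time points labelled "effect" per treatment (the binary label rule).
effect_time_points <- list(
  IN  = "30min",
  KXN = c("30min", "150min"),
  C   = c("30min", "150min", "300min"),
  untreated = character(0)
)

check_treatment_time <- function(treatment, time_label) {
  if (!treatment %in% names(treatment_time_grid))
    stop("unknown treatment: '", treatment, "'", call. = FALSE)
  if (!time_label %in% treatment_time_grid[[treatment]])
    stop("unknown treatment/time combination: ('", treatment, "', '",
         time_label, "')", call. = FALSE)
  invisible(TRUE)
}

#' Latent action-unit distribution for a treatment at a time point
#'
#' Returns the per-unit mean and standard deviation of the truncated-Gaussian
#' latent intensities used by the generator. Time points carrying the
#' post-anesthetic/surgical effect get their means raised by `margin` above
#' the baseline mean; untreated animals follow the baseline profile at every
#' time point.
#'
#' @param treatment One of `"IN"`, `"KXN"`, `"C"`, `"untreated"`.
#' @param time_label A time label from [treatment_time_grid].
#' @param margin Mean shift (intensity units) between effect and no-effect
#'   time points. Default 1.0, giving clearly separated classes; 0 makes the
#'   two distributions identical.
#' @param baseline_mean Baseline mean intensity per action unit.
#' @param unit_sd Per-unit standard deviation before truncation to `[0, 2]`.
#' @param signature Length-5 non-negative weights distributing the margin
#'   over the action units (order of [mgs_action_units]); lets different
#'   treatments express distinct facial signatures. Default: all units
#'   shifted equally.
#' @return List with named numeric vectors `mean` and `sd` over the five
#'   action units, and logical `effect`.
#' @export
sample_time_profile <- function(treatment, time_label, margin = 1.0,
                                baseline_mean = 0.25, unit_sd = 0.2,
                                signature = rep(1, 5)) {
  check_treatment_time(treatment, time_label)
  stopifnot(length(signature) == 5, all(signature >= 0))
  effect <- time_label %in% effect_time_points[[treatment]]
  mu <- baseline_mean + if (effect) margin * signature else rep(0, 5)
  names(mu) <- mgs_action_units
  list(mean = mu,
       sd = setNames(rep(unit_sd, 5), mgs_action_units),
       effect = effect)
}

#' Construct an action-unit state
#'
#' @param orbital_tightening,nose_bulge,cheek_bulge,ear_position,whisker_change
#'   Latent intensities, each in `[0, 2]` (continuous analogue of the human
#'   0/1/2 scoring scale).
#' @return An `au_state` list with the five intensities and their mean
#'   (`mean_score`).
#' @export
action_unit_state <- function(orbital_tightening = 0, nose_bulge = 0,
                              cheek_bulge = 0, ear_position = 0,
                              whisker_change = 0) {
  v <- c(orbital_tightening = orbital_tightening, nose_bulge = nose_bulge,
         cheek_bulge = cheek_bulge, ear_position = ear_position,
         whisker_change = whisker_change)
  stopifnot(all(v >= 0), all(v <= 2))
  structure(c(as.list(v), list(mean_score = mean(v))), class = "au_state")
}

# Draw an action-unit state from a profile, truncating to [0, 2].
sample_au_state <- function(profile, seed) {
  with_seed(seed, {
    v <- rnorm(5, profile$mean, profile$sd)
    v <- pmin(pmax(v, 0), 2)
    do.call(action_unit_state, as.list(setNames(v, mgs_action_units)))
  })
}

#' Scene (rendering) parameters
#'
#' @param image_size `c(height, width)` in pixels, at least 64 each.
#' @param background_brightness Cage-wall brightness in `[0, 1]` (light, to
#'   contrast the dark fur).
#' @param pose_jitter List with `translate` (max abs translation, px) and
#'   `rotate` (max abs rotation, degrees) applied per image.
#' @param blur_sigma Gaussian blur sigma in px.
#' @param pellet_count Number of food-pellet distractors rendered near the
#'   cage floor.
#' @param noise_sd Additive Gaussian pixel noise sd (on the `[0, 1]` scale).
#' @param occlusion Probability that a render hides the muzzle behind a
#'   bedding-colored block (the mouse digging or sitting behind litter):
#'   eyes and ears stay visible, the whole-face appearance is broken.
#' @return A `scene_params` list.
#' @export
scene_params <- function(image_size = c(96, 96), background_brightness = 0.82,
                         pose_jitter = list(translate = 4, rotate = 6),
                         blur_sigma = 0.7, pellet_count = 2, noise_sd = 0.02,
                         occlusion = 0) {
  stopifnot(length(image_size) == 2, all(image_size >= 64),
            background_brightness >= 0, background_brightness <= 1,
            pose_jitter$translate >= 0, pose_jitter$rotate >= 0,
            blur_sigma >= 0, pellet_count >= 0, noise_sd >= 0, noise_sd <= 1,
            occlusion >= 0, occlusion <= 1)
  structure(list(image_size = as.integer(image_size),
                 background_brightness = background_brightness,
                 pose_jitter = pose_jitter, blur_sigma = blur_sigma,
                 pellet_count = as.integer(pellet_count), noise_sd = noise_sd,
                 occlusion = occlusion),
            class = "scene_params")
}

#' Sample a per-animal identity
#'
#' Identity nuisance parameters (face size, fur darkness, eye spacing, ear
#' size, baseline whisker angle) are fixed across all images of one animal,
#' so subject-disjoint splitting is a meaningful test: even with effect
#' margin 0 the images carry an identity signal.
#'
#' @param animal_id Unique id string.
#' @param sex `"female"` or `"male"`.
#' @param treatment Treatment group.
#' @param seed Integer seed (derive with [derive_seed()] for reproducible
#'   subsets).
#' @return An `animal_identity` list.
#' @export
animal_identity <- function(animal_id, sex = c("female", "male"),
                            treatment = "KXN", seed = 1) {
  sex <- match.arg(sex)
  if (!treatment %in% names(treatment_time_grid))
    stop("unknown treatment: '", treatment, "'", call. = FALSE)
  with_seed(seed, {
    p <- list(face_size = runif(1, 34, 44),
              fur_darkness = runif(1, 0.70, 0.95),
              eye_spacing = NA_real_,
              ear_size = NA_real_,
              whisker_angle = runif(1, -10, 10))
    p$eye_spacing <- p$face_size * runif(1, 0.42, 0.52)
    p$ear_size <- p$face_size * runif(1, 0.22, 0.30)
    structure(list(animal_id = animal_id, sex = sex, treatment = treatment,
                   identity_params = p), class = "animal_identity")
  })
}

# ---- rendering primitives ---------------------------------------------------

draw_ellipse <- function(img, cx, cy, rx, ry, value) {
  h <- nrow(img); w <- ncol(img)
  xs <- seq_len(w) - 0.5; ys <- seq_len(h) - 0.5
  cs <- which(xs >= cx - rx - 1 & xs <= cx + rx + 1)
  rs <- which(ys >= cy - ry - 1 & ys <= cy + ry + 1)
  if (!length(cs) || !length(rs)) return(img)
  m <- outer(((ys[rs] - cy) / ry)^2, ((xs[cs] - cx) / rx)^2, "+") <= 1
  sub <- img[rs, cs, drop = FALSE]
  sub[m] <- value
  img[rs, cs] <- sub
  img
}

draw_stroke <- function(img, x0, y0, x1, y1, value) {
  n <- max(2L, ceiling(2 * sqrt((x1 - x0)^2 + (y1 - y0)^2)))
  t <- seq(0, 1, length.out = n)
  cc <- pmin(pmax(ceiling(x0 + t * (x1 - x0)), 1L), ncol(img))
  rr <- pmin(pmax(ceiling(y0 + t * (y1 - y0)), 1L), nrow(img))
  img[cbind(rr, cc)] <- value
  img
}

ellipse_box <- function(cx, cy, rx, ry) {
  bbox(floor(cx - rx), floor(cy - ry), ceiling(cx + rx), ceiling(cy + ry))
}

rot2 <- function(xy, deg) {
  a <- deg * pi / 180
  c(cos(a) * xy[1] - sin(a) * xy[2], sin(a) * xy[1] + cos(a) * xy[2])
}

#' Render one synthetic mouse-face image
#'
#' Pure function of its arguments: the same identity, state, scene, and seed
#' always produce a bitwise-identical image. Orbital tightening shrinks the
#' drawn eye opening, ear position displaces the ear ellipses downward and
#' outward, nose bulge enlarges the nose, cheek bulge brightens the cheek
#' patches, and whisker change rotates the whisker strokes.
#'
#' @param identity An [animal_identity()].
#' @param state An [action_unit_state()].
#' @param scene A [scene_params()].
#' @param rng_seed Integer seed controlling pose jitter and noise.
#' @return List with `image` (H x W matrix of integers in 0..255) and
#'   `geometry` (list of ground-truth boxes: `face`, `left_eye`, `right_eye`,
#'   `left_ear`, `right_ear`, `nose`; 0-based half-open pixel coordinates).
#' @export
render_face <- function(identity, state, scene = scene_params(), rng_seed = 1) {
  stopifnot(inherits(identity, "animal_identity"), inherits(state, "au_state"),
            inherits(scene, "scene_params"))
  H <- scene$image_size[1]; W <- scene$image_size[2]
  p <- identity$identity_params
  s <- p$face_size / 2
  ear_r <- p$ear_size / 2
  # full extent including ears; must fit in the frame
  extent <- 2 * max(s, 0.88 * s + 2 * ear_r) + 2
  if (extent > min(H, W))
    stop("face does not fit: required extent ", round(extent, 1),
         " px exceeds image size ", min(H, W), " px", call. = FALSE)

  with_seed(rng_seed, {
    jt <- scene$pose_jitter
    tx <- runif(1, -jt$translate, jt$translate)
    ty <- runif(1, -jt$translate, jt$translate)
    rot <- runif(1, -jt$rotate, jt$rotate)
    # clamp the centre so the whole face (incl. ears) stays in frame
    half <- extent / 2
    cx <- min(max(W / 2 + tx, half), W - half)
    cy <- min(max(H / 2 + ty, half), H - half)

    img <- matrix(scene$background_brightness, H, W)
    # floor shading and pellet distractors
    img[ceiling(0.9 * H):H, ] <- scene$background_brightness - 0.12
    if (scene$pellet_count > 0) {
      for (i in seq_len(scene$pellet_count)) {
        px <- runif(1, 0.1 * W, 0.9 * W); py <- runif(1, 0.9 * H, 0.98 * H)
        img <- draw_ellipse(img, px, py, runif(1, 1.5, 3), runif(1, 1, 2), 0.35)
      }
    }

    fur <- 1 - p$fur_darkness   # dark fur intensity
    at <- function(off) { d <- rot2(off, rot); c(cx + d[1], cy + d[2]) }

    # ears (drawn before head so inner halves merge into the head outline)
    ear_dx <- 0.62 * s + 0.06 * s * state$ear_position
    ear_dy <- -0.88 * s + 0.07 * s * state$ear_position
    le <- at(c(-ear_dx, ear_dy)); re <- at(c(ear_dx, ear_dy))
    img <- draw_ellipse(img, le[1], le[2], ear_r, ear_r, fur + 0.10)
    img <- draw_ellipse(img, re[1], re[2], ear_r, ear_r, fur + 0.10)
    # head
    img <- draw_ellipse(img, cx, cy, s, 0.92 * s, fur)
    # cheek patches brighten with cheek bulge
    chv <- fur + 0.05 + 0.10 * state$cheek_bulge
    lc <- at(c(-0.45 * s, 0.30 * s)); rc <- at(c(0.45 * s, 0.30 * s))
    img <- draw_ellipse(img, lc[1], lc[2], 0.22 * s, 0.16 * s, chv)
    img <- draw_ellipse(img, rc[1], rc[2], 0.22 * s, 0.16 * s, chv)
    # eyes: opening height shrinks with orbital tightening; bright glint
    eye_w <- 0.15 * s
    eye_h <- 0.14 * s * (1 - 0.40 * state$orbital_tightening)
    lye <- at(c(-p$eye_spacing / 2, -0.18 * s))
    rye <- at(c(p$eye_spacing / 2, -0.18 * s))
    img <- draw_ellipse(img, lye[1], lye[2], eye_w, eye_h, 0.02)
    img <- draw_ellipse(img, rye[1], rye[2], eye_w, eye_h, 0.02)
    img <- draw_ellipse(img, lye[1], lye[2], 0.4 * eye_w, 0.6 * eye_h, 0.95)
    img <- draw_ellipse(img, rye[1], rye[2], 0.4 * eye_w, 0.6 * eye_h, 0.95)
    # nose, enlarged and brightened by nose bulge
    nr <- 0.10 * s * (1 + 0.35 * state$nose_bulge)
    no <- at(c(0, 0.58 * s))
    img <- draw_ellipse(img, no[1], no[2], nr, 0.8 * nr,
                        0.55 + 0.10 * state$nose_bulge)
    # whiskers rotate with whisker change
    for (side in c(-1, 1)) {
      pad <- at(c(side * 0.25 * s, 0.42 * s))
      for (base in c(8, 22, 36)) {
        ang <- side * (base + p$whisker_angle + 9 * state$whisker_change) + rot * side
        len <- 0.95 * s
        dx <- side * len * cos(ang * pi / 180)
        dy <- len * sin(ang * pi / 180) * 0.35
        img <- draw_stroke(img, pad[1], pad[2], pad[1] + dx, pad[2] + dy, 0.88)
      }
    }

    if (!is.null(scene$occlusion) && scene$occlusion > 0 &&
        runif(1) < scene$occlusion) {
      # bedding block hides the muzzle; eyes and ears stay visible
      occ_top <- cy + 0.08 * s
      rr <- ceiling(occ_top):H
      img[rr, ] <- scene$background_brightness - 0.18 +
        matrix(runif(length(rr) * W, -0.04, 0.04), length(rr), W)
    }
    if (scene$blur_sigma > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = scene$blur_sigma))
    if (scene$noise_sd > 0)
      img <- img + matrix(rnorm(H * W, 0, scene$noise_sd), H, W)
    img <- matrix(as.integer(round(pmin(pmax(img, 0), 1) * 255)), H, W)

    geom <- list(
      left_eye  = ellipse_box(lye[1], lye[2], eye_w, eye_h),
      right_eye = ellipse_box(rye[1], rye[2], eye_w, eye_h),
      left_ear  = ellipse_box(le[1], le[2], ear_r, ear_r),
      right_ear = ellipse_box(re[1], re[2], ear_r, ear_r),
      nose      = ellipse_box(no[1], no[2], nr, 0.8 * nr)
    )
    head_box <- ellipse_box(cx, cy, s, 0.92 * s)
    face <- bbox(min(head_box$x0, geom$left_ear$x0, geom$right_ear$x0),
                 min(head_box$y0, geom$left_ear$y0, geom$right_ear$y0),
                 max(head_box$x1, geom$left_ear$x1, geom$right_ear$x1),
                 max(head_box$y1, geom$left_ear$y1, geom$right_ear$y1))
    geom <- c(list(face = clip_box(face, W, H)),
              lapply(geom, clip_box, width = W, height = H))
    list(image = img, geometry = geom)
  })
}

# ---- dataset generation -----------------------------------------------------

#' Synthetic dataset configuration
#'
#' Defaults mirror the study's group structure: animal counts per treatment
#' (52 isoflurane, 48 ketamine/xylazine, 19 castration, 26 untreated; the
#' castration group all male), the full acquisition time grid of each
#' treatment, and an effect margin of 1.0 latent units between classes.
#'
#' @param animals Named integer vector: number of animals per treatment.
#' @param female_fraction Named numeric vector: fraction of females per
#'   treatment.
#' @param times Named list of time labels per treatment; default the full
#'   grid of each treatment.
#' @param images_per_group Images per (animal, time point) series.
#' @param margin,baseline_mean,unit_sd Latent-profile parameters, see
#'   [sample_time_profile()].
#' @param signatures Optional named list of length-5 action-unit weight
#'   vectors, one per treatment, giving treatments distinct facial
#'   signatures (see [sample_time_profile()]).
#' @param scene A [scene_params()].
#' @return A `synth_config` list.
#' @export
synth_config <- function(animals = c(IN = 52, KXN = 48, C = 19, untreated = 26),
                         female_fraction = c(IN = 0.5, KXN = 22 / 48, C = 0,
                                             untreated = 0.5),
                         times = NULL, images_per_group = 5,
                         margin = 1.0, baseline_mean = 0.25, unit_sd = 0.2,
                         signatures = NULL, scene = scene_params()) {
  stopifnot(all(animals >= 1), images_per_group >= 1,
            all(names(animals) %in% names(treatment_time_grid)))
  if (is.null(times)) times <- treatment_time_grid[names(animals)]
  stopifnot(all(names(animals) %in% names(times)))
  if (!is.null(signatures))
    stopifnot(all(names(animals) %in% names(signatures)))
  structure(list(animals = animals, female_fraction = female_fraction,
                 times = times, images_per_group = as.integer(images_per_group),
                 margin = margin, baseline_mean = baseline_mean,
                 unit_sd = unit_sd, signatures = signatures, scene = scene),
            class = "synth_config")
}

#' Generate a synthetic face-image dataset
#'
#' One identity per animal; per (animal, time point) the requested number of
#' images with independent pose jitter and per-image latent action-unit draws
#' around that animal/time profile. The binary label column is filled by
#' [assign_binary_label()]. The global seed fans out to per-animal and
#' per-image sub-seeds by stable hashing, so identical `(config, seed)` give
#' identical datasets.
#'
#' @param config A [synth_config()].
#' @param seed Global integer seed.
#' @param out_dir Output directory. If `NULL` (default), images are returned
#'   in memory as `$images` (named list of matrices) instead of written as
#'   PNG files.
#' @return List with `metadata` (data.frame: image_path, animal_id, sex,
#'   treatment, time_label, binary_label, mean_latent_score, one column per
#'   action unit), `geometry` (data.frame of ground-truth boxes per image),
#'   and `images` (when `out_dir` is `NULL`).
#' @export
generate_dataset <- function(config = synth_config(), seed = 1,
                             out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  write_files <- !is.null(out_dir)
  if (write_files) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  meta <- list(); geom_rows <- list(); images <- list()
  for (tr in names(config$animals)) {
    n_a <- config$animals[[tr]]
    n_f <- round(config$female_fraction[[tr]] * n_a)
    for (a in seq_len(n_a)) {
      aid <- sprintf("%s_%03d", tr, a)
      sex <- if (a <= n_f) "female" else "male"
      ident <- animal_identity(aid, sex, tr,
                               seed = derive_seed(seed, "animal", aid))
      sig <- if (!is.null(config$signatures)) config$signatures[[tr]]
             else rep(1, 5)
      for (tl in config$times[[tr]]) {
        prof <- sample_time_profile(tr, tl, margin = config$margin,
                                    baseline_mean = config$baseline_mean,
                                    unit_sd = config$unit_sd,
                                    signature = sig)
        for (i in seq_len(config$images_per_group)) {
          sub <- derive_seed(seed, "image", aid, tl, i)
          st <- sample_au_state(prof, derive_seed(sub, "au"))
          r <- render_face(ident, st, config$scene,
                           rng_seed = derive_seed(sub, "render"))
          img_name <- sprintf("%s_%s_%02d.png", aid, tl, i)
          path <- if (write_files) file.path(out_dir, img_name) else img_name
          if (write_files) png::writePNG(r$image / 255, path)
          else images[[img_name]] <- r$image
          meta[[length(meta) + 1L]] <- data.frame(
            image_path = path, animal_id = aid, sex = sex, treatment = tr,
            time_label = tl,
            binary_label = assign_binary_label(tr, tl),
            mean_latent_score = st$mean_score,
            orbital_tightening = st$orbital_tightening,
            nose_bulge = st$nose_bulge, cheek_bulge = st$cheek_bulge,
            ear_position = st$ear_position,
            whisker_change = st$whisker_change,
            stringsAsFactors = FALSE)
          g <- r$geometry
          row <- data.frame(image_path = path, stringsAsFactors = FALSE)
          for (part in names(g))
            for (cc in c("x0", "y0", "x1", "y1"))
              row[[paste0(part, "_", cc)]] <- g[[part]][[cc]]
          geom_rows[[length(geom_rows) + 1L]] <- row
        }
      }
    }
  }
  metadata <- do.call(rbind, meta)
  geometry <- do.call(rbind, geom_rows)
  if (write_files) {
    write_metadata(metadata, file.path(out_dir, "metadata.csv"))
    write.csv(geometry, file.path(out_dir, "geometry.csv"), row.names = FALSE)
  }
  out <- list(metadata = metadata, geometry = geometry, config = config,
              seed = seed)
  if (!write_files) out$images <- images else out$dir <- out_dir
  out
}
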