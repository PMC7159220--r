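# Boosted cascade of simple rectangular features (Viola-Jones style):
# integral-image Haar-like features, AdaBoost over decision stumps, staged
# rejection, and multi-scale sliding-window detection. This is a small-scale
# training path intended for synthetic crops; externally trained cascade
# files (same XML schema) are accepted wherever a cascade object is.

integral_image <- function(img) {
  H <- nrow(img); W <- ncol(img)
  ii <- matrix(0, H + 1, W + 1)
  ii[-1, -1] <- t(apply(apply(img, 2, cumsum), 1, cumsum))
  ii
}

# Random pool of two/three/four-rectangle contrast features inside a
# `win` x `win` canonical window. Rects are (x, y, w, h) in window pixels.
gen_haar_features <- function(win, n, seed = 1) {
  with_seed(seed, {
    feats <- vector("list", n)
    for (i in seq_len(n)) {
      type <- sample(c("h2", "v2", "h3", "v3", "c4"), 1)
      repeat {
        a <- sample(2:max(2, win %/% 2), 1)   # half/third width
        b <- sample(2:max(2, win %/% 2), 1)   # height
        nx <- switch(type, h2 = 2, v2 = 1, h3 = 3, v3 = 1, c4 = 2)
        ny <- switch(type, h2 = 1, v2 = 2, h3 = 1, v3 = 3, c4 = 2)
        if (a * nx <= win && b * ny <= win) break
      }
      x <- sample(0:(win - a * nx), 1)
      y <- sample(0:(win - b * ny), 1)
      rects <- switch(type,
        h2 = list(c(x, y, a, b), c(x + a, y, a, b)),
        v2 = list(c(x, y, a, b), c(x, y + b, a, b)),
        h3 = list(c(x, y, a, b), c(x + a, y, a, b), c(x + 2 * a, y, a, b)),
        v3 = list(c(x, y, a, b), c(x, y + b, a, b), c(x, y + 2 * b, a, b)),
        c4 = list(c(x, y, a, b), c(x + a, y, a, b),
                  c(x, y + b, a, b), c(x + a, y + b, a, b)))
      weights <- switch(type, h2 = c(-1, 1), v2 = c(-1, 1),
                        h3 = c(-1, 2, -1), v3 = c(-1, 2, -1),
                        c4 = c(1, -1, -1, 1))
      feats[[i]] <- list(rects = rects, weights = weights)
    }
    feats
  })
}

# Feature values for canonical-window samples. iis: (win+1)^2 x N matrix of
# flattened integral images; sdw: per-sample window sd used to normalize out
# brightness/contrast.
eval_features_samples <- function(feats, iis, sdw, win) {
  N <- ncol(iis)
  X <- matrix(0, N, length(feats))
  lin <- function(x, y) y + 1 + (win + 1) * x   # ii is (win+1) x (win+1)
  for (fi in seq_along(feats)) {
    f <- feats[[fi]]
    v <- numeric(N)
    for (ri in seq_along(f$rects)) {
      r <- f$rects[[ri]]
      s <- iis[lin(r[1] + r[3], r[2] + r[4]), ] - iis[lin(r[1], r[2] + r[4]), ] -
           iis[lin(r[1] + r[3], r[2]), ] + iis[lin(r[1], r[2]), ]
      v <- v + f$weights[ri] * s
    }
    X[, fi] <- v / (sdw + 1e-3)
  }
  X
}

window_sd <- function(ii, ii2, xs, ys, win) {
  rs <- function(iimg) {
    iimg[ys + win + 1, xs + win + 1, drop = FALSE] -
      iimg[ys + 1, xs + win + 1, drop = FALSE] -
      iimg[ys + win + 1, xs + 1, drop = FALSE] +
      iimg[ys + 1, xs + 1, drop = FALSE]
  }
  n <- win * win
  m <- rs(ii) / n
  v <- rs(ii2) / n - m^2
  sqrt(pmax(v, 0))
}

# Weighted best stump for one feature's values (AdaBoost inner step).
best_stump <- function(v, y, w, ord) {
  sv <- v[ord]; sy <- y[ord]; sw <- w[ord]
  cpos <- cumsum(sw * sy); cneg <- cumsum(sw * (1 - sy))
  tpos <- cpos[length(cpos)]; tneg <- cneg[length(cneg)]
  # threshold between sv[i] and sv[i+1]; polarity +1 predicts positive above
  err_up <- cpos + (tneg - cneg)       # positives below thr misclassified
  err_dn <- cneg + (tpos - cpos)       # negatives below thr misclassified
  i_up <- which.min(err_up); i_dn <- which.min(err_dn)
  if (err_up[i_up] <= err_dn[i_dn]) {
    list(err = err_up[i_up], polarity = 1,
         thr = if (i_up < length(sv)) (sv[i_up] + sv[i_up + 1]) / 2
               else sv[i_up] + 1e-9)
  } else {
    list(err = err_dn[i_dn], polarity = -1,
         thr = if (i_dn < length(sv)) (sv[i_dn] + sv[i_dn + 1]) / 2
               else sv[i_dn] + 1e-9)
  }
}

stump_predict <- function(v, thr, polarity) {
  if (polarity > 0) as.numeric(v > thr) else as.numeric(v <= thr)
}

#' Train a boosted cascade detector
#'
#' AdaBoost over decision stumps on normalized Haar-like rectangle features,
#' organized as a short rejection cascade. Stage thresholds are set to keep
#' nearly all training positives, trading precision for sensitivity (the
#' regime the study's detector also chose). This is a small-scale training
#' path for synthetic crops, not a production cascade trainer.
#'
#' @param positives,negatives Lists of grayscale crops (matrices, any size;
#'   resized to the canonical window, values 0..255 or 0..1).
#' @param window Canonical window side in px.
#' @param stumps Integer vector: number of stumps per stage.
#' @param n_features Size of the random candidate-feature pool.
#' @param seed Integer seed.
#' @return A `haar_cascade` object.
#' @export
train_cascade <- function(positives, negatives, window = 24,
                          stumps = c(8, 25), n_features = 300, seed = 1) {
  stopifnot(length(positives) > 0, length(negatives) > 0)
  feats <- gen_haar_features(window, n_features, seed = derive_seed(seed, "feat"))
  to_canon <- function(cr) {
    m <- if (max(cr) > 1) cr / 255 else cr
    if (!all(dim(m) == window))
      m <- as.matrix(EBImage::resize(m, w = window, h = window,
                                     filter = "bilinear"))
    m
  }
  canon_pos <- lapply(positives, to_canon)
  canon_neg <- lapply(negatives, to_canon)
  feat_matrix <- function(crops) {
    iis <- vapply(crops, function(m) as.vector(integral_image(m)),
                  numeric((window + 1)^2))
    sdw <- vapply(crops, function(m) stats::sd(as.vector(m)), numeric(1))
    eval_features_samples(feats, iis, sdw, window)
  }
  Xp <- feat_matrix(canon_pos)
  stages <- list()
  neg_pool <- canon_neg
  for (si in seq_along(stumps)) {
    Xn <- feat_matrix(neg_pool)
    X <- rbind(Xp, Xn)
    y <- c(rep(1, nrow(Xp)), rep(0, nrow(Xn)))
    st <- train_boosted_stage_cols(X, y, feats, stumps[si])
    stages[[si]] <- st
    if (si < length(stumps)) {
      # bootstrap: keep only negatives that pass this stage
      sc <- stage_score_matrix(st, Xn)
      hard <- which(sc >= st$threshold)
      neg_pool <- if (length(hard) >= 20) neg_pool[hard] else neg_pool
    }
  }
  # mean positive template (zero mean, unit sd): the cascade stages gate
  # candidate windows, the template's normalized cross-correlation ranks
  # them, giving a continuous localization score where the boosted sum of
  # binary stumps would tie.
  tmpl <- Reduce(`+`, canon_pos) / length(canon_pos)
  tmpl <- (tmpl - mean(tmpl)) / max(stats::sd(as.vector(tmpl)), 1e-6)
  # acceptance threshold on the template score, calibrated on the training
  # positives' own correlations (keeps ~98% of them, minus a safety margin)
  self_ncc <- vapply(canon_pos, function(p) {
    mean(tmpl * (p - mean(p)) / max(stats::sd(as.vector(p)), 1e-6))
  }, numeric(1))
  ncc_thr <- as.numeric(quantile(self_ncc, 0.02, type = 7)) - 0.08
  structure(list(window = as.integer(window), stages = stages,
                 template = tmpl, ncc_threshold = ncc_thr),
            class = "haar_cascade")
}

# Normalized cross-correlation of the template with every window of the
# grid; tmpl is zero-mean unit-sd, so NCC = (X . T) / (n * sd_window).
ncc_grid <- function(sc, tmpl, xs, ys, win, sdw) {
  acc <- matrix(0, length(ys), length(xs))
  for (j in seq_len(win)) for (i in seq_len(win)) {
    tv <- tmpl[i, j]
    if (tv != 0) acc <- acc + tv * sc[ys + i, xs + j, drop = FALSE]
  }
  acc / (win * win) / (sdw + 1e-3)
}

# Boosting variant keeping the selected column index with each stump so
# stage scores can be recomputed on a sample matrix.
train_boosted_stage_cols <- function(X, y, feats, n_stumps,
                                     target_tpr = 0.995) {
  N <- nrow(X)
  w <- rep(1 / N, N)
  ords <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  stumps <- list()
  for (t in seq_len(n_stumps)) {
    best <- NULL
    for (j in seq_len(ncol(X))) {
      s <- best_stump(X[, j], y, w, ords[[j]])
      if (is.null(best) || s$err < best$err) { best <- s; best$fi <- j }
    }
    err <- min(max(best$err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    h <- stump_predict(X[, best$fi], best$thr, best$polarity)
    w <- w * exp(alpha * as.numeric(h != y)); w <- w / sum(w)
    stumps[[t]] <- list(feature = feats[[best$fi]], col = best$fi,
                        thr = best$thr, polarity = best$polarity,
                        alpha = alpha)
  }
  st <- list(stumps = stumps, threshold = 0)
  sc <- stage_score_matrix(st, X[y == 1, , drop = FALSE])
  st$threshold <- as.numeric(quantile(sc, 1 - target_tpr, type = 1)) - 1e-9
  st
}

stage_score_matrix <- function(stage, X) {
  score <- 0
  for (s in stage$stumps)
    score <- score + s$alpha * stump_predict(X[, s$col], s$thr, s$polarity)
  score
}

# Evaluate one stage on a window grid: returns ny x nx score matrix.
stage_score_grid <- function(stage, ii, sdw, xs, ys) {
  score <- 0
  for (s in stage$stumps) {
    v <- 0
    for (ri in seq_along(s$feature$rects)) {
      r <- s$feature$rects[[ri]]
      sub <- ii[ys + r[2] + r[4] + 1, xs + r[1] + r[3] + 1, drop = FALSE] -
             ii[ys + r[2] + 1, xs + r[1] + r[3] + 1, drop = FALSE] -
             ii[ys + r[2] + r[4] + 1, xs + r[1] + 1, drop = FALSE] +
             ii[ys + r[2] + 1, xs + r[1] + 1, drop = FALSE]
      v <- v + s$feature$weights[ri] * sub
    }
    v <- v / (sdw + 1e-3)
    h <- if (s$polarity > 0) (v > s$thr) else (v <= s$thr)
    score <- score + s$alpha * h
  }
  score
}

#' Multi-scale sliding-window cascade detection
#'
#' Slides the canonical window over a scale pyramid (the image is rescaled,
#' the window stays canonical), applies the cascade stages, and returns the
#' surviving boxes after greedy non-maximum suppression, sorted by score
#' descending with ties broken by larger area, then smaller `(x0, y0)`.
#'
#' @param image Grayscale matrix (0..255 or 0..1).
#' @param cascade A `haar_cascade` object or path to a cascade XML file.
#' @param min_size,max_size Object size range (px) searched in the original
#'   image.
#' @param scale_step Pyramid factor between successive object sizes.
#' @param stride Window stride (px) at canonical scale.
#' @param nms_iou IoU above which overlapping detections are merged.
#' @return Box data frame (possibly empty), see [bbox()].
#' @export
detect_cascade <- function(image, cascade, min_size = 24, max_size = 64,
                           scale_step = 1.2, stride = 2, nms_iou = 0.3,
                           min_score = NULL) {
  cascade <- load_cascade_if_path(cascade)
  if (is.null(min_score))
    min_score <- if (!is.null(cascade$ncc_threshold)) cascade$ncc_threshold
                 else -Inf
  img <- if (max(image) > 1) image / 255 else image
  win <- cascade$window
  H <- nrow(img); W <- ncol(img)
  dets <- empty_boxes()
  obj <- min_size
  while (obj <= max_size) {
    f <- win / obj
    Hs <- round(H * f); Ws <- round(W * f)
    if (Hs >= win + 1 && Ws >= win + 1) {
      sc <- as.matrix(EBImage::resize(img, w = Hs, h = Ws, filter = "bilinear"))
      ii <- integral_image(sc); ii2 <- integral_image(sc^2)
      xs <- seq(0, ncol(sc) - win, by = stride)
      ys <- seq(0, nrow(sc) - win, by = stride)
      sdw <- window_sd(ii, ii2, xs, ys, win)
      pass <- matrix(TRUE, length(ys), length(xs))
      for (st in cascade$stages) {
        score <- stage_score_grid(st, ii, sdw, xs, ys)
        pass <- pass & (score >= st$threshold)
      }
      hit <- which(pass, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        ncc <- ncc_grid(sc, cascade$template, xs, ys, win, sdw)
        keep <- ncc[hit] >= min_score
        hit <- hit[keep, , drop = FALSE]
      }
      if (nrow(hit) > 0) {
        x0 <- xs[hit[, 2]] / f; y0 <- ys[hit[, 1]] / f
        dets <- rbind(dets, data.frame(
          x0 = x0, y0 = y0, x1 = x0 + win / f, y1 = y0 + win / f,
          score = ncc[hit]))
      }
    }
    obj <- obj * scale_step
  }
  if (nrow(dets) == 0) return(dets)
  nms_boxes(dets, nms_iou)
}

nms_boxes <- function(dets, nms_iou) {
  area <- (dets$x1 - dets$x0) * (dets$y1 - dets$y0)
  ord <- order(-dets$score, -area, dets$x0, dets$y0)
  dets <- dets[ord, , drop = FALSE]
  keep <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    ok <- TRUE
    for (j in which(keep))
      if (box_iou(dets[i, ], dets[j, ]) > nms_iou) { ok <- FALSE; break }
    keep[i] <- ok
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

load_cascade_if_path <- function(cascade) {
  if (inherits(cascade, "haar_cascade")) return(cascade)
  if (is.character(cascade)) {
    if (!file.exists(cascade))
      stop("cannot read cascade model file: ", cascade, call. = FALSE)
    return(read_cascade_xml(cascade))
  }
  stop("not a cascade model", call. = FALSE)
}

#' Write a cascade to an XML file
#' @param cascade A `haar_cascade`.
#' @param path Output path.
#' @export
write_cascade_xml <- function(cascade, path) {
  doc <- xml2::xml_new_root("cascade", window = cascade$window,
                            ncc_threshold = format(cascade$ncc_threshold,
                                                   digits = 17))
  tn <- xml2::xml_add_child(doc, "template")
  xml2::xml_text(tn) <- paste(format(as.vector(cascade$template),
                                     digits = 10), collapse = ",")
  for (st in cascade$stages) {
    stn <- xml2::xml_add_child(doc, "stage",
                               threshold = format(st$threshold, digits = 17))
    for (s in st$stumps) {
      sn <- xml2::xml_add_child(stn, "stump",
                                alpha = format(s$alpha, digits = 17),
                                thr = format(s$thr, digits = 17),
                                polarity = s$polarity)
      for (ri in seq_along(s$feature$rects)) {
        r <- s$feature$rects[[ri]]
        xml2::xml_add_child(sn, "rect", x = r[1], y = r[2], w = r[3],
                            h = r[4],
                            weight = s$feature$weights[ri])
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a cascade from an XML file
#' @param path Cascade XML path.
#' @return A `haar_cascade`.
#' @export
read_cascade_xml <- function(path) {
  if (!file.exists(path))
    stop("cannot read cascade model file: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  win <- as.integer(xml2::xml_attr(doc, "window"))
  stages <- lapply(xml2::xml_find_all(doc, "stage"), function(stn) {
    stumps <- lapply(xml2::xml_find_all(stn, "stump"), function(sn) {
      rects <- lapply(xml2::xml_find_all(sn, "rect"), function(rn)
        as.numeric(xml2::xml_attrs(rn)[c("x", "y", "w", "h")]))
      weights <- vapply(xml2::xml_find_all(sn, "rect"), function(rn)
        as.numeric(xml2::xml_attr(rn, "weight")), numeric(1))
      list(feature = list(rects = rects, weights = weights),
           thr = as.numeric(xml2::xml_attr(sn, "thr")),
           polarity = as.numeric(xml2::xml_attr(sn, "polarity")),
           alpha = as.numeric(xml2::xml_attr(sn, "alpha")))
    })
    list(stumps = stumps, threshold = as.numeric(xml2::xml_attr(stn, "threshold")))
  })
  tmpl <- matrix(as.numeric(strsplit(xml2::xml_text(
    xml2::xml_find_first(doc, "template")), ",")[[1]]), win, win)
  structure(list(window = win, stages = stages, template = tmpl,
                 ncc_threshold = as.numeric(xml2::xml_attr(doc,
                                                           "ncc_threshold"))),
            class = "haar_cascade")
}
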