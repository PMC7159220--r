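#' @useDynLib grimscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd setNames
#' @importFrom utils read.csv write.csv head modifyList
NULL

#' Construct a bounding box
#'
#' Boxes use the package-wide pixel convention: 0-based, half-open
#' `[x0, x1) x [y0, y1)`, with y increasing downward.
#'
#' @param x0,y0,x1,y1 Box edges in pixels; `x0 < x1`, `y0 < y1`.
#' @param score Optional detector confidence (unitless).
#' @return A one-row `data.frame` with columns `x0, y0, x1, y1, score`.
#' @export
bbox <- function(x0, y0, x1, y1, score = NA_real_) {
  stopifnot(all(x0 < x1), all(y0 < y1))
  data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1, score = score)
}

empty_boxes <- function() {
  data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
             y1 = numeric(0), score = numeric(0))
}

#' Intersection-over-union of two boxes
#'
#' @param a,b One-row box data frames (see [bbox()]).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- ix * iy
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Clip a box to image bounds
#' @param box One-row box data frame.
#' @param width,height Image dimensions in pixels.
#' @return The clipped box.
#' @export
clip_box <- function(box, width, height) {
  box$x0 <- max(0, min(box$x0, width))
  box$x1 <- max(0, min(box$x1, width))
  box$y0 <- max(0, min(box$y0, height))
  box$y1 <- max(0, min(box$y1, height))
  box
}

box_center <- function(box) c(x = (box$x0 + box$x1) / 2, y = (box$y0 + box$y1) / 2)

box_contains <- function(outer, inner) {
  inner$x0 >= outer$x0 && inner$x1 <= outer$x1 &&
    inner$y0 >= outer$y0 && inner$y1 <= outer$y1
}

#' Derive a reproducible sub-seed from a parent seed and a key
#'
#' One global seed fans out to per-animal and per-image streams by stable
#' string hashing, so any subset of a generated dataset is reproducible on
#' its own. The hash is a plain multiplicative hash modulo 2^31 - 1,
#' platform-independent.
#'
#' @param seed Parent integer seed.
#' @param ... Key components (coerced to character).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# Evaluate `code` under a private RNG stream without disturbing the caller's.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
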