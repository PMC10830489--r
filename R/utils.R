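#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif rgamma sd quantile predict
#' @importFrom utils head modifyList
NULL

#' Derive a stage-specific seed from a global seed
#'
#' Stable 32-bit seed fan-out: one user-facing seed, independent streams per
#' pipeline stage (polynomial hash of the stage name folded with the base
#' seed), so each stage is reproducible on its own.
#'
#' @param seed integer base seed.
#' @param stage character stage name.
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 16777619
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert an RGB array to luminance grayscale
#'
#' Uses the Rec. 601 luma weights 0.299 R + 0.587 G + 0.114 B. Input channels
#' are expected on the 0--255 scale (a height x width x 3 array); a matrix is
#' returned unchanged.
#'
#' @param img numeric matrix (already grayscale) or H x W x 3 array.
#' @return numeric H x W matrix.
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Bilinear resize of a matrix or HxWxC array to side x side, via EBImage.
# EBImage stores images as x (columns) by y (rows); transpose on the way in/out.
resize_image <- function(img, side) {
  if (is.matrix(img)) {
    out <- EBImage::resize(EBImage::Image(t(img) / 255), w = side, h = side)
    return(t(EBImage::imageData(out)) * 255)
  }
  stopifnot(length(dim(img)) == 3L)
  ei <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  out <- EBImage::resize(ei, w = side, h = side)
  aperm(EBImage::imageData(out), c(2, 1, 3)) * 255
}

#' Windowed (local) variance of an intensity image
#'
#' Box-window variance, used to verify that crumpling raises local texture
#' variation inside the gauze region.
#'
#' @param x numeric matrix.
#' @param k window side in pixels.
#' @param mask optional 0/1 matrix; when given, returns the vector of
#'   variances at mask-positive pixels.
#' @return matrix of local variances, or a vector under a mask.
#' @export
local_variance <- function(x, k = 7L, mask = NULL) {
  box <- matrix(1 / (k * k), k, k)
  m1 <- t(EBImage::imageData(EBImage::filter2(EBImage::Image(t(x)), box)))
  m2 <- t(EBImage::imageData(EBImage::filter2(EBImage::Image(t(x^2)), box)))
  v <- pmax(m2 - m1^2, 0)
  if (!is.null(mask)) v[mask > 0] else v
}

# Deterministic band-limited noise: low-resolution white noise, bilinearly
# upsampled; octaves at increasing resolution, standardized to sd 1.
band_limited_noise <- function(h, w, cells = c(6L, 12L), weights = c(0.65, 0.35)) {
  acc <- matrix(0, h, w)
  for (i in seq_along(cells)) {
    n <- cells[i]
    g <- matrix(rnorm((n + 2)^2), n + 2, n + 2)
    up <- EBImage::resize(EBImage::Image(t(g)), w = w, h = h)
    acc <- acc + weights[i] * t(EBImage::imageData(up))
  }
  (acc - mean(acc)) / stats::sd(acc)
}

is_binary_mask <- function(m) is.matrix(m) && all(m %in% c(0, 1, FALSE, TRUE))

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (strict_lo && x <= lo) abort(sprintf("`%s` must be > %s", name, lo))
  if (!strict_lo && x < lo) abort(sprintf("`%s` must be >= %s", name, lo))
  if (x > hi) abort(sprintf("`%s` must be <= %s", name, hi))
  invisible(x)
}
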