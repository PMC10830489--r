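#' Tiling geometry for frame classification
#'
#' @param tile_size square tile side in pixels (>= 16).
#' @param stride step between tile origins in pixels (1 <= stride <=
#'   tile_size).
#' @param input_resize side to which tiles are resized before entering the
#'   classifier.
#' @return an object of class `tile_spec`.
#' @export
tile_spec <- function(tile_size = 64L, stride = tile_size, input_resize = 32L) {
  assert_scalar_num(tile_size, "tile_size", lo = 16)
  assert_scalar_num(stride, "stride", lo = 1, hi = tile_size)
  assert_scalar_num(input_resize, "input_resize", lo = 8)
  structure(list(tile_size = as.integer(tile_size), stride = as.integer(stride),
                 input_resize = as.integer(input_resize)),
            class = "tile_spec")
}

tile_grid_dims <- function(frame_dims, spec) {
  c(rows = floor((frame_dims[1] - spec$tile_size) / spec$stride) + 1L,
    cols = floor((frame_dims[2] - spec$tile_size) / spec$stride) + 1L)
}

#' Cut a frame into classification tiles
#'
#' Tiles are enumerated row-major over a regular grid; each covers the
#' half-open pixel range `[r0, r0 + tile_size) x [c0, c0 + tile_size)`
#' (0-based origins, origin top-left). Right/bottom remainder pixels that do
#' not fit a whole tile are dropped.
#'
#' @param frame H x W matrix or H x W x 3 array.
#' @param spec a [tile_spec()].
#' @return tibble with `tile_row`, `tile_col` (1-based grid coordinates),
#'   `r0`, `c0` (0-based pixel origins) and list-column `image` holding each
#'   crop.
#' @export
tile_frame <- function(frame, spec = tile_spec()) {
  dims <- dim(frame)[1:2]
  if (any(dims < spec$tile_size)) {
    abort("frame is smaller than one tile in at least one dimension")
  }
  g <- tile_grid_dims(dims, spec)
  out <- vector("list", g["rows"] * g["cols"])
  rows <- cols <- r0s <- c0s <- integer(length(out))
  i <- 0L
  for (tr in seq_len(g["rows"])) {
    for (tc in seq_len(g["cols"])) {
      i <- i + 1L
      r0 <- (tr - 1L) * spec$stride
      c0 <- (tc - 1L) * spec$stride
      rows[i] <- tr; cols[i] <- tc; r0s[i] <- r0; c0s[i] <- c0
      rr <- (r0 + 1L):(r0 + spec$tile_size)
      cc <- (c0 + 1L):(c0 + spec$tile_size)
      out[[i]] <- if (length(dims) == 2L && is.matrix(frame)) {
        frame[rr, cc, drop = FALSE]
      } else {
        frame[rr, cc, , drop = FALSE]
      }
    }
  }
  tibble::tibble(tile_row = rows, tile_col = cols, r0 = r0s, c0 = c0s,
                 image = out)
}

#' The fixed tile-state order
#'
#' Background tissue plus the three gauze states. Probability vectors and
#' tie-breaking use this order throughout.
#' @return character vector of length 4.
#' @export
tile_classes <- function() c("background", "clean", "stained", "soaked")

#' Assemble a binary gauze mask from tile classifications
#'
#' A pixel is gauze when the mean gauze probability (clean + stained +
#' soaked) of all tiles covering it is at least 0.5. Pixels covered by no
#' tile (remainder border) are background. Optional morphological closing
#' (5 px disc by default) removes grid artifacts at tile boundaries.
#'
#' @param classification tibble from [classify_tiles()] (needs `r0`, `c0`
#'   and the per-class probability columns).
#' @param frame_dims `c(height, width)` of the original frame.
#' @param spec the [tile_spec()] used for tiling.
#' @param closing apply morphological closing (default TRUE).
#' @param closing_size disc diameter in pixels for closing.
#' @return H x W 0/1 integer matrix.
#' @export
assemble_mask <- function(classification, frame_dims, spec = tile_spec(),
                          closing = TRUE, closing_size = 5L) {
  h <- frame_dims[1]; w <- frame_dims[2]
  acc <- matrix(0, h, w); cov <- matrix(0, h, w)
  pg <- classification$clean + classification$stained + classification$soaked
  for (i in seq_len(nrow(classification))) {
    rr <- (classification$r0[i] + 1L):(classification$r0[i] + spec$tile_size)
    cc <- (classification$c0[i] + 1L):(classification$c0[i] + spec$tile_size)
    acc[rr, cc] <- acc[rr, cc] + pg[i]
    cov[rr, cc] <- cov[rr, cc] + 1
  }
  mask <- matrix(0L, h, w)
  covered <- cov > 0
  mask[covered] <- as.integer(acc[covered] / cov[covered] >= 0.5)
  if (closing && any(mask > 0)) {
    brush <- EBImage::makeBrush(closing_size, shape = "disc")
    closed <- EBImage::closing(EBImage::Image(t(mask)), brush)
    mask <- matrix(as.integer(t(EBImage::imageData(closed)) > 0), h, w)
  }
  mask
}

#' Zero out everything but the detected gauze
#'
#' @param frame H x W x 3 array (or matrix).
#' @param gauze_mask 0/1 matrix of the same height/width.
#' @return list with `image` (frame with non-gauze pixels set to zero) and
#'   `bbox` (named vector r0/r1/c0/c1, 1-based inclusive tight bounds).
#' @export
extract_masked_image <- function(frame, gauze_mask) {
  dims <- dim(frame)[1:2]
  stopifnot(all(dims == dim(gauze_mask)))
  if (sum(gauze_mask) == 0) abort("no gauze detected")
  keep <- gauze_mask > 0
  out <- frame
  if (is.matrix(frame)) {
    out[!keep] <- 0
  } else {
    for (ch in seq_len(dim(frame)[3])) {
      plane <- out[, , ch]; plane[!keep] <- 0; out[, , ch] <- plane
    }
  }
  rs <- range(which(rowSums(gauze_mask) > 0))
  cs <- range(which(colSums(gauze_mask) > 0))
  list(image = out, bbox = c(r0 = rs[1], r1 = rs[2], c0 = cs[1], c1 = cs[2]))
}

#' Extract gauze patches from a classified frame
#'
#' Patches are the detection tiles whose within-tile gauze-mask coverage is
#' at least `min_gauze_fraction`. Each patch carries its image crop, mask
#' crop and a blood-evidence score (the tile's stained + soaked
#' probability), which later weights the patch CSV. When a per-pixel blood
#' mass map is supplied (synthetic data), the per-patch mass is recorded
#' too.
#'
#' @param frame H x W x 3 array.
#' @param gauze_mask 0/1 matrix.
#' @param classification tibble from [classify_tiles()].
#' @param spec the [tile_spec()] used.
#' @param min_gauze_fraction minimum mask coverage in (0, 1], default 0.5.
#' @param blood_mass_map optional per-pixel gram map (synthetic ground
#'   truth).
#' @return tibble (possibly empty) with `tile_row`, `tile_col`, `r0`, `c0`,
#'   `coverage`, `blood_evidence`, list-columns `image` and `mask`, and
#'   `patch_mass_g` when a mass map was given.
#' @export
extract_patches <- function(frame, gauze_mask, classification,
                            spec = tile_spec(), min_gauze_fraction = 0.5,
                            blood_mass_map = NULL) {
  assert_scalar_num(min_gauze_fraction, "min_gauze_fraction", lo = 0, hi = 1,
                    strict_lo = TRUE)
  rows <- vector("list", nrow(classification))
  n <- 0L
  for (i in seq_len(nrow(classification))) {
    rr <- (classification$r0[i] + 1L):(classification$r0[i] + spec$tile_size)
    cc <- (classification$c0[i] + 1L):(classification$c0[i] + spec$tile_size)
    mcrop <- gauze_mask[rr, cc, drop = FALSE]
    coverage <- mean(mcrop > 0)
    if (coverage < min_gauze_fraction) next
    n <- n + 1L
    rows[[n]] <- tibble::tibble(
      tile_row = classification$tile_row[i], tile_col = classification$tile_col[i],
      r0 = classification$r0[i], c0 = classification$c0[i],
      coverage = coverage,
      blood_evidence = classification$stained[i] + classification$soaked[i],
      image = list(frame[rr, cc, , drop = FALSE]),
      mask = list(matrix(as.integer(mcrop > 0), spec$tile_size, spec$tile_size)),
      patch_mass_g = if (is.null(blood_mass_map)) NA_real_
                     else sum(blood_mass_map[rr, cc])
    )
  }
  if (n == 0L) {
    return(tibble::tibble(tile_row = integer(), tile_col = integer(),
                          r0 = integer(), c0 = integer(), coverage = numeric(),
                          blood_evidence = numeric(), image = list(),
                          mask = list(), patch_mass_g = numeric()))
  }
  dplyr::bind_rows(rows[seq_len(n)])
}

#' Gauze-versus-background detection metrics
#'
#' Binarises labels to gauze (positive: any of clean/stained/soaked) versus
#' background and reports sensitivity, specificity and precision in percent
#' with the underlying confusion counts. Undefined ratios (zero denominator)
#' are reported as `NA`, never as 0.
#'
#' @param predicted,truth character vectors of tile labels (any of the four
#'   tile states, or already-binary `"gauze"`/`"background"`).
#' @return one-row tibble: tp, fp, tn, fn, sensitivity_pct, specificity_pct,
#'   precision_pct.
#' @export
detection_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) abort("label vectors differ in length")
  as_pos <- function(x) x != "background"
  p <- as_pos(predicted); t <- as_pos(truth)
  tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity_pct = ratio(tp, tp + fn),
                 specificity_pct = ratio(tn, tn + fp),
                 precision_pct = ratio(tp, tp + fp))
}
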