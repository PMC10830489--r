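#' Local binary pattern configuration
#'
#' The LBP code of a center pixel thresholds `p` neighbours sampled on a
#' circle of radius `r` against the center: bit k is 1 when
#' `g_k - g_c >= 0` (ties count as 1), and the bits are read as an integer
#' `sum(s_k * 2^k)`. Neighbour k sits at angle `2*pi*k/p` starting from the
#' offset (+r, 0) in (column, row) and proceeding counterclockwise
#' (row decreasing on screen). Defaults are the gauze-texture setting
#' `r = 3`, `p = 8`.
#'
#' @param r circle radius in pixels (>= 1).
#' @param p number of sampled neighbours (>= 4).
#' @param sampling `"bilinear"` (default) interpolates non-integer neighbour
#'   positions; `"nearest"` rounds them to the nearest pixel (exact on
#'   integer images, used by test oracles).
#' @return an object of class `lbp_config`.
#' @export
lbp_config <- function(r = 3, p = 8L, sampling = c("bilinear", "nearest")) {
  assert_scalar_num(r, "r", lo = 1)
  assert_scalar_num(p, "p", lo = 4)
  sampling <- match.arg(sampling)
  structure(list(r = r, p = as.integer(p), sampling = sampling),
            class = "lbp_config")
}

# neighbour offsets in (row, col) for each of the p sampling points
lbp_offsets <- function(config) {
  k <- seq_len(config$p) - 1L
  theta <- 2 * pi * k / config$p
  list(drow = -config$r * sin(theta), dcol = config$r * cos(theta))
}

#' Compute the LBP code map of a grayscale image
#'
#' Vectorised circular LBP: each of the `p` neighbour planes is obtained by a
#' constant sub-pixel shift of the image (bilinear mix of four integer
#' shifts, or a single rounded shift for `"nearest"`), compared against the
#' center plane, and accumulated into the code. Pixels whose full
#' neighbourhood leaves the image are marked invalid (`NA` code), never
#' silently zero.
#'
#' @param gray single-channel numeric matrix; convert colour frames with
#'   [rgb_to_gray()] first.
#' @param config an [lbp_config()].
#' @return object of class `lbp_map`: list with `codes` (integer matrix,
#'   values in `[0, 2^p - 1]`, `NA` outside the valid region), `valid_mask`
#'   (0/1 matrix) and the `config`.
#' @export
lbp_map <- function(gray, config = lbp_config()) {
  if (!is.matrix(gray)) {
    abort("`gray` must be a single-channel matrix; convert with rgb_to_gray() first")
  }
  stopifnot(inherits(config, "lbp_config"))
  h <- nrow(gray); w <- ncol(gray)
  m <- as.integer(ceiling(config$r))
  if (h <= 2 * m + 1 || w <= 2 * m + 1) {
    abort(sprintf("image must exceed %d pixels in each dimension", 2 * m + 1))
  }
  off <- lbp_offsets(config)
  vr <- (m + 1L):(h - m); vc <- (m + 1L):(w - m)
  center <- gray[vr, vc, drop = FALSE]
  codes_valid <- matrix(0, length(vr), length(vc))
  for (k in seq_len(config$p)) {
    dr <- off$drow[k]; dc <- off$dcol[k]
    if (config$sampling == "nearest") {
      gp <- gray[vr + round(dr), vc + round(dc), drop = FALSE]
    } else {
      r0 <- floor(dr); c0 <- floor(dc)
      fr <- dr - r0; fc <- dc - c0
      # integer offsets collapse to a single shift (the +1 term has weight 0)
      r1 <- if (fr < 1e-12) r0 else r0 + 1
      c1 <- if (fc < 1e-12) c0 else c0 + 1
      gp <- (1 - fr) * (1 - fc) * gray[vr + r0, vc + c0, drop = FALSE] +
        (1 - fr) * fc * gray[vr + r0, vc + c1, drop = FALSE] +
        fr * (1 - fc) * gray[vr + r1, vc + c0, drop = FALSE] +
        fr * fc * gray[vr + r1, vc + c1, drop = FALSE]
    }
    # s(x) = 1 for x >= 0; the 1e-6 gray-level epsilon absorbs floating-point
    # noise from bilinear interpolation so constant regions compare as ties
    codes_valid <- codes_valid + (gp - center >= -1e-6) * 2^(k - 1L)
  }
  codes <- matrix(NA_integer_, h, w)
  codes[vr, vc] <- as.integer(round(codes_valid))
  valid <- matrix(0L, h, w)
  valid[vr, vc] <- 1L
  structure(list(codes = codes, valid_mask = valid, config = config),
            class = "lbp_map")
}

#' Crumpled state value of a gauze region
#'
#' The CSV is the mean LBP code over the detected gauze region: the sum of
#' gauze LBP values divided by the pixel count of the region. Only pixels
#' with a valid (fully in-image) LBP neighbourhood enter numerator and
#' denominator, so border pixels never bias the value.
#'
#' @param lbp an [lbp_map()] result.
#' @param gauze_mask 0/1 matrix of detected gauze pixels (same size).
#' @return object of class `crumple_state`: list with `csv` (unitless, in
#'   `[0, 2^p - 1]`) and `region_pixel_count`.
#' @export
compute_csv <- function(lbp, gauze_mask) {
  stopifnot(inherits(lbp, "lbp_map"), is_binary_mask(gauze_mask),
            all(dim(gauze_mask) == dim(lbp$codes)))
  sel <- gauze_mask > 0 & lbp$valid_mask > 0
  n <- sum(sel)
  if (n == 0) abort("no valid gauze pixels")
  structure(list(csv = sum(as.numeric(lbp$codes[sel])) / n,
                 region_pixel_count = n),
            class = "crumple_state")
}

#' @export
print.crumple_state <- function(x, ...) {
  cat(sprintf("<crumple_state> CSV = %.3f over %d gauze pixels\n",
              x$csv, x$region_pixel_count))
  invisible(x)
}

#' Per-patch CSV descriptors and the fixed-length fusion vector
#'
#' For each gauze patch, computes its CSV and multiplies it by a patch
#' weight; the weighted CSVs, sorted in descending order and zero-padded (or
#' truncated) to length `n_vector`, form the fixed-length input of the
#' patch-wise crumpled-state (P-W CS) regression head.
#'
#' Weighting modes for "the blood associated with that patch":
#' `"blood_evidence"` (default) uses the detector's stained + soaked
#' probability — the only signal available at inference time;
#' `"uniform"` sets all weights to 1 (so weighted CSV = CSV);
#' `"ground_truth_mass"` uses the simulated per-patch blood mass normalised
#' by the scene maximum (synthetic data only, to validate the proxy).
#'
#' @param patches tibble from [extract_patches()] (columns `image`, `mask`,
#'   `blood_evidence`, optionally `patch_mass_g`).
#' @param config an [lbp_config()].
#' @param weighting one of `"blood_evidence"`, `"uniform"`,
#'   `"ground_truth_mass"`.
#' @param n_vector length of the fixed fusion vector (default 16).
#' @return list with `descriptors` (tibble: patch_id, csv,
#'   region_pixel_count, weight, weighted_csv) and `fixed_vector`
#'   (length `n_vector`, descending, zero-padded). Zero patches yield an
#'   all-zero vector with a warning, so clean frames still regress.
#' @export
patch_descriptors <- function(patches, config = lbp_config(),
                              weighting = c("blood_evidence", "uniform",
                                            "ground_truth_mass"),
                              n_vector = 16L) {
  weighting <- match.arg(weighting)
  if (is.null(patches) || nrow(patches) == 0) {
    warn("no gauze patches; returning an all-zero descriptor vector")
    return(list(descriptors = tibble::tibble(patch_id = integer(), csv = numeric(),
                                             region_pixel_count = integer(),
                                             weight = numeric(),
                                             weighted_csv = numeric()),
                fixed_vector = numeric(n_vector)))
  }
  csvs <- counts <- numeric(nrow(patches))
  for (i in seq_len(nrow(patches))) {
    gray <- rgb_to_gray(patches$image[[i]])
    cs <- compute_csv(lbp_map(gray, config), patches$mask[[i]])
    csvs[i] <- cs$csv; counts[i] <- cs$region_pixel_count
  }
  weight <- switch(weighting,
    uniform = rep(1, nrow(patches)),
    blood_evidence = clamp(patches$blood_evidence, 0, 1),
    ground_truth_mass = {
      if (is.null(patches$patch_mass_g)) {
        abort("ground_truth_mass weighting requires a `patch_mass_g` column")
      }
      mx <- max(patches$patch_mass_g)
      if (mx > 0) patches$patch_mass_g / mx else rep(0, nrow(patches))
    })
  desc <- tibble::tibble(patch_id = seq_len(nrow(patches)), csv = csvs,
                         region_pixel_count = as.integer(counts),
                         weight = weight, weighted_csv = weight * csvs)
  v <- sort(desc$weighted_csv, decreasing = TRUE)
  fixed <- numeric(n_vector)
  take <- min(n_vector, length(v))
  fixed[seq_len(take)] <- v[seq_len(take)]
  list(descriptors = desc, fixed_vector = fixed)
}
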