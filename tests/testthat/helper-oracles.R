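# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with naive scalar loops so they share no code path
# with the package implementations they check.

# Per-pixel LBP oracle: double loop over centers, each bit re-derived by
# direct interpolation at the circle position and comparison with the center.
lbp_oracle <- function(gray, r = 3, p = 8, sampling = "bilinear") {
  h <- nrow(gray); w <- ncol(gray)
  m <- as.integer(ceiling(r))
  codes <- matrix(NA_integer_, h, w)
  for (i in (m + 1):(h - m)) {
    for (j in (m + 1):(w - m)) {
      code <- 0
      for (k in 0:(p - 1)) {
        theta <- 2 * pi * k / p
        dr <- -r * sin(theta); dc <- r * cos(theta)
        if (sampling == "nearest") {
          g <- gray[i + round(dr), j + round(dc)]
        } else {
          r0 <- floor(dr); c0 <- floor(dc)
          fr <- dr - r0; fc <- dc - c0
          r1 <- if (fr < 1e-12) r0 else r0 + 1
          c1 <- if (fc < 1e-12) c0 else c0 + 1
          g <- (1 - fr) * (1 - fc) * gray[i + r0, j + c0] +
            (1 - fr) * fc * gray[i + r0, j + c1] +
            fr * (1 - fc) * gray[i + r1, j + c0] +
            fr * fc * gray[i + r1, j + c1]
        }
        if (g - gray[i, j] >= -1e-6) code <- code + 2^k
      }
      codes[i, j] <- as.integer(code)
    }
  }
  codes
}

# naive metric loops
mae_oracle <- function(pred, truth) {
  s <- 0
  for (i in seq_along(pred)) s <- s + abs(truth[i] - pred[i])
  s / length(pred)
}
mape_oracle <- function(pred, truth) {
  s <- 0
  for (i in seq_along(pred)) s <- s + abs((truth[i] - pred[i]) / truth[i])
  100 * s / length(pred)
}
mse_oracle <- function(pred, truth) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (truth[i] - pred[i])^2
  s / length(pred)
}

# trivially separable tiles: pure red vs pure gray blocks (plus noise-free
# labels) for the perfect-separation training check
separable_tiles <- function(n_per_class = 30, side = 64) {
  mk <- function(col) {
    arr <- array(0, c(side, side, 3))
    for (ch in 1:3) arr[, , ch] <- col[ch]
    arr
  }
  tibble::tibble(
    image = c(replicate(n_per_class, mk(c(200, 10, 10)), simplify = FALSE),
              replicate(n_per_class, mk(c(120, 120, 120)), simplify = FALSE)),
    label = rep(c("soaked", "background"), each = n_per_class))
}

# small scene helper
tiny_scene <- function(seed = 1, mass = 4.17, crumple = 1, size = 128L) {
  generate_scene(scene_params(image_height = size, image_width = size,
                              blood_mass_g = mass, crumple_intensity = crumple,
                              seed = seed))
}
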