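#' Parameters for one synthetic laparoscopic gauze scene
#'
#' Bundles and validates everything needed to render a single scene: frame
#' geometry, gauze coverage, crumple amplitude, blood mass and stain
#' dispersion. Defaults target desk-scale frames (256 x 256) and the blood
#' mass range observed on weighed surgical gauze (0.13--9.98 g, mean about
#' 4.17 g); full-HD frames are available by changing the dimensions.
#'
#' @param image_height,image_width frame size in pixels.
#' @param gauze_area_fraction fraction of the frame covered by gauze,
#'   strictly in (0, 1).
#' @param crumple_intensity nonnegative amplitude of the blood-era fold
#'   field (unitless; 0 = perfectly flat gauze). Blood stains co-locate
#'   with these folds.
#' @param handling_intensity nonnegative amplitude of a second,
#'   spatially independent fold field added after staining — the crumpling
#'   produced by handling and extraction, which carries no blood.
#' @param blood_mass_g blood mass absorbed by the gauze, in grams (>= 0).
#' @param stain_spread spatial dispersion of the stain in pixels (> 0);
#'   standard deviation of each stain kernel.
#' @param background_kind `"tissue"` (reddish organ background) or
#'   `"dark_cavity"`.
#' @param seed integer seed; every derived random stream is a pure function
#'   of it.
#' @param mass_range permitted simulation range for `blood_mass_g`, grams.
#' @return an object of class `scene_params` (a validated list).
#' @export
scene_params <- function(image_height = 256L, image_width = 256L,
                         gauze_area_fraction = 0.35, crumple_intensity = 1,
                         handling_intensity = 0, blood_mass_g = 4.17,
                         stain_spread = 12,
                         background_kind = c("tissue", "dark_cavity"),
                         seed = 1L, mass_range = c(0, 9.98)) {
  assert_scalar_num(image_height, "image_height", lo = 32)
  assert_scalar_num(image_width, "image_width", lo = 32)
  assert_scalar_num(gauze_area_fraction, "gauze_area_fraction", lo = 0, hi = 1,
                    strict_lo = TRUE)
  if (gauze_area_fraction >= 1) abort("`gauze_area_fraction` must be < 1")
  assert_scalar_num(crumple_intensity, "crumple_intensity", lo = 0)
  assert_scalar_num(handling_intensity, "handling_intensity", lo = 0)
  assert_scalar_num(blood_mass_g, "blood_mass_g", lo = 0)
  if (blood_mass_g < mass_range[1] || blood_mass_g > mass_range[2]) {
    abort(sprintf("`blood_mass_g` = %.3f outside simulation range [%.2f, %.2f]",
                  blood_mass_g, mass_range[1], mass_range[2]))
  }
  assert_scalar_num(stain_spread, "stain_spread", lo = 0, strict_lo = TRUE)
  background_kind <- match.arg(background_kind)
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 gauze_area_fraction = gauze_area_fraction,
                 crumple_intensity = crumple_intensity,
                 handling_intensity = handling_intensity,
                 blood_mass_g = blood_mass_g, stain_spread = stain_spread,
                 background_kind = background_kind, seed = as.integer(seed),
                 mass_range = mass_range),
            class = "scene_params")
}

#' Render the woven gauze texture and its mask
#'
#' Draws a single connected, star-convex gauze region whose area matches
#' `gauze_area_fraction` of the frame (within a few percent) and fills it
#' with a periodic two-direction weave pattern plus thread noise. The weave
#' period (7 px at the default scale) is what the LBP texture stage later
#' reads out.
#'
#' @param params a [scene_params()] object.
#' @return list with `texture` (H x W grayscale matrix, 0--255, zero outside
#'   the gauze) and `gauze_mask` (H x W 0/1 matrix).
#' @export
generate_gauze_texture <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$image_height; w <- params$image_width
  set.seed(derive_seed(params$seed, "texture"))

  cy <- h * (0.5 + runif(1, -0.07, 0.07))
  cx <- w * (0.5 + runif(1, -0.07, 0.07))
  amp <- runif(3, 0.03, 0.09)
  phs <- runif(3, 0, 2 * pi)
  lobes <- c(2, 3, 5)

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  theta <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  boundary_shape <- 1 +
    amp[1] * sin(lobes[1] * theta + phs[1]) +
    amp[2] * sin(lobes[2] * theta + phs[2]) +
    amp[3] * sin(lobes[3] * theta + phs[3])

  target <- params$gauze_area_fraction * h * w
  R <- sqrt(target / (pi * (1 + sum(amp^2) / 2)))
  mask <- rho <= R * boundary_shape
  for (i in 1:3) {  # rescale radius so clipped shapes still hit the target area
    got <- sum(mask)
    if (abs(got - target) / target < 0.01) break
    R <- R * sqrt(target / max(got, 1))
    mask <- rho <= R * boundary_shape
  }

  # taut cloth reflects uniformly: flat plateaus at the base intensity with
  # darker thread lines in two directions. The plateaus yield many exact
  # intensity ties, which the LBP tie convention (s(0) = 1) reads as high
  # codes; crumpling later breaks the ties, so the CSV has a wide dynamic
  # range over the fold-amplitude scale. High-frequency grain belongs to the
  # crumple stage, not the flat cloth.
  phi <- runif(1, 0, pi / 2)
  period <- 11
  u <- cos(phi) * cols + sin(phi) * rows
  v <- -sin(phi) * cols + cos(phi) * rows
  line <- (u %% period) < 1.2 | (v %% period) < 1.2
  tex <- matrix(205, h, w)
  tex[line] <- 177
  tex[!mask] <- 0
  list(texture = tex, gauze_mask = matrix(as.integer(mask), h, w))
}

#' Crumple a gauze texture with a band-limited fold field
#'
#' Simulates folds by (i) warping the weave along the gradient of a smooth
#' band-limited noise field, which locally compresses/stretches the thread
#' pattern, and (ii) modulating shading by the field itself. Both effects
#' scale with `intensity`; `intensity = 0` returns the input untouched.
#' Local intensity variance inside the mask grows with the fold amplitude,
#' which is the signal the crumpled-state value (CSV) summarises.
#'
#' @param texture H x W grayscale matrix (0--255).
#' @param mask H x W 0/1 gauze mask.
#' @param intensity nonnegative fold amplitude.
#' @param seed integer seed for the fold field.
#' @return list with `texture` (crumpled, clipped to 0--255) and
#'   `crumple_field` (H x W nonnegative fold amplitude, `intensity` times a
#'   field normalised to \[0, 1\]).
#' @export
apply_crumple <- function(texture, mask, intensity, seed = 1L) {
  stopifnot(is.matrix(texture), is_binary_mask(mask),
            all(dim(texture) == dim(mask)))
  assert_scalar_num(intensity, "intensity", lo = 0)
  h <- nrow(texture); w <- ncol(texture)
  if (intensity == 0) {
    return(list(texture = texture, crumple_field = matrix(0, h, w)))
  }
  set.seed(derive_seed(seed, "crumple"))
  f <- band_limited_noise(h, w)
  fpos <- (f - min(f)) / (max(f) - min(f))

  # warp texture coordinates along the fold gradient
  gy <- (rbind(f[-1, , drop = FALSE], f[h, ]) -
           rbind(f[1, ], f[-h, , drop = FALSE])) / 2
  gx <- (cbind(f[, -1, drop = FALSE], f[, w]) -
           cbind(f[, 1], f[, -w, drop = FALSE])) / 2
  disp <- 1.6 * min(intensity, 2.5)  # fold displacement saturates; shadows
                                     # and grain carry the response beyond
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  # nearest-neighbour resampling: distorts the weave without the low-pass
  # blur of interpolation, so local variance never drops below the flat case
  rr <- round(clamp(rows + disp * gy * h / 16, 1, h))
  cc <- round(clamp(cols + disp * gx * w / 16, 1, w))
  warped <- matrix(texture[cbind(as.vector(rr), as.vector(cc))], h, w)

  # Fold shadows and micro-wrinkle grain, both constructed so the flat
  # cloth's intensity ties erode *progressively* with the fold amplitude:
  # the shadow is quantised to flat steps (plateaus survive inside a step,
  # break along level-set lines that multiply with intensity) and the grain
  # touches a pixel fraction growing with intensity rather than shifting
  # every pixel at once. Windowed variance grows with intensity; the LBP tie
  # convention (s(0) = 1) reads the tie erosion as a wide CSV response.
  # shadow depth saturates with the displacement (a fully shadowed fold gets
  # no darker); past that point the response is carried by the grain term
  amp <- 28 * min(intensity, 2.5)
  shadow <- clamp(-f, 0, 2) / 2
  tier <- 3 + 1.2 * min(intensity, 2.5)  # deeper folds cast coarser tiers
  shadow_q <- round(amp * shadow / tier) * tier
  # grain concentrates on the folds but reaches the whole cloth as the
  # amplitude grows, so the texture response does not saturate early
  grain_on <- matrix(runif(h * w) < pmin(0.5 * intensity * (0.3 + fpos), 1), h, w)
  micro <- matrix(rnorm(h * w), h, w) * grain_on
  out <- clamp(warped - shadow_q + 8 * micro, 0, 255)
  inside <- mask > 0
  res <- texture
  res[inside] <- out[inside]
  list(texture = res, crumple_field = intensity * fpos)
}

#' Deposit a blood stain on a gauze scene
#'
#' Stain seeds are drawn inside the gauze mask with probability increasing in
#' the local crumple amplitude, so blood and folds co-locate (crumpled areas
#' absorb more blood). Each seed contributes an isotropic Gaussian density of
#' standard deviation `stain_spread`; the number of seeds grows with mass, so
#' the stained area is non-decreasing in `blood_mass_g` at a fixed seed. The
#' per-pixel mass map is the density renormalised to sum exactly to the mass.
#' Stain darkness carries a per-scene random factor: two gauzes with the same
#' mass can look differently dark, as real blood does with age and depth.
#'
#' @param scene list with `frame` (H x W x 3, 0--255), `gauze_mask`
#'   (0/1 matrix) and `crumple_field`.
#' @param blood_mass_g total stain mass in grams (>= 0).
#' @param stain_spread stain kernel standard deviation in pixels.
#' @param seed integer seed.
#' @return list with `frame` (stained RGB), `blood_mass_map` (grams per
#'   pixel, summing to `blood_mass_g`) and `stain_alpha` (opacity in
#'   \[0, 1\], the rendered stain footprint).
#' @export
apply_blood_stain <- function(scene, blood_mass_g, stain_spread, seed = 1L) {
  stopifnot(is.list(scene), !is.null(scene$frame), !is.null(scene$gauze_mask))
  assert_scalar_num(blood_mass_g, "blood_mass_g", lo = 0)
  assert_scalar_num(stain_spread, "stain_spread", lo = 0, strict_lo = TRUE)
  mask <- scene$gauze_mask
  h <- nrow(mask); w <- ncol(mask)
  if (sum(mask) == 0) abort("no gauze region")
  zero_map <- matrix(0, h, w)
  if (blood_mass_g == 0) {
    return(list(frame = scene$frame, blood_mass_map = zero_map,
                stain_alpha = zero_map))
  }
  set.seed(derive_seed(seed, "stain"))
  field <- scene$crumple_field %||% zero_map
  fn <- if (max(field) > 0) field / max(field) else zero_map
  idx <- which(mask > 0)
  prob <- (0.15 + fn[idx])^2

  # a fixed ordered pool of candidate seeds: lower masses use a prefix of the
  # pool, so the stained footprint is nested (monotone) across masses
  n_pool <- min(52L, length(idx))
  pool <- sample(idx, n_pool, prob = prob)
  darkness <- runif(1, 0.55, 0.95)
  # The stained footprint saturates as the gauze approaches soaked: beyond a
  # few grams extra blood deepens the stain rather than spreading it, so
  # visible area alone cannot resolve heavy gauze. A lognormal absorption
  # factor adds scene-to-scene spread. Both respect monotonicity in mass at
  # a fixed seed.
  absorb <- exp(rnorm(1, 0, 0.3))
  footprint <- 2 + 40 * (1 - exp(-blood_mass_g / 2.2))
  n_seeds <- min(n_pool, max(1L, as.integer(round(footprint * absorb))))
  seeds <- pool[seq_len(n_seeds)]

  dens <- zero_map
  rs <- seq_len(h); cs <- seq_len(w)
  for (s in seeds) {
    sr <- ((s - 1L) %% h) + 1L
    sc <- ((s - 1L) %/% h) + 1L
    dens <- dens + outer(exp(-(rs - sr)^2 / (2 * stain_spread^2)),
                         exp(-(cs - sc)^2 / (2 * stain_spread^2)))
  }
  dens <- dens * (mask > 0)
  blood_mass_map <- dens / sum(dens) * blood_mass_g
  alpha <- 1 - exp(-1.2 * dens)
  # stains render as a few flat tiers with sharp boundaries, the way blood
  # dries into rings on cloth: a continuous alpha ramp would overwrite the
  # fabric's intensity plateaus everywhere and erase the texture ties the
  # crumple analysis reads, whereas wide tiered rings keep them inside each
  # ring (rings must be wider than the LBP sampling circle to do so)
  # opacity is capped: even soaked cloth transmits its texture, so the
  # crumple-analysis stage keeps its signal inside the stain
  alpha <- round(alpha / 0.34) * 0.34
  alpha[alpha < 0.34] <- 0
  alpha <- pmin(alpha, 0.68)

  col <- darkness * c(170, 22, 28)
  frame <- scene$frame
  for (ch in 1:3) {
    frame[, , ch] <- (1 - alpha) * frame[, , ch] + alpha * col[ch]
  }
  list(frame = frame, blood_mass_map = blood_mass_map, stain_alpha = alpha)
}

render_background <- function(params) {
  h <- params$image_height; w <- params$image_width
  set.seed(derive_seed(params$seed, "background"))
  f <- band_limited_noise(h, w, cells = c(4L, 10L))
  rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  vr <- sqrt(((rows - h / 2) / (h / 2))^2 + ((cols - w / 2) / (w / 2))^2)
  vignette <- 1 - 0.35 * clamp(vr - 0.4, 0, 1)
  base <- if (params$background_kind == "tissue") c(138, 60, 55) else c(40, 24, 26)
  mod <- (1 + 0.22 * f) * vignette
  frame <- array(0, c(h, w, 3))
  for (ch in 1:3) frame[, , ch] <- clamp(base[ch] * mod, 0, 255)
  frame
}

#' Generate one complete synthetic scene
#'
#' Composes background, woven gauze, crumpling and blood stain into a frame
#' with full ground truth. Everything is a deterministic function of
#' `params` (including its seed).
#'
#' @param params a [scene_params()] object.
#' @return an object of class `scene_sample`: list with `frame` (H x W x 3,
#'   0--255), `gauze_mask`, `blood_mass_map` (sums to `ebl_label_g`),
#'   `crumple_field`, `stain_alpha`, `ebl_label_g`, `gauze_id`, `patient_id`
#'   and the generating `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  tex <- generate_gauze_texture(params)
  # blood-era folds: stains will co-locate with this field
  cr <- apply_crumple(tex$texture, tex$gauze_mask, params$crumple_intensity,
                      seed = params$seed)
  bg <- render_background(params)
  inside <- tex$gauze_mask > 0
  frame <- bg
  tint <- c(1.0, 0.985, 0.95)  # slightly warm gauze white
  for (ch in 1:3) {
    plane <- frame[, , ch]
    plane[inside] <- cr$texture[inside] * tint[ch]
    frame[, , ch] <- plane
  }
  st <- apply_blood_stain(list(frame = frame, gauze_mask = tex$gauze_mask,
                               crumple_field = cr$crumple_field),
                          params$blood_mass_g, params$stain_spread,
                          seed = params$seed)
  frame <- st$frame
  total_field <- cr$crumple_field
  if (params$handling_intensity > 0) {
    # handling folds: added after staining and confined to a localized
    # region (grasping crumples part of the gauze), spatially independent
    # of the blood, so they perturb texture without any stain evidence
    gray <- rgb_to_gray(frame)
    hc <- apply_crumple(gray, tex$gauze_mask, params$handling_intensity,
                        seed = derive_seed(params$seed, "handling"))
    set.seed(derive_seed(params$seed, "handlingregion"))
    region <- band_limited_noise(dim(gray)[1], dim(gray)[2],
                                 cells = c(8L, 16L)) > 0.55
    ratio <- ifelse(gray > 1e-9, hc$texture / pmax(gray, 1e-9), 1)
    ratio[tex$gauze_mask == 0 | !region] <- 1
    for (ch in 1:3) frame[, , ch] <- clamp(frame[, , ch] * ratio, 0, 255)
    total_field <- total_field + hc$crumple_field * region
  }
  structure(list(frame = frame, gauze_mask = tex$gauze_mask,
                 blood_mass_map = st$blood_mass_map,
                 crumple_field = total_field,
                 stain_alpha = st$stain_alpha,
                 ebl_label_g = params$blood_mass_g,
                 gauze_id = "", patient_id = "", params = params),
            class = "scene_sample")
}

#' Sample gauze blood masses from the simulated surgical distribution
#'
#' Right-skewed gamma draws (shape 2.2, scale 1.9; mean about 4.2 g)
#' truncated by rejection to the weighed-gauze range, emulating the blood
#' mass distribution of gauze retrieved during laparoscopic surgery
#' (0.13--9.98 g, mean 4.17 g).
#'
#' @param n number of masses.
#' @param range truncation range in grams.
#' @param shape,scale gamma parameters.
#' @return numeric vector of n masses in grams.
#' @export
sample_ebl_masses <- function(n, range = c(0.13, 9.98), shape = 2.2, scale = 1.9) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rgamma(2 * (n - length(out)) + 8, shape = shape, scale = scale)
    out <- c(out, draw[draw >= range[1] & draw <= range[2]])
  }
  out[seq_len(n)]
}

# Scene parameter draws for a dataset: crumple amplitude is coupled to blood
# mass (heavier gauze is more crumpled -- the premise the CSV features exploit),
# plus scene-to-scene nuisance in spread, coverage and background.
draw_scene_params <- function(i, mass, seed, image_size) {
  sseed <- derive_seed(seed, paste0("scene", i))
  set.seed(sseed)
  crumple <- clamp(0.35 + 0.22 * mass + rnorm(1, sd = 0.1), 0.05, 3.5)
  scene_params(
    image_height = image_size[1], image_width = image_size[2],
    gauze_area_fraction = runif(1, 0.25, 0.45),
    crumple_intensity = crumple,
    handling_intensity = runif(1, 0, 1),
    blood_mass_g = mass,
    stain_spread = runif(1, 9, 16),
    background_kind = if (runif(1) < 0.75) "tissue" else "dark_cavity",
    seed = sseed
  )
}

#' Generate a set of scenes in memory
#'
#' Convenience wrapper used by [generate_dataset()], tests and training:
#' draws masses, couples crumple intensity to mass, assigns gauze and
#' synthetic patient identifiers and renders every scene.
#'
#' @param n number of gauze scenes (>= 1).
#' @param seed integer seed.
#' @param image_size `c(height, width)` in pixels.
#' @param masses optional numeric vector of blood masses (grams); defaults to
#'   [sample_ebl_masses()] draws.
#' @return list with `scenes` (list of `scene_sample`) and `info` (tibble
#'   with gauze_id, patient_id, ebl_g).
#' @export
generate_scene_set <- function(n, seed = 1L, image_size = c(256L, 256L),
                               masses = NULL) {
  stopifnot(n >= 1)
  set.seed(derive_seed(seed, "sceneset"))
  if (is.null(masses)) masses <- sample_ebl_masses(n)
  stopifnot(length(masses) == n)
  patient_id <- assign_patients(n, seed)
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    p <- draw_scene_params(i, masses[i], seed, image_size)
    sc <- generate_scene(p)
    sc$gauze_id <- sprintf("G%04d", i)
    sc$patient_id <- patient_id[i]
    scenes[[i]] <- sc
  }
  info <- tibble::tibble(gauze_id = vapply(scenes, `[[`, "", "gauze_id"),
                         patient_id = patient_id, ebl_g = masses)
  list(scenes = scenes, info = info)
}

# 1-10 gauzes per synthetic patient, consecutive in generation order
assign_patients <- function(n, seed) {
  set.seed(derive_seed(seed, "patients"))
  sizes <- integer(0)
  while (sum(sizes) < n) sizes <- c(sizes, sample.int(10L, 1L))
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  sizes <- sizes[sizes > 0]
  rep(sprintf("P%03d", seq_along(sizes)), times = sizes)
}

#' EBL-stratified train/validation/test assignment
#'
#' Exact-integer-ratio split: gauzes are sorted by blood mass and the ratio
#' pattern is assigned within consecutive blocks (shuffled within each
#' block), so every split covers the whole weight range.
#'
#' @param masses numeric vector of blood masses (grams).
#' @param split_ratio integer `c(train, val, test)` ratio.
#' @param seed integer seed.
#' @return character vector of `"train"`/`"val"`/`"test"` labels.
#' @export
stratified_split <- function(masses, split_ratio = c(3, 1, 1), seed = 1L) {
  stopifnot(all(split_ratio > 0), length(split_ratio) == 3L)
  ratio <- as.integer(split_ratio)
  if (any(ratio != split_ratio)) abort("`split_ratio` must be integers, e.g. c(3, 1, 1)")
  set.seed(derive_seed(seed, "split"))
  n <- length(masses)
  block <- sum(ratio)
  pattern <- rep(c("train", "val", "test"), times = ratio)
  ord <- order(masses)
  lab <- character(n)
  pos <- 1L
  while (pos <= n) {
    take <- min(block, n - pos + 1L)
    labs <- sample(pattern)[seq_len(take)]
    lab[ord[pos:(pos + take - 1L)]] <- labs
    pos <- pos + take
  }
  lab
}

#' Generate a synthetic gauze dataset on disk
#'
#' Renders `n` scenes, writes frames and masks as PNG (plus the per-pixel
#' blood-mass share map as 32-bit float TIFF), splits them 3:1:1 (or any
#' integer ratio) into train/validation/test strata covering the whole EBL
#' range, and writes a `manifest.csv` plus the effective configuration.
#'
#' @param n number of gauzes (>= 5).
#' @param dir output directory (created if needed).
#' @param split_ratio integer train:val:test ratio, default `c(3, 1, 1)`.
#' @param seed integer seed.
#' @param image_size `c(height, width)` pixels.
#' @param masses optional mass vector (grams); default draws from
#'   [sample_ebl_masses()].
#' @param write_massmaps write the float TIFF mass share maps (default TRUE).
#' @return the manifest tibble with columns `frame_path`, `mask_path`,
#'   `massmap_path`, `gauze_id`, `patient_id`, `ebl_g`, `split`.
#' @export
generate_dataset <- function(n, dir, split_ratio = c(3, 1, 1), seed = 1L,
                             image_size = c(256L, 256L), masses = NULL,
                             write_massmaps = TRUE) {
  if (n < 5) abort("`n` must be >= 5")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) abort(sprintf("cannot write to '%s'", dir))
  for (d in c("frames", "masks", if (write_massmaps) "massmaps")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  ss <- generate_scene_set(n, seed = seed, image_size = image_size, masses = masses)
  split <- stratified_split(ss$info$ebl_g, split_ratio, seed)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- ss$scenes[[i]]
    fp <- file.path(dir, "frames", paste0(sc$gauze_id, ".png"))
    mp <- file.path(dir, "masks", paste0(sc$gauze_id, ".png"))
    write_frame_png(sc$frame, fp)
    write_mask_png(sc$gauze_mask, mp)
    zp <- NA_character_
    if (write_massmaps) {
      zp <- file.path(dir, "massmaps", paste0(sc$gauze_id, ".tif"))
      share <- if (sc$ebl_label_g > 0) sc$blood_mass_map / sc$ebl_label_g
               else sc$blood_mass_map
      tiff::writeTIFF(share, zp, bits.per.sample = 32L)
    }
    rows[[i]] <- tibble::tibble(frame_path = fp, mask_path = mp,
                                massmap_path = zp,
                                gauze_id = sc$gauze_id,
                                patient_id = sc$patient_id,
                                ebl_g = sc$ebl_label_g, split = split[i])
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(list(n = n, seed = as.integer(seed),
                        split_ratio = as.integer(split_ratio),
                        image_size = as.integer(image_size)),
                   file.path(dir, "config.yaml"))
  manifest
}

write_frame_png <- function(frame, path) {
  EBImage::writeImage(EBImage::Image(aperm(frame, c(2, 1, 3)) / 255,
                                     colormode = "Color"), path)
}

write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask)), path)
}

#' Read a frame (and optionally mask / mass map) back from a manifest row
#'
#' @param row one manifest row (tibble or list) as written by
#'   [generate_dataset()].
#' @return list with `frame` (H x W x 3, 0--255), `gauze_mask` (0/1 matrix or
#'   NULL), `blood_mass_map` (grams, or NULL), `ebl_label_g`, `gauze_id`,
#'   `patient_id`.
#' @export
read_scene <- function(row) {
  fr <- EBImage::imageData(EBImage::readImage(row$frame_path))
  frame <- aperm(fr, c(2, 1, 3)) * 255
  mask <- NULL
  if (!is.null(row$mask_path) && !is.na(row$mask_path)) {
    m <- EBImage::imageData(EBImage::readImage(row$mask_path))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    mask <- t(m)
    mask <- matrix(as.integer(mask > 0.5), nrow(mask), ncol(mask))
  }
  mm <- NULL
  if (!is.null(row$massmap_path) && !is.na(row$massmap_path)) {
    share <- tiff::readTIFF(row$massmap_path)
    mm <- share * row$ebl_g
  }
  list(frame = frame, gauze_mask = mask, blood_mass_map = mm,
       ebl_label_g = row$ebl_g, gauze_id = row$gauze_id,
       patient_id = row$patient_id)
}
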