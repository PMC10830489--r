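test_that("constant and strict-local-maximum images give the forced codes", {
  cm <- lbp_map(matrix(100, 20, 20))
  expect_true(all(cm$codes[cm$valid_mask > 0] == 255))
  expect_true(all(is.na(cm$codes[cm$valid_mask == 0])))

  # a center strictly above every sampled neighbour codes to 0
  img <- matrix(50, 15, 15)
  img[8, 8] <- 200
  lm <- lbp_map(img)
  expect_equal(lm$codes[8, 8], 0L)
})

test_that("fast LBP equals the brute-force oracle in both sampling modes", {
  set.seed(42)
  for (i in 1:12) {
    img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    for (mode in c("bilinear", "nearest")) {
      fast <- lbp_map(img, lbp_config(sampling = mode))
      slow <- lbp_oracle(img, sampling = mode)
      expect_identical(fast$codes, slow)
    }
  }
})

test_that("LBP codes stay in range and reject colour input", {
  set.seed(7)
  img <- matrix(runif(900, 0, 255), 30, 30)
  lm <- lbp_map(img)
  codes <- lm$codes[lm$valid_mask > 0]
  expect_true(all(codes >= 0 & codes <= 255))
  expect_error(lbp_map(array(0, c(20, 20, 3))), "rgb_to_gray")
  expect_error(lbp_map(matrix(1, 5, 5)), "exceed")
})

test_that("monotone gray-level transforms leave nearest-sampling LBP unchanged", {
  set.seed(13)
  img <- matrix(sample(0:200, 625, replace = TRUE), 25, 25)
  cfg <- lbp_config(sampling = "nearest")
  base <- lbp_map(img, cfg)
  for (tf in list(function(x) x + 30, function(x) 1.7 * x + 2,
                  function(x) x^2 / 40)) {
    expect_identical(lbp_map(tf(img), cfg)$codes, base$codes)
  }
  mask <- matrix(1L, 25, 25)
  expect_equal(compute_csv(lbp_map(img + 30, cfg), mask)$csv,
               compute_csv(base, mask)$csv)
})

test_that("CSV is the exact mean code over the valid gauze region", {
  sc <- tiny_scene(seed = 5)
  gray <- rgb_to_gray(sc$frame)
  lm <- lbp_map(gray)
  cs <- compute_csv(lm, sc$gauze_mask)
  expect_gte(cs$csv, 0)
  expect_lte(cs$csv, 255)

  # independent re-summation
  sel <- sc$gauze_mask > 0 & lm$valid_mask > 0
  s <- 0; n <- 0
  for (v in lm$codes[sel]) { s <- s + v; n <- n + 1 }
  expect_equal(cs$csv, s / n, tolerance = 1e-9)
  expect_equal(cs$region_pixel_count, n)

  # single-pixel region: CSV equals that code
  one <- matrix(0L, nrow(gray), ncol(gray))
  one[60, 60] <- 1L
  expect_equal(compute_csv(lm, one)$csv, as.numeric(lm$codes[60, 60]))

  # empty intersection errors
  border <- matrix(0L, nrow(gray), ncol(gray))
  border[1, 1] <- 1L
  expect_error(compute_csv(lm, border), "no valid gauze pixels")
})

test_that("crumpled and flat gauze CSVs separate distributionally", {
  csv_at <- function(ci, sd) {
    s <- generate_scene(scene_params(image_height = 128L, image_width = 128L,
                                     crumple_intensity = ci, blood_mass_g = 0,
                                     seed = sd))
    compute_csv(lbp_map(rgb_to_gray(s$frame)), s$gauze_mask)$csv
  }
  flat <- vapply(1:15, function(sd) csv_at(0, sd), numeric(1))
  crumpled <- vapply(1:15, function(sd) csv_at(2, sd), numeric(1))
  expect_lt(stats::wilcox.test(flat, crumpled)$p.value, 0.01)
})

test_that("patch descriptors weight, sort and pad as declared", {
  sc <- tiny_scene(seed = 9, mass = 6)
  spec <- tile_spec(tile_size = 32L, stride = 32L)
  tl <- tile_frame(sc$frame, spec)
  cls <- dplyr::mutate(dplyr::select(tl, -image),
                       background = 0, clean = 0, stained = 0.5, soaked = 0)
  patches <- extract_patches(sc$frame, sc$gauze_mask, cls, spec,
                             blood_mass_map = sc$blood_mass_map)
  expect_gt(nrow(patches), 0)

  pd_u <- patch_descriptors(patches, weighting = "uniform")
  expect_equal(pd_u$descriptors$weighted_csv, pd_u$descriptors$csv)

  pd_g <- patch_descriptors(patches, weighting = "ground_truth_mass")
  ranking <- order(pd_g$descriptors$weighted_csv, decreasing = TRUE)
  by_hand <- order(patches$patch_mass_g * pd_g$descriptors$csv,
                   decreasing = TRUE)
  expect_equal(ranking, by_hand)

  v <- pd_g$fixed_vector
  expect_length(v, 16)
  expect_true(all(diff(v) <= 1e-12))
  k <- nrow(patches)
  if (k < 16) expect_true(all(v[(k + 1):16] == 0))

  expect_warning(pd0 <- patch_descriptors(patches[0, ]), "no gauze patches")
  expect_equal(pd0$fixed_vector, numeric(16))
})
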