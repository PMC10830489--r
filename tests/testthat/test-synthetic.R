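test_that("scene generation is deterministic and respects the area contract", {
  p <- scene_params(gauze_area_fraction = 0.5, seed = 7)
  a <- generate_gauze_texture(p)
  b <- generate_gauze_texture(p)
  expect_identical(a, b)

  frac <- mean(a$gauze_mask)
  expect_gte(frac, 0.45)
  expect_lte(frac, 0.55)

  s1 <- generate_scene(p)
  s2 <- generate_scene(scene_params(gauze_area_fraction = 0.5, seed = 7))
  expect_identical(s1$frame, s2$frame)
  expect_identical(s1$blood_mass_map, s2$blood_mass_map)
})

test_that("gauze region is a single connected component", {
  for (sd in c(1, 5, 9)) {
    tex <- generate_gauze_texture(scene_params(seed = sd))
    labelled <- EBImage::bwlabel(EBImage::Image(t(tex$gauze_mask)))
    expect_equal(max(labelled), 1)
  }
})

test_that("scene parameter validation rejects bad inputs", {
  expect_error(scene_params(gauze_area_fraction = 0), "gauze_area_fraction")
  expect_error(scene_params(gauze_area_fraction = 1), "gauze_area_fraction")
  expect_error(scene_params(crumple_intensity = -1), "crumple_intensity")
  expect_error(scene_params(blood_mass_g = 12), "outside simulation range")
  expect_error(apply_crumple(matrix(1, 64, 64), matrix(1L, 64, 64), -0.5),
               "intensity")
})

test_that("crumple at zero intensity is the identity and variance grows with it", {
  p <- scene_params(seed = 3)
  tex <- generate_gauze_texture(p)
  cr0 <- apply_crumple(tex$texture, tex$gauze_mask, 0, seed = 3)
  expect_identical(cr0$texture, tex$texture)
  expect_true(all(cr0$crumple_field == 0))

  lv <- vapply(c(0, 0.5, 1, 2, 3), function(ci) {
    cr <- apply_crumple(tex$texture, tex$gauze_mask, ci, seed = 3)
    expect_true(all(cr$texture >= 0 & cr$texture <= 255))
    mean(local_variance(cr$texture, 7, tex$gauze_mask))
  }, numeric(1))
  expect_true(all(diff(lv) >= 0))
})

test_that("blood stain conserves mass, stays on gauze, grows with mass", {
  base <- generate_scene(scene_params(seed = 11, blood_mass_g = 0))
  expect_true(all(base$blood_mass_map == 0))

  sc <- list(frame = base$frame, gauze_mask = base$gauze_mask,
             crumple_field = base$crumple_field)
  st0 <- apply_blood_stain(sc, 0, 12, seed = 11)
  expect_identical(st0$frame, base$frame)

  st <- apply_blood_stain(sc, 4.17, 12, seed = 11)
  expect_equal(sum(st$blood_mass_map), 4.17, tolerance = 1e-9)
  expect_true(all(st$blood_mass_map[base$gauze_mask == 0] == 0))

  counts <- vapply(c(0.5, 1, 2, 4, 8), function(m) {
    sum(apply_blood_stain(sc, m, 12, seed = 11)$stain_alpha > 0.05)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))

  empty <- list(frame = base$frame,
                gauze_mask = matrix(0L, nrow(base$gauze_mask), ncol(base$gauze_mask)),
                crumple_field = base$crumple_field)
  expect_error(apply_blood_stain(empty, 1, 12), "no gauze region")
})

test_that("every generated sample conserves mass and aligns its grids", {
  ss <- generate_scene_set(6, seed = 2, image_size = c(128L, 128L))
  for (sc in ss$scenes) {
    expect_equal(sum(sc$blood_mass_map), sc$ebl_label_g, tolerance = 1e-6)
    expect_true(all(sc$blood_mass_map[sc$gauze_mask == 0] == 0))
    expect_identical(dim(sc$frame)[1:2], dim(sc$gauze_mask))
    expect_identical(dim(sc$crumple_field), dim(sc$gauze_mask))
    expect_true(all(sc$frame >= 0 & sc$frame <= 255))
  }
})

test_that("dataset generation writes an exact stratified split and manifest", {
  dir <- withr::local_tempdir()
  manifest <- generate_dataset(100, dir, seed = 4, image_size = c(64L, 64L))
  expect_equal(nrow(manifest), 100)
  expect_equal(unname(table(manifest$split)[c("train", "val", "test")]),
               c(60L, 20L, 20L), ignore_attr = TRUE)

  rng <- range(manifest$ebl_g)
  span <- diff(rng)
  for (sp in c("train", "val", "test")) {
    r <- range(manifest$ebl_g[manifest$split == sp])
    expect_lte(abs(r[1] - rng[1]), 0.15 * span)
    expect_lte(abs(r[2] - rng[2]), 0.15 * span)
  }

  sizes <- table(manifest$patient_id)
  expect_true(all(sizes >= 1 & sizes <= 10))

  on_disk <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(on_disk), 100)

  sc <- read_scene(manifest[1, ])
  expect_equal(dim(sc$frame), c(64, 64, 3))
  expect_equal(sum(sc$blood_mass_map), manifest$ebl_g[1], tolerance = 1e-4)
  expect_gt(sum(sc$gauze_mask), 0)
})

test_that("mass sampler stays in the surgical range with the right mean", {
  set.seed(99)
  m <- sample_ebl_masses(4000)
  expect_true(all(m >= 0.13 & m <= 9.98))
  expect_equal(mean(m), 4.17, tolerance = 0.15)
})
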