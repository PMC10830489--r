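make_feature_set <- function(n = 24, seed = 1, input_side = 32L) {
  ss <- generate_scene_set(n, seed = seed, image_size = c(128L, 128L))
  feats <- regression_features(ss$scenes, spec = tile_spec(tile_size = 32),
                               input_side = input_side)
  feats$split <- rep_len(c("train", "train", "train", "val"), n)
  feats
}

test_that("training minimises the configured loss and is reproducible", {
  feats <- make_feature_set(20, seed = 3)
  cfg <- regression_config(variant = "cs", input_side = 32L, epochs = 4,
                           batch_size = 8L, seed = 2)
  fit <- train_regressor(build_model(cfg), feats)
  h <- tidy(fit)
  expect_equal(nrow(h), 4)
  expect_lte(min(h$val_loss), h$val_loss[1])

  fit2 <- train_regressor(build_model(cfg), feats)
  expect_identical(tidy(fit), tidy(fit2))

  # recorded first-epoch loss equals the hand-computed loss of the same
  # batches (single batch covering the train split, untrained weights)
  cfg1 <- regression_config(variant = "cs", input_side = 32L, epochs = 1,
                            batch_size = 64L, seed = 2)
  tr <- which(feats$split == "train")
  fit1 <- train_regressor(build_model(cfg1), feats)
  m0 <- build_model(cfg1)
  inorm <- gauzeloss:::channel_norm(feats$image[tr])
  fm <- gauzeloss:::feature_matrix(feats, cfg1)
  fw <- gauzeloss:::model_forward(m0, gauzeloss:::stack_images(feats$image[tr], inorm),
                                  fm$x[tr, , drop = FALSE])
  expect_equal(fit1$history$train_loss[1],
               loss_mae(fw$pred, feats$ebl_g[tr])$loss, tolerance = 1e-6)

  # MAE and MSE runs record different losses on identical data
  cfg_mse <- regression_config(variant = "cs", input_side = 32L, epochs = 1,
                               batch_size = 64L, loss = "mse", seed = 2)
  fit_mse <- train_regressor(build_model(cfg_mse), feats)
  expect_equal(fit_mse$history$train_loss[1],
               loss_mse(fw$pred, feats$ebl_g[tr])$loss, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(fit1$history$train_loss[1],
                                fit_mse$history$train_loss[1])))
})

test_that("prediction is clamped, pure and order-preserving", {
  feats <- make_feature_set(16, seed = 5)
  cfg <- regression_config(variant = "base", input_side = 32L, epochs = 2,
                           batch_size = 8L, seed = 1)
  fit <- train_regressor(build_model(cfg), feats)
  p1 <- predict_ebl(fit, feats)
  p2 <- predict_ebl(fit, feats)
  expect_identical(p1, p2)
  expect_true(all(p1$pred_ebl_g >= 0, na.rm = TRUE))
  expect_equal(p1$gauze_id, feats$gauze_id)

  # clamping: a raw negative head output is reported as 0
  neg <- fit
  bias_layer <- length(neg$model$head) - 1L
  neg$model$head[[bias_layer]]$params$b <- neg$model$head[[bias_layer]]$params$b - 1e3
  pneg <- predict_ebl(neg, feats)
  expect_true(all(pneg$pred_ebl_g == 0, na.rm = TRUE))
})

test_that("missing features for a variant are reported by gauze id", {
  feats <- make_feature_set(8, seed = 7)
  feats$csv[2] <- NA_real_
  cfg <- regression_config(variant = "cs", input_side = 32L, epochs = 1,
                           seed = 1)
  expect_error(train_regressor(build_model(cfg), feats),
               feats$gauze_id[2])
  cfgb <- regression_config(variant = "base", input_side = 32L, epochs = 1,
                            batch_size = 8L, seed = 1)
  expect_silent(fitb <- train_regressor(build_model(cfgb), feats))
  expect_error(train_regressor(build_model(cfgb), feats[0, ]), "val sample")
})

test_that("trained models track the simulated blood mass", {
  ss <- generate_scene_set(60, seed = 9, image_size = c(128L, 128L))
  feats <- regression_features(ss$scenes, spec = tile_spec(tile_size = 32),
                               input_side = 32L)
  feats$split <- rep_len(c("train", "train", "train", "val", "test"), 60)
  cfg <- regression_config(variant = "cs", input_side = 32L, epochs = 12,
                           batch_size = 16L, seed = 4)
  fit <- train_regressor(build_model(cfg), feats)
  te <- feats$split == "test"
  preds <- predict_ebl(fit, feats[te, ])
  expect_gt(stats::cor(preds$pred_ebl_g, preds$true_ebl_g), 0.5)
})
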