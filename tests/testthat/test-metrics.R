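test_that("error metrics match their worked values and naive oracles", {
  expect_equal(mae(c(1, 5), c(2, 4)), 1.0)
  expect_equal(mape(c(1, 5), c(2, 4)), 37.5)
  expect_equal(mae(c(2, 4), c(2, 4)), 0)
  expect_equal(mape(c(2, 4), c(2, 4)), 0)

  set.seed(10)
  truth <- runif(100, 0.5, 10); pred <- truth + rnorm(100)
  expect_equal(mae(pred, truth), mae_oracle(pred, truth), tolerance = 1e-12)
  expect_equal(mape(pred, truth), mape_oracle(pred, truth), tolerance = 1e-12)
  expect_equal(mse(pred, truth), mse_oracle(pred, truth), tolerance = 1e-12)

  # Jensen: mean of squares >= square of mean absolute error
  expect_gte(mse(pred, truth), mae(pred, truth)^2)

  expect_error(mae(1:3, 1:2), "length")
  expect_error(mape(c(1, 1), c(2, 0.005), ids = c("a", "b")), "b")
})

test_that("stratified reports partition, pool and expose imbalance", {
  set.seed(4)
  truth <- c(runif(40, 0.2, 3), runif(5, 3.01, 5), runif(3, 5.01, 9.9))
  pred <- truth * (1 + rnorm(48, 0, 0.15))
  tb <- tibble::tibble(true_ebl_g = truth, pred_ebl_g = pred,
                       gauze_id = sprintf("g%02d", 1:48))
  rep1 <- stratified_report(tb, overall = "both")
  expect_equal(sum(rep1$n[rep1$stratum %in% c("le3g", "g3to5", "gt5g")]), 48)
  pooled <- rep1$mape_pct[rep1$stratum == "all_pooled"]
  stratmean <- rep1$mape_pct[rep1$stratum == "all_stratum_mean"]
  expect_false(isTRUE(all.equal(pooled, stratmean)))
  expect_equal(pooled, mape(pred, truth), tolerance = 1e-12)

  # all samples in one stratum leaves the others empty with NA metrics
  low <- tibble::tibble(true_ebl_g = runif(10, 0.2, 2.9),
                        pred_ebl_g = runif(10, 0.2, 2.9))
  rep2 <- stratified_report(low)
  expect_equal(rep2$n[rep2$stratum == "g3to5"], 0)
  expect_true(is.na(rep2$mae_g[rep2$stratum == "gt5g"]))
  expect_error(stratified_report(low, strata = c(5, 3)), "increasing")
})

test_that("per-patient aggregation is additive and Bland-Altman is exact", {
  one <- tibble::tibble(patient_id = c("a", "b", "c"),
                        true_ebl_g = c(1, 2, 3), pred_ebl_g = c(1.2, 1.8, 3.5))
  pp1 <- per_patient_report(one)
  expect_equal(pp1$metrics$mae_g, mae(one$pred_ebl_g, one$true_ebl_g))

  # opposite per-gauze errors cancel in the patient total
  two <- tibble::tibble(patient_id = c("p", "p"),
                        true_ebl_g = c(2, 3), pred_ebl_g = c(2.3, 2.7))
  pp2 <- per_patient_report(two)
  expect_equal(pp2$metrics$mae_g, 0)

  set.seed(8)
  many <- tibble::tibble(patient_id = rep(sprintf("p%d", 1:12), each = 4),
                         true_ebl_g = runif(48, 0.5, 9),
                         pred_ebl_g = runif(48, 0.5, 9))
  pp3 <- per_patient_report(many)
  d <- pp3$totals$pred_total_g - pp3$totals$true_total_g
  expect_equal(pp3$bland_altman$bias_g, mean(d), tolerance = 1e-12)
  expect_equal(pp3$bland_altman$loa_low_g, mean(d) - 1.96 * sd(d),
               tolerance = 1e-12)
  expect_equal(pp3$bland_altman$loa_high_g, mean(d) + 1.96 * sd(d),
               tolerance = 1e-12)
  expect_lte(pp3$bland_altman$loa_low_g, pp3$bland_altman$bias_g)

  # per-patient error equals |sum of signed per-gauze errors|
  for (p in unique(many$patient_id)) {
    sel <- many$patient_id == p
    tot <- pp3$totals[pp3$totals$patient_id == p, ]
    expect_equal(abs(tot$pred_total_g - tot$true_total_g),
                 abs(sum(many$pred_ebl_g[sel] - many$true_ebl_g[sel])),
                 tolerance = 1e-12)
  }
})

test_that("relative improvement reproduces the two-decimal arithmetic", {
  expect_equal(relative_improvement(8.56, 6.97), 18.57)
  expect_equal(relative_improvement(9.10, 6.15), 32.42)
  expect_equal(relative_improvement(4, 4), 0)
  expect_error(relative_improvement(0, 1), "undefined")
})

test_that("grouped stratified k-fold partitions patients cleanly", {
  set.seed(2)
  manifest <- tibble::tibble(
    gauze_id = sprintf("g%03d", 1:60),
    patient_id = rep(sprintf("p%02d", 1:15), each = 4),
    ebl_g = runif(60, 0.2, 9.9))
  cv <- kfold_cv(manifest, k = 5,
                 train_fn = function(tr) mean(tr$ebl_g),
                 eval_fn = function(fit, te) {
                   tibble::tibble(mae_g = mae(rep(fit, nrow(te)), te$ebl_g))
                 }, seed = 3)
  sizes <- table(cv$folds$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sort(unique(cv$folds$patient_id)), sort(unique(manifest$patient_id)))
  expect_equal(nrow(cv$per_fold), 5)
  # no patient spans folds and the test folds cover every gauze exactly once
  joined <- dplyr::left_join(manifest, cv$folds, by = "patient_id")
  expect_false(anyNA(joined$fold))
  expect_equal(nrow(joined), 60)

  cv2 <- kfold_cv(manifest, k = 5,
                  train_fn = function(tr) mean(tr$ebl_g),
                  eval_fn = function(fit, te) tibble::tibble(m = fit), seed = 3)
  expect_identical(cv$folds, cv2$folds)
  expect_error(kfold_cv(manifest[1:4, ], k = 5, train_fn = identity,
                        eval_fn = identity), "fewer patients")
})
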