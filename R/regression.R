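#' Configuration of the gauze EBL regression network
#'
#' Three variants mirror the model comparison: `"base"` regresses blood mass
#' from the masked gauze image alone; `"cs"` additionally feeds the single
#' crumpled state value through an MLP whose output is concatenated with the
#' image feature; `"pwcs"` feeds the length-`n_vector` weighted patch-CSV
#' vector instead. Training defaults follow the published setup: batch size
#' 32, learning rate 5e-3, MAE loss, linear head activation.
#'
#' @param variant `"base"`, `"cs"` or `"pwcs"`.
#' @param backbone image feature backbone (see [train_tile_classifier()] for
#'   the available conv stacks).
#' @param head_activation `"linear"` (default) or `"relu"` on the output.
#' @param loss `"mae"` (default) or `"mse"`.
#' @param mlp_hidden widths of the CSV-branch MLP, default `c(32, 16)`.
#' @param input_side side of the resized masked-image input (default 64).
#' @param n_vector length of the patch-CSV vector (pwcs only).
#' @param batch_size,learning_rate,epochs,seed training hyper-parameters.
#' @return object of class `regression_config`.
#' @export
regression_config <- function(variant = c("base", "cs", "pwcs"),
                              backbone = "small_cnn",
                              head_activation = c("linear", "relu"),
                              loss = c("mae", "mse"),
                              mlp_hidden = c(32L, 16L), input_side = 64L,
                              n_vector = 16L, batch_size = 32L,
                              learning_rate = 5e-3, epochs = 25L, seed = 1L) {
  variant <- match.arg(variant)
  head_activation <- match.arg(head_activation)
  loss <- match.arg(loss)
  backbone_plan(backbone)  # errors on unknown backbone
  structure(list(variant = variant, backbone = backbone,
                 head_activation = head_activation, loss = loss,
                 mlp_hidden = as.integer(mlp_hidden),
                 input_side = as.integer(input_side),
                 n_vector = as.integer(n_vector),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "regression_config")
}

feat_width <- function(config) {
  switch(config$variant, base = 0L, cs = 1L, pwcs = config$n_vector)
}

#' Build an (untrained) EBL regression model
#'
#' Assembles the image backbone, the optional CSV MLP branch and the fused
#' regression head; initial weights are a pure function of the config seed,
#' so two builds with the same config are identical.
#'
#' @param config a [regression_config()].
#' @return object of class `ebl_model` with `img_branch`, `feat_branch`,
#'   `head` layer stacks and `n_params`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "regression_config"))
  set.seed(derive_seed(config$seed, "reg-init"))
  img_branch <- build_conv_stack(config$backbone)
  fw <- feat_width(config)
  feat_branch <- if (fw > 0) build_mlp(fw, config$mlp_hidden) else NULL
  concat_w <- backbone_out_width(config$backbone) +
    if (fw > 0) config$mlp_hidden[length(config$mlp_hidden)] else 0L
  head <- c(build_mlp(concat_w, 32L),
            list(nn_dense(32L, 1L), nn_act(config$head_activation)))
  structure(list(config = config, img_branch = img_branch,
                 feat_branch = feat_branch, head = head,
                 n_params = n_params(img_branch) + n_params(head) +
                   if (is.null(feat_branch)) 0 else n_params(feat_branch)),
            class = "ebl_model")
}

model_forward <- function(model, ximg, xfeat) {
  fi <- seq_forward(model$img_branch, ximg)
  model$img_branch <- fi$layers
  z <- fi$out
  if (!is.null(model$feat_branch)) {
    ff <- seq_forward(model$feat_branch, xfeat)
    model$feat_branch <- ff$layers
    z <- cbind(z, ff$out)
  }
  fh <- seq_forward(model$head, z)
  model$head <- fh$layers
  list(model = model, pred = as.vector(fh$out))
}

model_backward <- function(model, dpred) {
  bh <- seq_backward(model$head, matrix(dpred, ncol = 1),
                     need_input_grad = TRUE)
  model$head <- bh$layers
  dz <- bh$dx
  wimg <- backbone_out_width(model$config$backbone)
  bi <- seq_backward(model$img_branch, dz[, seq_len(wimg), drop = FALSE])
  model$img_branch <- bi$layers
  if (!is.null(model$feat_branch)) {
    bf <- seq_backward(model$feat_branch,
                       dz[, -seq_len(wimg), drop = FALSE])
    model$feat_branch <- bf$layers
  }
  model
}

model_adam <- function(model, lr, t, max_grad_norm = 5) {
  stacks <- list(img = model$img_branch, head = model$head)
  if (!is.null(model$feat_branch)) stacks$feat <- model$feat_branch
  stacks <- clip_grad_norm(stacks, max_grad_norm)
  model$img_branch <- adam_step(stacks$img, lr, t)
  model$head <- adam_step(stacks$head, lr, t)
  if (!is.null(model$feat_branch)) {
    model$feat_branch <- adam_step(stacks$feat, lr, t)
  }
  model
}

# Masked-image preprocessing: tight bounding-box crop, zero-pad to square,
# resize to the network input side.
masked_input_image <- function(frame, gauze_mask, input_side) {
  mi <- extract_masked_image(frame, gauze_mask)
  bb <- mi$bbox
  crop <- mi$image[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], , drop = FALSE]
  d <- dim(crop)
  side <- max(d[1:2])
  sq <- array(0, c(side, side, d[3]))
  ro <- (side - d[1]) %/% 2; co <- (side - d[2]) %/% 2
  sq[ro + seq_len(d[1]), co + seq_len(d[2]), ] <- crop
  resize_image(sq, input_side)
}

#' Build per-gauze regression features from scenes
#'
#' For each scene: obtain the gauze mask (from a trained detector, or the
#' simulation ground truth when `detector` is NULL), preprocess the masked
#' image, compute the whole-region CSV and the weighted patch-CSV vector.
#' With ground-truth masks the patch blood-evidence score is the fraction of
#' gauze pixels under visible stain; with a detector it is the tile's
#' stained + soaked probability. Frames whose mask comes out empty are
#' flagged `skipped`.
#'
#' @param scenes list of `scene_sample` objects (e.g.
#'   `generate_scene_set()$scenes`) or a manifest tibble from
#'   [generate_dataset()].
#' @param detector optional [train_tile_classifier()] fit.
#' @param spec [tile_spec()] for patch extraction.
#' @param lbp [lbp_config()] for texture codes.
#' @param weighting patch weighting mode, see [patch_descriptors()].
#' @param input_side masked-image input side, pixels.
#' @param n_vector patch vector length.
#' @param min_gauze_fraction patch mask-coverage threshold.
#' @return tibble with `gauze_id`, `patient_id`, `ebl_g`, list-columns
#'   `image` and `csv_vector`, scalar `csv`, `n_patches`, `skipped`,
#'   `skip_reason`.
#' @export
regression_features <- function(scenes, detector = NULL, spec = tile_spec(),
                                lbp = lbp_config(),
                                weighting = "blood_evidence",
                                input_side = 64L, n_vector = 16L,
                                min_gauze_fraction = 0.5) {
  if (is.data.frame(scenes)) {
    scenes <- lapply(seq_len(nrow(scenes)), function(i) read_scene(scenes[i, ]))
  }
  rows <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    gid <- sc$gauze_id %||% sprintf("G%04d", i)
    pid <- sc$patient_id %||% NA_character_
    ebl <- sc$ebl_label_g %||% NA_real_
    skel <- tibble::tibble(gauze_id = gid, patient_id = pid, ebl_g = ebl,
                           image = list(NULL), csv = NA_real_,
                           csv_vector = list(numeric(n_vector)),
                           n_patches = 0L, skipped = TRUE,
                           skip_reason = NA_character_)
    gray <- rgb_to_gray(sc$frame)
    if (!is.null(detector)) {
      tl <- tile_frame(sc$frame, spec)
      cls <- classify_tiles(detector, tl)
      mask <- assemble_mask(cls, dim(gray), spec)
    } else {
      mask <- sc$gauze_mask
      cls <- NULL
    }
    if (is.null(mask) || sum(mask) == 0) {
      skel$skip_reason <- "no gauze detected"
      rows[[i]] <- skel
      next
    }
    lm <- lbp_map(gray, lbp)
    cs <- compute_csv(lm, mask)
    if (is.null(cls)) {
      # ground-truth path: emulate tile classification from the simulation
      tl <- tile_frame(sc$frame, spec)
      alpha <- sc$stain_alpha %||% matrix(0, nrow(gray), ncol(gray))
      # blood evidence as a saturating selector: the peak stain opacity in
      # the patch (mirrors the detector's stained+soaked probability, which
      # saturates once any clear stain is visible in the tile)
      ev <- numeric(nrow(tl))
      for (j in seq_len(nrow(tl))) {
        rr <- (tl$r0[j] + 1L):(tl$r0[j] + spec$tile_size)
        cc <- (tl$c0[j] + 1L):(tl$c0[j] + spec$tile_size)
        mc <- mask[rr, cc] > 0
        ev[j] <- if (any(mc)) max(alpha[rr, cc][mc]) else 0
      }
      cls <- dplyr::mutate(dplyr::select(tl, -"image"),
                           background = 0, clean = 0, stained = ev,
                           soaked = 0)
    }
    patches <- extract_patches(sc$frame, mask, cls, spec,
                               min_gauze_fraction = min_gauze_fraction,
                               blood_mass_map = sc$blood_mass_map)
    pd <- patch_descriptors(patches, lbp, weighting = weighting,
                            n_vector = n_vector)
    skel$image <- list(masked_input_image(sc$frame, mask, input_side))
    skel$csv <- cs$csv
    skel$csv_vector <- list(pd$fixed_vector)
    skel$n_patches <- nrow(patches)
    skel$skipped <- FALSE
    rows[[i]] <- skel
  }
  dplyr::bind_rows(rows)
}

check_variant_features <- function(features, variant) {
  if (variant %in% c("cs", "pwcs")) {
    bad <- features$gauze_id[is.na(features$csv)]
    if (length(bad) > 0) {
      abort(sprintf("missing CSV features for variant '%s': %s", variant,
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  bad <- features$gauze_id[vapply(features$image, is.null, TRUE)]
  if (length(bad) > 0) {
    abort(sprintf("missing masked image for: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  invisible(features)
}

# CSV-feature scaling: every CSV input column is standardised by its
# training-split mean/sd (per sorted position for the patch vector, so the
# padded tail positions carry their own statistics). Constant columns are
# guarded with a unit sd.
feature_matrix <- function(features, config, fnorm = NULL) {
  fw <- feat_width(config)
  if (fw == 0L) return(list(x = NULL, norm = fnorm))
  x <- if (config$variant == "cs") {
    matrix(features$csv, ncol = 1)
  } else {
    do.call(rbind, features$csv_vector)
  }
  if (is.null(fnorm)) {
    sds <- apply(x, 2, stats::sd)
    fnorm <- list(mean = colMeans(x), sd = ifelse(sds > 1e-6, sds, 1))
  }
  x <- sweep(sweep(x, 2, fnorm$mean), 2, fnorm$sd, "/")
  # standardised features are clipped: a value far outside the training
  # range (e.g. a sorted position that was all-padding in training) must
  # not drive the network into extrapolation
  list(x = clamp(x, -5, 5), norm = fnorm)
}

#' Train an EBL regression model
#'
#' Minimises the configured loss (MAE by default) with Adam over the train
#' split, tracks train/validation loss per epoch and retains the weights of
#' the best validation epoch. CSV features are standardised by
#' training-split mean/sd; images are channel-normalised likewise; both sets
#' of constants are stored in the fit.
#'
#' @param model an [build_model()] result (or a [regression_config()], which
#'   is built first).
#' @param features tibble from [regression_features()] with an added `split`
#'   column containing `"train"` and `"val"`.
#' @param config optional override of the model's config.
#' @return object of class `ebl_regressor`: the trained model plus
#'   `history` (per-epoch tibble) and normalisation constants.
#' @export
train_regressor <- function(model, features, config = NULL) {
  if (inherits(model, "regression_config")) model <- build_model(model)
  stopifnot(inherits(model, "ebl_model"))
  config <- config %||% model$config
  if (is.null(features$split)) abort("`features` needs a split column")
  features <- features[!features$skipped, ]
  check_variant_features(features, config$variant)
  tr <- which(features$split == "train"); va <- which(features$split == "val")
  if (length(tr) < 1 || length(va) < 1) abort("need >= 1 train and 1 val sample")

  inorm <- channel_norm(features$image[tr])
  fm <- feature_matrix(features, config)
  xf <- fm$x
  y <- features$ebl_g
  loss_fn <- if (config$loss == "mae") loss_mae else loss_mse

  xval <- stack_images(features$image[va], inorm)
  xfval <- if (!is.null(xf)) xf[va, , drop = FALSE]
  best <- list(loss = Inf, model = model)
  history <- vector("list", config$epochs)
  set.seed(derive_seed(config$seed, "reg-train"))
  t_global <- 0L
  for (ep in seq_len(config$epochs)) {
    # step decay stabilises the late epochs of short CPU runs
    decay <- if (ep > 0.85 * config$epochs) 0.25 else {
      if (ep > 0.6 * config$epochs) 0.5 else 1
    }
    lr <- config$learning_rate * decay
    ord <- sample(tr)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      fw <- model_forward(model, stack_images(features$image[bi], inorm),
                          if (!is.null(xf)) xf[bi, , drop = FALSE])
      ls <- loss_fn(fw$pred, y[bi])
      if (!is.finite(ls$loss)) abort(sprintf("non-finite loss at epoch %d", ep))
      model <- model_backward(fw$model, ls$grad)
      t_global <- t_global + 1L
      model <- model_adam(model, lr, t_global)
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1L
    }
    fv <- model_forward(model, xval, xfval)
    vl <- loss_fn(fv$pred, y[va])$loss
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / nb,
                                    val_loss = vl)
    if (vl < best$loss) best <- list(loss = vl, model = model)
  }
  fit <- best$model
  fit$img_branch <- strip_training_state(fit$img_branch)
  fit$head <- strip_training_state(fit$head)
  if (!is.null(fit$feat_branch)) {
    fit$feat_branch <- strip_training_state(fit$feat_branch)
  }
  structure(list(model = fit, config = config, image_norm = inorm,
                 feature_norm = fm$norm,
                 history = dplyr::bind_rows(history)),
            class = "ebl_regressor")
}

#' Predict per-gauze EBL
#'
#' Pure inference: identical inputs give identical outputs, predictions are
#' clamped at 0 g, and row order is preserved.
#'
#' @param fit an [train_regressor()] fit.
#' @param features tibble from [regression_features()] (skipped rows are
#'   carried through with `NA` predictions).
#' @param chunk inference batch size.
#' @return tibble `gauze_id`, `patient_id`, `true_ebl_g`, `pred_ebl_g`.
#' @export
predict_ebl <- function(fit, features, chunk = 64L) {
  stopifnot(inherits(fit, "ebl_regressor"))
  config <- fit$config
  ok <- which(!features$skipped)
  pred <- rep(NA_real_, nrow(features))
  if (length(ok) > 0) {
    feats <- features[ok, ]
    check_variant_features(feats, config$variant)
    fm <- feature_matrix(feats, config, fnorm = fit$feature_norm)
    for (b0 in seq(1, length(ok), by = chunk)) {
      bi <- b0:min(b0 + chunk - 1L, length(ok))
      fw <- model_forward(fit$model,
                          stack_images(feats$image[bi], fit$image_norm),
                          if (!is.null(fm$x)) fm$x[bi, , drop = FALSE])
      pred[ok[bi]] <- pmax(fw$pred, 0)
    }
  }
  tibble::tibble(gauze_id = features$gauze_id,
                 patient_id = features$patient_id,
                 true_ebl_g = features$ebl_g, pred_ebl_g = pred)
}

#' Run the full gauze EBL pipeline on frames
#'
#' For every frame: tile, classify, assemble the gauze mask, extract the
#' masked image and patches, compute CSV features and regress the blood
#' mass. Frames with no detected gauze are reported as skipped with a
#' reason, never dropped, so the output has exactly one row per input frame.
#'
#' @param scenes list of `scene_sample` objects, or a manifest tibble whose
#'   rows point at frame images.
#' @param detector a trained [train_tile_classifier()] fit.
#' @param regressor a trained [train_regressor()] fit.
#' @param spec [tile_spec()] used for detection and patches.
#' @param lbp [lbp_config()].
#' @return tibble with one row per frame: `gauze_id`, `patient_id`,
#'   `status` (`"predicted"` / `"skipped"`), `skip_reason`, `true_ebl_g`,
#'   `pred_ebl_g`.
#' @export
run_pipeline <- function(scenes, detector, regressor, spec = tile_spec(),
                         lbp = lbp_config()) {
  stopifnot(inherits(detector, "gauze_classifier"),
            inherits(regressor, "ebl_regressor"))
  feats <- regression_features(
    scenes, detector = detector, spec = spec, lbp = lbp,
    input_side = regressor$config$input_side,
    n_vector = regressor$config$n_vector)
  preds <- predict_ebl(regressor, feats)
  tibble::tibble(gauze_id = feats$gauze_id, patient_id = feats$patient_id,
                 status = ifelse(feats$skipped, "skipped", "predicted"),
                 skip_reason = feats$skip_reason,
                 true_ebl_g = preds$true_ebl_g, pred_ebl_g = preds$pred_ebl_g)
}

#' @export
print.ebl_model <- function(x, ...) {
  cat(sprintf("<ebl_model> variant=%s backbone=%s, %d parameters\n",
              x$config$variant, x$config$backbone, x$n_params))
  invisible(x)
}

#' @export
print.ebl_regressor <- function(x, ...) {
  cat(sprintf("<ebl_regressor> variant=%s backbone=%s, best val loss %.4f\n",
              x$config$variant, x$config$backbone, min(x$history$val_loss)))
  invisible(x)
}
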