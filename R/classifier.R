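#' Train the four-state tile classifier
#'
#' Learns to label tiles as background tissue, clean gauze, stained gauze or
#' soaked gauze. Tiles are split 3:1:1 per class into train/validation/test,
#' resized to `input_resize`, channel-normalised by training-split
#' statistics, and fed to a convolutional backbone (`"small_cnn"` by
#' default; EfficientNet-style width/depth-scaled stacks with swish
#' activation are available) trained with Adam on cross-entropy. The weights
#' of the best validation epoch are retained.
#'
#' @param tiles tibble with a list-column `image` (H x W x 3 arrays,
#'   0--255); if `labels` is NULL a `label` column is used.
#' @param labels character vector of tile states (subset of
#'   [tile_classes()]).
#' @param model_config list: `backbone`, `input_resize` (default 32),
#'   `head_width` (default 32).
#' @param train_config list: `epochs` (default 10), `batch_size` (32),
#'   `learning_rate` (1e-3), `seed` (1), `split_ratio` (c(3, 1, 1)).
#' @return object of class `gauze_classifier` with the fitted layers, class
#'   order, normalisation constants, per-epoch `history`, held-out test
#'   accuracy and gauze-vs-background [detection_metrics()].
#' @export
train_tile_classifier <- function(tiles, labels = NULL, model_config = list(),
                                  train_config = list()) {
  mc <- modifyList(list(backbone = "small_cnn", input_resize = 32L,
                        head_width = 32L), model_config)
  tc <- modifyList(list(epochs = 10L, batch_size = 32L, learning_rate = 1e-3,
                        seed = 1L, split_ratio = c(3, 1, 1)), train_config)
  labels <- labels %||% tiles$label
  stopifnot(length(labels) == nrow(tiles))
  if (!all(labels %in% tile_classes())) {
    abort(sprintf("labels must be among: %s", paste(tile_classes(), collapse = ", ")))
  }
  if (length(unique(labels)) < 2L) abort("need at least 2 classes to train")

  set.seed(derive_seed(tc$seed, "clf-split"))
  split <- character(length(labels))
  pattern <- rep(c("train", "val", "test"), times = tc$split_ratio)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    split[idx] <- rep_len(pattern, length(idx))
  }
  if (!any(split == "val")) split[sample(which(split == "train"), 1)] <- "val"

  imgs <- lapply(tiles$image, resize_image, side = mc$input_resize)
  y <- match(labels, tile_classes())
  norm <- channel_norm(imgs[split == "train"])

  set.seed(derive_seed(tc$seed, "clf-init"))
  layers <- c(build_conv_stack(mc$backbone),
              build_mlp(backbone_out_width(mc$backbone), mc$head_width),
              list(nn_dense(mc$head_width, 4L)))

  tr <- which(split == "train"); va <- which(split == "val")
  xval <- stack_images(imgs[va], norm)
  best <- list(loss = Inf, layers = layers)
  history <- vector("list", tc$epochs)
  set.seed(derive_seed(tc$seed, "clf-train"))
  t_global <- 0L
  for (ep in seq_len(tc$epochs)) {
    ord <- sample(tr)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1, length(ord), by = tc$batch_size)) {
      bi <- ord[b0:min(b0 + tc$batch_size - 1L, length(ord))]
      fw <- seq_forward(layers, stack_images(imgs[bi], norm))
      ls <- loss_xent(fw$out, y[bi])
      if (!is.finite(ls$loss)) abort(sprintf("non-finite loss at epoch %d", ep))
      bw <- seq_backward(fw$layers, ls$grad)
      t_global <- t_global + 1L
      layers <- adam_step(bw$layers, tc$learning_rate, t_global)
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1L
    }
    fv <- seq_forward(layers, xval)
    vl <- loss_xent(fv$out, y[va])
    vacc <- mean(apply(fv$out, 1, which.max) == y[va])
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / nb,
                                    val_loss = vl$loss, val_accuracy = vacc)
    if (vl$loss < best$loss) best <- list(loss = vl$loss, layers = layers)
  }
  fit <- structure(list(layers = strip_training_state(best$layers),
                        classes = tile_classes(),
                        input_resize = mc$input_resize, norm = norm,
                        backbone = mc$backbone,
                        n_params = n_params(best$layers),
                        history = dplyr::bind_rows(history),
                        config = list(model = mc, train = tc)),
                   class = "gauze_classifier")
  te <- which(split == "test")
  if (length(te) > 0) {
    probs <- classifier_probs(fit, imgs[te], resized = TRUE)
    pred <- tile_classes()[apply(probs, 1, which.max)]
    fit$test_accuracy <- mean(pred == labels[te])
    fit$test_detection <- detection_metrics(pred, labels[te])
  }
  fit
}

classifier_probs <- function(fit, imgs, resized = FALSE, chunk = 128L) {
  if (!resized) imgs <- lapply(imgs, resize_image, side = fit$input_resize)
  out <- matrix(0, length(imgs), 4L)
  for (b0 in seq(1, length(imgs), by = chunk)) {
    bi <- b0:min(b0 + chunk - 1L, length(imgs))
    fw <- seq_forward(fit$layers, stack_images(imgs[bi], fit$norm))
    out[bi, ] <- softmax_rows(fw$out)
  }
  colnames(out) <- tile_classes()
  out
}

#' Classify frame tiles into the four tile states
#'
#' Runs the classifier over the tiles of a frame and returns a probability
#' simplex per tile plus the hard label (argmax; exact ties resolve toward
#' the lower class index in the fixed order background, clean, stained,
#' soaked).
#'
#' @param fit a [train_tile_classifier()] fit.
#' @param tiles tibble from [tile_frame()].
#' @return the input tibble (minus the image column) with columns
#'   `background`, `clean`, `stained`, `soaked` and `hard_label`.
#' @export
classify_tiles <- function(fit, tiles) {
  stopifnot(inherits(fit, "gauze_classifier"))
  if (is.null(tiles) || nrow(tiles) == 0) abort("empty tile list")
  probs <- classifier_probs(fit, tiles$image)
  out <- dplyr::select(tiles, -"image")
  out <- dplyr::bind_cols(out, tibble::as_tibble(probs))
  out$hard_label <- tile_classes()[apply(probs, 1, which.max)]
  out
}

#' @export
print.gauze_classifier <- function(x, ...) {
  cat(sprintf("<gauze_classifier> backbone=%s, %d parameters, input %dpx\n",
              x$backbone, x$n_params, x$input_resize))
  if (!is.null(x$test_accuracy)) {
    cat(sprintf("  held-out tile accuracy: %.1f%%\n", 100 * x$test_accuracy))
  }
  invisible(x)
}

#' Generate a labelled synthetic tile dataset
#'
#' Renders scenes across the blood-mass range (including clean, mass-zero
#' gauze) and cuts them into ground-truth-labelled tiles: background when
#' gauze coverage is at most 20%, a gauze state when coverage is at least
#' 80% (clean/stained/soaked by the fraction of gauze pixels under visible
#' stain: < 5% clean, > 45% soaked); boundary-straddling tiles in between
#' are skipped, as in hand-curated tile collections. Collection stops when
#' every class reaches `n_per_class` (classes are truncated to that quota).
#'
#' @param n_per_class tiles wanted per gauze class.
#' @param background_multiplier background-tile quota as a multiple of
#'   `n_per_class` (default 2.75, matching the roughly 3:1
#'   background-to-gauze balance of curated laparoscopic tile collections).
#' @param tile_size tile side in pixels.
#' @param seed integer seed.
#' @param image_size scene size, `c(height, width)`.
#' @return tibble with list-column `image`, `label`, `gauze_id`.
#' @export
generate_tile_dataset <- function(n_per_class = 200L, tile_size = 64L,
                                  seed = 1L, image_size = c(256L, 256L),
                                  background_multiplier = 2.75) {
  spec <- tile_spec(tile_size = tile_size, stride = tile_size)
  mass_cycle <- c(0, 0, 0.6, 2.5, 4.17, 6.5, 8, 9.5)
  quota <- stats::setNames(rep(as.integer(n_per_class), 4), tile_classes())
  quota["background"] <- as.integer(round(background_multiplier * n_per_class))
  got <- stats::setNames(integer(4), tile_classes())
  acc <- list()
  chunk <- 0L
  while (any(got < quota) && chunk < 60L) {
    chunk <- chunk + 1L
    n_sc <- 8L
    masses <- rep_len(mass_cycle, n_sc)
    ss <- generate_scene_set(n_sc, seed = derive_seed(seed, paste0("tiles", chunk)),
                             image_size = image_size, masses = masses)
    for (sc in ss$scenes) {
      tl <- tile_frame(sc$frame, spec)
      for (i in seq_len(nrow(tl))) {
        rr <- (tl$r0[i] + 1L):(tl$r0[i] + tile_size)
        cc <- (tl$c0[i] + 1L):(tl$c0[i] + tile_size)
        mcrop <- sc$gauze_mask[rr, cc] > 0
        cov <- mean(mcrop)
        # curated blocks: clearly background or clearly gauze; tiles
        # straddling the gauze boundary are skipped, as in hand-curated
        # tile collections
        if (cov > 0.2 && cov < 0.8) next
        lab <- if (cov <= 0.2) "background" else {
          sf <- sum(sc$stain_alpha[rr, cc] > 0.05 & mcrop) / sum(mcrop)
          if (sf < 0.05) "clean" else if (sf > 0.45) "soaked" else "stained"
        }
        if (got[lab] >= quota[lab]) next
        got[lab] <- got[lab] + 1L
        acc[[length(acc) + 1L]] <- tibble::tibble(
          image = tl$image[i], label = lab,
          gauze_id = paste0("T", chunk, "_", sc$gauze_id))
      }
    }
  }
  if (any(got < quota)) {
    warn(sprintf("tile quota not reached for: %s",
                 paste(names(got)[got < quota], collapse = ", ")))
  }
  dplyr::bind_rows(acc)
}
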