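#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_line
#'   labs theme_minimal geom_raster scale_fill_identity coord_fixed
NULL

#' Plot a Bland--Altman agreement analysis
#'
#' Difference (predicted - true, grams) against the mean of the two, with
#' the bias line (solid) and 1.96-sd limits of agreement (dashed).
#'
#' @param object a [bland_altman()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot(object$data, aes(x = .data$mean_g, y = .data$diff_g)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = object$bias_g) +
    geom_hline(yintercept = c(object$loa_low_g, object$loa_high_g),
               linetype = "dashed") +
    labs(x = "Mean of predicted and true EBL (g)",
         y = "Predicted - true EBL (g)",
         title = sprintf("Bland-Altman: bias %.2f g, LoA [%.2f, %.2f] g",
                         object$bias_g, object$loa_low_g, object$loa_high_g)) +
    theme_minimal()
}

#' Plot the training history of a fitted model
#'
#' @param object a [train_regressor()] or [train_tile_classifier()] fit.
#' @param ... unused.
#' @return a ggplot object with train/validation loss per epoch.
#' @export
autoplot.ebl_regressor <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, cols = c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot(h, aes(x = .data$epoch, y = .data$loss, colour = .data$series)) +
    geom_line() +
    labs(x = "Epoch", y = sprintf("%s loss (g)", toupper(object$config$loss)),
         colour = NULL) +
    theme_minimal()
}

#' @rdname autoplot.ebl_regressor
#' @export
autoplot.gauze_classifier <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, cols = c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot(h, aes(x = .data$epoch, y = .data$loss, colour = .data$series)) +
    geom_line() +
    labs(x = "Epoch", y = "Cross-entropy loss", colour = NULL) +
    theme_minimal()
}

#' Display a synthetic scene frame
#'
#' Renders the RGB frame (optionally with the gauze mask outline) as a
#' raster; mostly a debugging aid.
#'
#' @param scene a `scene_sample`.
#' @param show_mask dim non-gauze pixels to visualise the ground-truth mask.
#' @return a ggplot object.
#' @export
plot_scene <- function(scene, show_mask = FALSE) {
  fr <- scene$frame
  if (show_mask) {
    for (ch in 1:3) fr[, , ch] <- fr[, , ch] * (0.35 + 0.65 * scene$gauze_mask)
  }
  h <- dim(fr)[1]; w <- dim(fr)[2]
  df <- tibble::tibble(
    row = rep(seq_len(h), times = w), col = rep(seq_len(w), each = h),
    fill = grDevices::rgb(as.vector(fr[, , 1]) / 255,
                          as.vector(fr[, , 2]) / 255,
                          as.vector(fr[, , 3]) / 255))
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$fill)) +
    geom_raster() + scale_fill_identity() +
    ggplot2::scale_y_reverse() + coord_fixed() +
    labs(x = NULL, y = NULL,
         title = sprintf("%s: %.2f g", scene$gauze_id, scene$ebl_label_g)) +
    theme_minimal()
}

#' Plot a stratified metrics report
#'
#' @param report tibble from [stratified_report()].
#' @param metric column to plot (default `"mape_pct"`).
#' @return a ggplot object.
#' @export
plot_stratified_report <- function(report, metric = "mape_pct") {
  ggplot(report, aes(x = .data$stratum, y = .data[[metric]])) +
    ggplot2::geom_col() +
    labs(x = "True EBL stratum", y = metric) +
    theme_minimal()
}
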