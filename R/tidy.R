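#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Broom-style accessors for gauzeloss fits
#'
#' `tidy()` returns the per-epoch training history (or the per-point
#' differences for a Bland--Altman analysis); `glance()` a one-row model
#' summary.
#'
#' @param x a `gauze_classifier`, `ebl_regressor` or `bland_altman` object.
#' @param ... unused.
#' @return a tibble.
#' @name gauzeloss-tidiers
NULL

#' @rdname gauzeloss-tidiers
#' @export
tidy.gauze_classifier <- function(x, ...) x$history

#' @rdname gauzeloss-tidiers
#' @export
glance.gauze_classifier <- function(x, ...) {
  tibble::tibble(backbone = x$backbone, n_params = x$n_params,
                 epochs = nrow(x$history),
                 best_val_loss = min(x$history$val_loss),
                 test_accuracy = x$test_accuracy %||% NA_real_,
                 test_sensitivity_pct =
                   if (is.null(x$test_detection)) NA_real_
                   else x$test_detection$sensitivity_pct,
                 test_specificity_pct =
                   if (is.null(x$test_detection)) NA_real_
                   else x$test_detection$specificity_pct)
}

#' @rdname gauzeloss-tidiers
#' @export
tidy.ebl_regressor <- function(x, ...) x$history

#' @rdname gauzeloss-tidiers
#' @export
glance.ebl_regressor <- function(x, ...) {
  tibble::tibble(variant = x$config$variant, backbone = x$config$backbone,
                 loss = x$config$loss, n_params = x$model$n_params,
                 epochs = nrow(x$history),
                 best_val_loss = min(x$history$val_loss))
}

#' @rdname gauzeloss-tidiers
#' @export
tidy.bland_altman <- function(x, ...) x$data

#' @rdname gauzeloss-tidiers
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias_g = x$bias_g, loa_low_g = x$loa_low_g,
                 loa_high_g = x$loa_high_g, n = nrow(x$data))
}
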