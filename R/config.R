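#' Default run configuration
#'
#' The full set of tunables for a pipeline run: paths, scene-generator
#' defaults, tiling, LBP, regression and evaluation settings, plus the
#' single global seed from which every stage derives its own stream.
#'
#' @return nested named list (class `run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    paths = list(data_dir = "data", artifact_dir = "artifacts",
                 output_dir = "out"),
    scene = list(image_height = 256L, image_width = 256L,
                 gauze_area_fraction = 0.35, crumple_intensity = 1,
                 blood_mass_g = 4.17, stain_spread = 12,
                 background_kind = "tissue"),
    tiles = list(tile_size = 64L, stride = 64L, input_resize = 32L),
    lbp = list(r = 3, p = 8L, sampling = "bilinear"),
    regression = list(variant = "pwcs", backbone = "small_cnn",
                      head_activation = "linear", loss = "mae",
                      mlp_hidden = c(32L, 16L), input_side = 64L,
                      n_vector = 16L, batch_size = 32L,
                      learning_rate = 5e-3, epochs = 25L),
    evaluation = list(strata = c(3, 5)),
    seed = 1L, verbosity = 1L), class = "run_config")
}

merge_config <- function(defaults, user, path = character()) {
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(defaults)) {
      abort(sprintf("unknown configuration key '%s'", here))
    }
    if (is.list(defaults[[nm]]) && !is.null(user[[nm]])) {
      if (!is.list(user[[nm]])) {
        abort(sprintf("configuration key '%s' must be a mapping", here))
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    } else if (!is.null(user[[nm]])) {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Omitted keys are filled with [default_run_config()] values; unknown keys
#' are rejected with the offending (dotted) key path named, so typos never
#' silently fall back to defaults.
#'
#' @param path YAML file; an empty file yields all defaults.
#' @return a `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  structure(merge_config(unclass(default_run_config()), user),
            class = "run_config")
}

#' Save a run configuration as YAML
#'
#' @param config a `run_config` list.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
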