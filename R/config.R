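#' Pipeline configuration
#'
#' A single YAML key-value file carries every tunable of the pipeline.
#' `default_config()` documents the defaults; `load_config()` reads a YAML
#' file and merges it over them (missing keys keep their defaults).
#' The declared left-right axis (`axes.left_right = 1`, the first voxel
#' axis) is what the flip augmentation mirrors and what laterality
#' reporting uses.
#'
#' @return A nested named list of settings.
#' @export
default_config <- function() {
  list(
    axes = list(left_right = 1L),
    phantom = list(grid = c(32L, 32L, 32L), effect = 0.7, noise_sd = 5,
                   global_scale_range = c(0.8, 1.2)),
    preprocess = list(threshold_frac = 0.30, center_scale = "log"),
    augment = list(apply_prob = 0.10, max_rotation_deg = 10),
    nets = list(grid = c(96L, 112L, 96L), strides = c(2L, 2L, 2L, 2L, 1L),
                dropout = 0.5, context = list(dilations = c(1L, 2L, 4L))),
    train = list(epochs = 30L, batch_size = 8L, lr = 1e-3, patience = 8L,
                 freeze_extractors = TRUE, seed = 1L),
    saliency = list(threshold = 0.7)
  )
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_lists(default_config(), user)
}

#' @rdname default_config
#' @param config configuration list to write.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
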