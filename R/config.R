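## Layered run configuration: package defaults <- YAML file <- explicit
## overrides, with unknown keys rejected by their full dotted path. The
## resolved tree is plain lists/vectors so it serialises losslessly to YAML.

#' Package default configuration tree
#'
#' @return nested named list covering data generation, attention, neck,
#'   detector and evaluation settings.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    log_level = "info",
    data = list(image_size = 416L, n_polyps = 3L, size_range = c(6, 64),
                contrast_delta = 0.10, n_folds = 6L, n_speculars = 8L,
                density_mode = FALSE),
    attention = list(reduction_ratio = 16L, order = "pos_then_chan",
                     position_gate = "hard_swish", shared_mlp = TRUE),
    neck = list(channels = 128L, conv_block_depth = 5L, downsample = "conv_s2"),
    detector = list(image_size = 416L,
                    backbone_widths = c(16L, 32L, 64L, 128L, 256L),
                    lr0 = 0.001, freeze_epochs = 10L, thaw_epochs = 20L,
                    mosaic = FALSE, optimizer = "adam",
                    lambda_box = 5, lambda_obj = 1, lambda_noobj = 0.5,
                    score_thr = 0.25, nms_iou = 0.5),
    eval = list(iou_thr = 0.5, score_thr = 0.5, interpolation = "all_point")
  )
}

merge_config <- function(base, upd, path = character(0)) {
  for (nm in names(upd)) {
    p <- c(path, nm)
    if (!nm %in% names(base))
      stop("unknown configuration key: ", paste(p, collapse = "."))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(upd[[nm]]))
        stop("configuration key ", paste(p, collapse = "."),
             " expects a nested section")
      base[[nm]] <- merge_config(base[[nm]], upd[[nm]], p)
    } else {
      v <- upd[[nm]]
      if (is.list(v)) v <- unlist(v)
      base[[nm]] <- v
    }
  }
  base
}

#' Resolve a layered configuration
#'
#' Merges package defaults, an optional YAML file and explicit overrides (in
#' that order of precedence). Unknown keys abort with the offending dotted
#' path.
#'
#' @param file optional YAML configuration file.
#' @param overrides optional nested list of overrides.
#' @return fully resolved configuration tree.
#' @export
resolve_config <- function(file = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    cfg <- merge_config(cfg, yaml::read_yaml(file))
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

## detector_config / neck_config views over a resolved tree
cfg_neck <- function(cfg) {
  neck_config(channels = cfg$neck$channels,
              conv_block_depth = cfg$neck$conv_block_depth,
              reduction_ratio = cfg$attention$reduction_ratio,
              order = cfg$attention$order,
              position_gate = cfg$attention$position_gate,
              shared_mlp = cfg$attention$shared_mlp)
}

cfg_detector <- function(cfg) {
  d <- cfg$detector
  detector_config(image_size = d$image_size, backbone_widths = d$backbone_widths,
                  neck = cfg_neck(cfg), lr0 = d$lr0,
                  freeze_epochs = d$freeze_epochs, thaw_epochs = d$thaw_epochs,
                  mosaic = d$mosaic, optimizer = d$optimizer,
                  lambda_box = d$lambda_box, lambda_obj = d$lambda_obj,
                  lambda_noobj = d$lambda_noobj, score_thr = d$score_thr,
                  nms_iou = d$nms_iou, seed = cfg$seed)
}

cfg_scene <- function(cfg, seed = NULL) {
  d <- cfg$data
  scene_spec(image_size = d$image_size, n_polyps = d$n_polyps,
             size_range = d$size_range, contrast_delta = d$contrast_delta,
             n_folds = d$n_folds, n_speculars = d$n_speculars,
             density_mode = d$density_mode, seed = seed %||% cfg$seed)
}
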