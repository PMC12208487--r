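#' Default run configuration
#'
#' Nested list of every tunable the toolkit exposes, grouped by stage.
#' The `trainer` block records, verbatim, the external detector's
#' training settings (80 epochs, 800-px input, batch 40, SGD momentum
#' 0.937, weight decay 5e-4, 3 warm-up epochs at momentum 0.8, initial
#' and final learning-rate factors 0.01, warm-up bias learning rate 0.1)
#' and prediction settings (confidence 0.1, NMS IoU 0.7, class-agnostic
#' NMS). The trainer is never invoked here; the block exists so a run's
#' full provenance can be exported alongside the prepared dataset.
#'
#' @return named nested list.
#' @export
default_config <- function() {
  list(
    seed = NULL,                      # sampling commands demand one
    ops = default_op_ranges(),
    catalog = aug_op_names(),
    min_box_frac = 0.25,
    balance = list(target_ratio = 3, max_copies = 10),
    split = list(portions = 25L, batches = 5L),
    eval = list(match_iou = 0.5, conf = 0.1, nms_iou = 0.7),
    trainer = list(epochs = 80L, imgsz = 800L, batch = 40L,
                   momentum = 0.937, weight_decay = 0.0005,
                   warmup_epochs = 3L, warmup_momentum = 0.8,
                   lr0 = 0.01, lrf = 0.01, warmup_bias_lr = 0.1,
                   conf = 0.1, iou = 0.7, agnostic_nms = TRUE)
  )
}

merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    here <- c(path, key)
    if (!key %in% names(base))
      stop("unknown configuration key: ", paste(here, collapse = "."),
           call. = FALSE)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stop("configuration key ", paste(here, collapse = "."),
             " must be a mapping", call. = FALSE)
      base[[key]] <- merge_config(base[[key]], override[[key]], here)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML file and merges it over [default_config()]. Unknown keys
#' are rejected with their full dotted path, so typos fail loudly instead
#' of silently running on defaults.
#'
#' @param path YAML file; an empty file yields all defaults.
#' @return the resolved configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  cfg <- merge_config(default_config(), y)
  basic <- c("match_iou", "conf", "nms_iou")
  ev <- cfg$eval[basic]
  if (any(unlist(ev) < 0) || any(unlist(ev) > 1))
    stop("eval thresholds must lie in [0, 1]", call. = FALSE)
  if (cfg$balance$target_ratio < 1)
    stop("balance.target_ratio must be >= 1", call. = FALSE)
  cfg
}

#' Export the external-trainer configuration template
#'
#' Writes the recorded detector training/prediction settings as a YAML
#' consumable by an external trainer. `load_config()`-style round-trips
#' reproduce the values exactly.
#'
#' @param config a configuration list (see [default_config()]).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
export_trainer_template <- function(config = default_config(), path) {
  yaml::write_yaml(config$trainer, path)
  invisible(path)
}
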