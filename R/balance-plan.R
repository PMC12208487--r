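#' Default augmentation parameter ranges
#'
#' The source protocol never quantifies its sampling ranges; these defaults
#' are chosen so every artifact is visible but structure-preserving, and
#' all of them are overridable through the run configuration.
#'
#' @return named list of per-op ranges: `defocus_sigma` (blur sd, pixels),
#'   `shadow_alpha` and `shadow_size` (opacity; box side as a fraction of
#'   the frame), `sidelobe_angle` and `sidelobe_alpha` (ghost rotation,
#'   degrees; ghost opacity), `brightness_bias` (intensity offset),
#'   `contrast_gain` (slope around mid-gray), `rotation_angle` (degrees).
#' @export
default_op_ranges <- function() {
  list(defocus_sigma = c(0.5, 2.5),
       shadow_alpha = c(0.4, 1.0),
       shadow_size = c(0.05, 0.30),
       sidelobe_angle = c(-10, 10),
       sidelobe_alpha = c(0.10, 0.35),
       brightness_bias = c(-40, 40),
       contrast_gain = c(0.7, 1.3),
       rotation_angle = c(-10, 10))
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# Sample the parameters of one op from its configured ranges. Consumes the
# global RNG stream; callers seed it.
sample_op_params <- function(op, ranges) {
  switch(op,
    defocus = list(sigma = runif1(ranges$defocus_sigma)),
    shadow_box = {
      w <- runif1(ranges$shadow_size); h <- runif1(ranges$shadow_size)
      list(x = stats::runif(1, 0.1, 0.9), y = stats::runif(1, 0.1, 0.9),
           w = w, h = h, alpha = runif1(ranges$shadow_alpha))
    },
    sidelobe = list(angle = runif1(ranges$sidelobe_angle),
                    alpha = runif1(ranges$sidelobe_alpha)),
    brightness = list(bias = runif1(ranges$brightness_bias)),
    contrast = list(gain = runif1(ranges$contrast_gain)),
    rotation = list(angle = runif1(ranges$rotation_angle)),
    stop("unknown op: ", op, call. = FALSE))
}

#' Sample one augmentation-op pair
#'
#' Each selected image receives exactly two augmentation methods (using
#' more per image has been reported not to help training): two *distinct*
#' ops drawn uniformly without replacement from the enabled catalog, each
#' with parameters sampled from the configured ranges. Fully determined by
#' the R RNG state — seed before calling for reproducibility.
#'
#' @param catalog character vector of enabled op names (>= 2).
#' @param ranges parameter ranges, see [default_op_ranges()].
#' @return list of two [aug_spec]s with distinct ops.
#' @export
sample_op_pair <- function(catalog = aug_op_names(),
                           ranges = default_op_ranges()) {
  catalog <- match.arg(catalog, aug_op_names(), several.ok = TRUE)
  if (length(catalog) < 2L)
    stop("op catalog must contain at least 2 ops", call. = FALSE)
  ops <- sample(catalog, 2L)
  lapply(ops, function(op) aug_spec(op, sample_op_params(op, ranges)))
}

# Classes contributed by applying a spec pair to an image's boxes: only
# rotation can drop boxes, so project the boxes through any rotation in
# the pair using the real box transform. Gives plan/execution consistency
# without touching pixels.
project_pair_classes <- function(boxes, specs, width, height,
                                 min_box_frac = 0.25) {
  for (s in specs)
    if (s$op == "rotation")
      boxes <- rotate_boxes(boxes, s$params$angle, width, height,
                            min_box_frac)
  boxes$class_id
}

#' Plan class-imbalance-driven augmentation
#'
#' Counts nodules per class, sets each class's target to
#' `max-class count / target_ratio` (so `target_ratio` bounds the final
#' max/min imbalance), and repeatedly selects — with replacement, a fresh
#' op pair each time — images containing an under-target class until every
#' class's projected count meets its target or the per-image copy cap is
#' exhausted. Because an image carries all its nodules, co-occurring
#' common-class nodules are counted into the projection too (so common
#' classes also grow somewhat, as observed in practice).
#'
#' @param dataset a [dataset_manifest].
#' @param target_ratio maximum tolerated max/min class-count ratio,
#'   `>= 1` (default 3).
#' @param catalog enabled op names.
#' @param seed integer seed; the plan is a pure function of
#'   (dataset, parameters, seed).
#' @param ranges parameter ranges, see [default_op_ranges()].
#' @param max_copies per-original augmented-copy cap (default 10), bounding
#'   dataset growth.
#' @param min_box_frac rotation box-survival fraction, must match what
#'   `execute_plan()` will use.
#' @return a `balance_plan`: `targets`, `before` (counts), `projected`
#'   (counts after execution), `selections` (each: `image_id`, `index`
#'   into the manifest, `specs` — two [aug_spec]s), `seed`. Classes that
#'   are deficient but appear in no image are reported by warning and
#'   listed in `$unfillable`.
#' @export
plan_balancing <- function(dataset, target_ratio = 3, catalog = aug_op_names(),
                           seed, ranges = default_op_ranges(),
                           max_copies = 10L, min_box_frac = 0.25) {
  stopifnot(inherits(dataset, "dataset_manifest"))
  if (target_ratio < 1) stop("target_ratio must be >= 1", call. = FALSE)
  stopifnot(is.numeric(seed))
  k <- length(dataset$class_names)
  n_img <- length(dataset$image_paths)
  if (n_img == 0L) stop("dataset is empty", call. = FALSE)

  boxes_by_img <- lapply(dataset$label_paths, read_labels, class_count = k)
  counts <- Reduce(`+`, lapply(boxes_by_img, function(b)
    tabulate(b$class_id + 1L, nbins = k)), integer(k))
  names(counts) <- dataset$class_names
  targets <- rep(min(ceiling(max(counts) / target_ratio), max(counts)), k)
  names(targets) <- dataset$class_names

  has_class <- lapply(seq_len(k) - 1L, function(cl)
    which(vapply(boxes_by_img, function(b) any(b$class_id == cl), logical(1))))

  unfillable <- dataset$class_names[counts < targets &
                                    lengths(has_class) == 0L]
  if (length(unfillable))
    warning("no image contains deficient class(es): ",
            paste(unfillable, collapse = ", "), call. = FALSE)

  set.seed(as.integer(seed))
  projected <- counts
  copies <- integer(n_img)
  selections <- list()
  dims_cache <- list()
  img_dims <- function(i) {
    key <- as.character(i)
    if (is.null(dims_cache[[key]])) {
      img <- read_image(dataset$image_paths[i])
      dims_cache[[key]] <<- c(ncol(img), nrow(img))
    }
    dims_cache[[key]]
  }

  repeat {
    deficient <- which(projected < targets)
    deficient <- deficient[lengths(has_class[deficient]) > 0L]
    if (!length(deficient)) break
    pool <- unique(unlist(has_class[deficient]))
    pool <- pool[copies[pool] < max_copies]
    if (!length(pool)) break
    i <- if (length(pool) == 1L) pool else sample(pool, 1L)
    specs <- sample_op_pair(catalog, ranges)
    wh <- if (any(vapply(specs, function(s) s$op == "rotation", logical(1))))
      img_dims(i) else c(1, 1)  # dims only matter to rotation
    cls <- project_pair_classes(boxes_by_img[[i]], specs, wh[1], wh[2],
                                min_box_frac)
    projected <- projected + tabulate(cls + 1L, nbins = k)
    copies[i] <- copies[i] + 1L
    selections[[length(selections) + 1L]] <-
      list(image_id = manifest_ids(dataset)[i], index = i, specs = specs)
  }

  structure(list(targets = targets, before = counts, projected = projected,
                 selections = selections, seed = as.integer(seed),
                 unfillable = unfillable, min_box_frac = min_box_frac),
            class = "balance_plan")
}

#' @export
print.balance_plan <- function(x, ...) {
  cat(sprintf("<balance_plan: %d selection(s), seed %d>\n",
              length(x$selections), x$seed))
  print(rbind(before = x$before, target = x$targets,
              projected = x$projected))
  invisible(x)
}

#' Execute a balancing plan
#'
#' Applies each selection's op pair (second op composed after the first),
#' writes the augmented images, label files and a JSON sidecar of the
#' applied specs under `out_dir`, and returns the merged manifest
#' (originals plus augmented copies). Deterministic: re-executing the same
#' plan yields byte-identical outputs.
#'
#' @param plan a `balance_plan`.
#' @param dataset the [dataset_manifest] the plan was built from.
#' @param out_dir output directory.
#' @return the merged [dataset_manifest] (also written as
#'   `manifest.yaml` in `out_dir`).
#' @export
execute_plan <- function(plan, dataset, out_dir) {
  stopifnot(inherits(plan, "balance_plan"),
            inherits(dataset, "dataset_manifest"))
  img_dir <- file.path(out_dir, "images")
  lab_dir <- file.path(out_dir, "labels")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  cache <- list()
  sidecar <- list()
  new_imgs <- new_labs <- character(length(plan$selections))
  seen_ids <- character()
  for (si in seq_along(plan$selections)) {
    sel <- plan$selections[[si]]
    key <- as.character(sel$index)
    if (is.null(cache[[key]])) cache[[key]] <- load_record(dataset, sel$index)
    rec <- cache[[key]]
    for (s in sel$specs) rec <- apply_spec(rec, s, plan$min_box_frac)
    id <- rec$image_id
    # continuous parameters make collisions vanishingly rare, but stay safe
    n_prev <- sum(seen_ids == id)
    if (n_prev > 0) id <- sprintf("%s_%d", id, n_prev + 1L)
    seen_ids <- c(seen_ids, rec$image_id)
    new_imgs[si] <- file.path(img_dir, paste0(id, ".png"))
    new_labs[si] <- file.path(lab_dir, paste0(id, ".txt"))
    write_image(rec$image, new_imgs[si])
    write_labels(rec$boxes, new_labs[si])
    sidecar[[id]] <- list(source = sel$image_id,
                          specs = lapply(sel$specs, spec_to_list))
  }
  jsonlite::write_json(sidecar, file.path(out_dir, "augspecs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  merged <- dataset_manifest(dataset$class_names,
                             c(dataset$image_paths, new_imgs),
                             c(dataset$label_paths, new_labs))
  write_manifest(merged, file.path(out_dir, "manifest.yaml"))
  merged
}
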