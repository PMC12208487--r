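#' Phantom generator configuration
#'
#' The generator emulates, at fixture scale, the statistical shape of a
#' thyroid-nodule ultrasound dataset: speckle-textured fan-sector frames,
#' each containing at least one elliptical "nodule" with an exact
#' ground-truth bounding box, class frequencies following a configurable
#' imbalance profile. The default class probabilities make the three
#' common categories (2, 3, 4A) carry 95.7% of nodules and the three rare
#' ones (4B, 4C, 5) 4.3%, mirroring the imbalance the balancing planner
#' exists to correct. No clinical realism is claimed: class "echo
#' profiles" are stylized intensity offsets so classes are merely
#' distinguishable in tests.
#'
#' @param image_size side of the square frame, pixels (default 96).
#' @param n_images number of frames.
#' @param class_probs per-class sampling probabilities (sum 1); default
#'   `c(0.25, 0.45, 0.257, 0.02, 0.015, 0.008)`.
#' @param nodules_per_image integer range `c(min, max)`, `min >= 1` (every
#'   frame contains at least one nodule).
#' @param nodule_echo_offsets per-class mean-intensity offset of the
#'   nodule interior relative to background.
#' @param nodule_edge_softness per-class border softness (pixels of
#'   smoothing; larger = more ill-defined margin).
#' @param speckle_scale multiplicative speckle noise standard deviation
#'   (unit-mean gamma); 0 disables noise.
#' @param background_level mean background intensity inside the sector.
#' @param seed integer seed.
#' @return a `phantom_config`.
#' @export
phantom_config <- function(image_size = 96L, n_images = 20L,
                           class_probs = c(0.25, 0.45, 0.257,
                                           0.02, 0.015, 0.008),
                           nodules_per_image = c(1L, 3L),
                           nodule_echo_offsets = c(45, 25, -15, -35, -55, -75),
                           nodule_edge_softness = c(0.5, 0.8, 1.2, 1.6,
                                                    2.0, 2.4),
                           speckle_scale = 0.25,
                           background_level = 110,
                           seed = 1L) {
  stopifnot(abs(sum(class_probs) - 1) < 1e-8,
            length(nodule_echo_offsets) == length(class_probs),
            length(nodule_edge_softness) == length(class_probs),
            nodules_per_image[1] >= 1L,
            nodules_per_image[2] >= nodules_per_image[1],
            speckle_scale >= 0, image_size >= 32L)
  structure(list(image_size = as.integer(image_size),
                 n_images = as.integer(n_images),
                 class_probs = class_probs,
                 nodules_per_image = as.integer(nodules_per_image),
                 nodule_echo_offsets = nodule_echo_offsets,
                 nodule_edge_softness = nodule_edge_softness,
                 speckle_scale = speckle_scale,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Fan-sector support mask: apex at the top-center, as on a convex-probe
# B-mode display. Cached per size within a generate_phantom() call.
sector_mask <- function(size) {
  cx <- (size + 1) / 2
  apex_r <- -0.15 * size
  gx <- matrix(rep(seq_len(size), each = size), size, size) - cx
  gy <- matrix(rep(seq_len(size), times = size), size, size) - apex_r
  rad <- sqrt(gx^2 + gy^2)
  ang <- atan2(gx, gy)                     # 0 = straight down
  rad > 0.25 * size & rad < 1.1 * size & abs(ang) < pi / 4.2
}

# Unit-mean multiplicative speckle; gamma with sd = scale.
speckle_noise <- function(n, scale) {
  if (scale <= 0) return(rep(1, n))
  shape <- 1 / scale^2
  stats::rgamma(n, shape = shape, rate = shape)
}

#' Generate a synthetic phantom dataset
#'
#' Each frame is `sector mask x (background level x speckle)` with
#' `nodules_per_image` elliptical nodules rendered inside the sector;
#' a nodule's class sets its interior intensity offset and border
#' softness, and its label is the exact bounding box of the ellipse.
#' Fully seeded and reproducible.
#'
#' @param config a [phantom_config].
#' @return list of [image_record]s (source `"synthetic"`, boxes carry no
#'   confidence).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  size <- config$image_size
  mask <- sector_mask(size)
  k <- length(config$class_probs)
  gx <- matrix(rep(seq_len(size), each = size), size, size)
  gy <- matrix(rep(seq_len(size), times = size), size, size)
  # nodule radii range, pixels: visible but comfortably inside the sector
  r_range <- c(0.04, 0.11) * size
  if (2 * r_range[1] > size * 0.5)
    stop("nodule larger than the sector; increase image_size", call. = FALSE)
  inside <- which(mask, arr.ind = TRUE)

  records <- vector("list", config$n_images)
  for (ii in seq_len(config$n_images)) {
    m <- matrix(0, size, size)
    m[mask] <- config$background_level *
      speckle_noise(sum(mask), config$speckle_scale)
    rng <- config$nodules_per_image
    n_nod <- if (rng[1] == rng[2]) rng[1] else
      sample(seq(rng[1], rng[2]), 1L)
    boxes <- NULL
    for (nn in seq_len(n_nod)) {
      cls <- sample.int(k, 1L, prob = config$class_probs) - 1L
      # center: a sector pixel far enough from the border for the ellipse
      for (try in 1:50) {
        ctr <- inside[sample.int(nrow(inside), 1L), ]
        a <- stats::runif(1, r_range[1], r_range[2])  # semi-axis, cols
        b <- stats::runif(1, r_range[1], r_range[2])  # semi-axis, rows
        r1 <- ctr[1] - b; r2 <- ctr[1] + b
        c1 <- ctr[2] - a; c2 <- ctr[2] + a
        if (r1 >= 1 && r2 <= size && c1 >= 1 && c2 <= size) break
      }
      soft <- config$nodule_edge_softness[cls + 1L]
      d <- sqrt(((gx - ctr[2]) / a)^2 + ((gy - ctr[1]) / b)^2)
      # soft-edged ellipse membership in [0,1]
      memb <- stats::plogis((1 - d) * max(a, b) / max(soft, 1e-6))
      memb[d > 1] <- 0                     # box tightly bounds the nodule
      m <- m + config$nodule_echo_offsets[cls + 1L] * memb *
        speckle_noise(length(m), config$speckle_scale / 2)
      boxes <- rbind(boxes, data.frame(
        class_id = cls,
        cx = ctr[2] / size, cy = ctr[1] / size,
        w = 2 * a / size, h = 2 * b / size,
        confidence = NA_real_))
    }
    m[!mask] <- 0
    records[[ii]] <- image_record(
      sprintf("phantom%05d", ii),
      clamp_image(m),
      as_labeled_boxes(boxes),
      source = "synthetic")
  }
  records
}

#' Corrupt gold labels to emulate an imperfect annotator
#'
#' Simulates first-pass (junior-physician-style) annotation errors on
#' synthetic gold labels so the evaluation module can be tested
#' end-to-end with a known ground truth: each label's class is resampled
#' from its row of `error_matrix`; each box is dropped (missed nodule)
#' with probability `fn_rate`; spurious boxes (vessels read as nodules)
#' are added per image at Poisson rate `fp_rate`. Box geometry is left
#' exact so class confusion is isolated from localization error.
#'
#' @param records list of [image_record]s with gold boxes.
#' @param error_matrix `C x C` row-stochastic table:
#'   `error_matrix[t, o]` is the probability a true class `t` nodule is
#'   annotated as class `o`. Identity = perfect annotator.
#' @param fp_rate expected spurious boxes per image.
#' @param fn_rate per-box miss probability.
#' @param seed integer seed.
#' @return `list(corrupted =, gold =)` — corrupted records (source
#'   `"junior"`) alongside the untouched originals.
#' @export
corrupt_labels <- function(records, error_matrix, fp_rate = 0,
                           fn_rate = 0, seed = 1L) {
  k <- nrow(error_matrix)
  stopifnot(ncol(error_matrix) == k,
            all(abs(rowSums(error_matrix) - 1) < 1e-8),
            all(error_matrix >= 0),
            fp_rate >= 0, fn_rate >= 0, fn_rate <= 1)
  set.seed(as.integer(seed))
  corrupted <- lapply(records, function(r) {
    b <- r$boxes
    if (nrow(b)) {
      keep <- stats::runif(nrow(b)) >= fn_rate
      b <- b[keep, , drop = FALSE]
      if (nrow(b))
        b$class_id <- vapply(b$class_id, function(t)
          sample.int(k, 1L, prob = error_matrix[t + 1L, ]) - 1L, integer(1))
    }
    n_fp <- stats::rpois(1, fp_rate)
    if (n_fp > 0) {
      fp <- data.frame(class_id = sample.int(k, n_fp, replace = TRUE) - 1L,
                       cx = stats::runif(n_fp, 0.2, 0.8),
                       cy = stats::runif(n_fp, 0.2, 0.8),
                       w = stats::runif(n_fp, 0.05, 0.15),
                       h = stats::runif(n_fp, 0.05, 0.15),
                       confidence = NA_real_)
      b <- rbind(b, fp)
    }
    rownames(b) <- NULL
    image_record(r$image_id, r$image, as_labeled_boxes(b), source = "junior")
  })
  list(corrupted = corrupted, gold = records)
}
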