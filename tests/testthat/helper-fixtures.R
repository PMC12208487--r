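# Shared fixtures and independent oracles. Oracles are deliberately naive
# (per-pixel loops, exhaustive search) and never call the code paths they
# check.

random_boxes <- function(n, class_count = 6L, with_conf = FALSE) {
  w <- runif(n, 0.05, 0.4)
  h <- runif(n, 0.05, 0.4)
  labeled_boxes(
    class_id = sample.int(class_count, n, replace = TRUE) - 1L,
    cx = runif(n, w / 2, 1 - w / 2),
    cy = runif(n, h / 2, 1 - h / 2),
    w = w, h = h,
    confidence = if (with_conf) runif(n) else NA_real_)
}

random_image <- function(size = 16L) {
  gray_image(matrix(sample(0:255, size * size, replace = TRUE), size, size))
}

# Per-pixel reference for the affine blends (shadow box, brightness).
oracle_affine <- function(m, gain, bias) {
  out <- m
  for (r in seq_len(nrow(m)))
    for (c in seq_len(ncol(m)))
      out[r, c] <- as.integer(min(max(round(gain * m[r, c] + bias), 0), 255))
  out
}

# Exhaustive check that an NMS result is exactly the greedy solution:
# recompute greedy with scalar loops and plain box arithmetic.
oracle_nms <- function(boxes, thr) {
  n <- nrow(boxes)
  ord <- order(-boxes$confidence)
  alive <- rep(TRUE, n)
  keep <- integer()
  iou1 <- function(i, j) {
    a <- boxes[i, ]; b <- boxes[j, ]
    x1 <- max(a$cx - a$w / 2, b$cx - b$w / 2)
    x2 <- min(a$cx + a$w / 2, b$cx + b$w / 2)
    y1 <- max(a$cy - a$h / 2, b$cy - b$h / 2)
    y2 <- min(a$cy + a$h / 2, b$cy + b$h / 2)
    if (x2 <= x1 || y2 <= y1) return(0)
    inter <- (x2 - x1) * (y2 - y1)
    inter / (a$w * a$h + b$w * b$h - inter)
  }
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    for (j in ord) if (alive[j] && iou1(i, j) > thr) alive[j] <- FALSE
    alive[i] <- FALSE
  }
  boxes[keep, , drop = FALSE]
}

# Greedy IoU matching recomputed with scalar loops.
oracle_match <- function(cand, gold, thr) {
  nc <- nrow(cand); ng <- nrow(gold)
  pairs <- NULL
  cfree <- rep(TRUE, nc); gfree <- rep(TRUE, ng)
  repeat {
    best <- c(NA, NA); best_iou <- -1
    for (i in seq_len(nc)) for (j in seq_len(ng)) {
      if (!cfree[i] || !gfree[j]) next
      v <- box_iou(cand[i, ], gold[j, ])
      if (v > best_iou + 1e-12) { best <- c(i, j); best_iou <- v }
    }
    if (is.na(best[1]) || best_iou < thr) break
    cfree[best[1]] <- gfree[best[2]] <- FALSE
    pairs <- rbind(pairs, c(best, best_iou))
  }
  pairs
}

count_record_classes <- function(recs, k) {
  counts <- integer(k)
  for (r in recs)
    counts <- counts + tabulate(r$boxes$class_id + 1L, nbins = k)
  counts
}

tiny_phantom <- function(n_images = 4L, seed = 7L, size = 64L,
                         nodules = c(1L, 2L)) {
  generate_phantom(phantom_config(image_size = size, n_images = n_images,
                                  nodules_per_image = nodules, seed = seed))
}

# Phantom dataset written to disk as a manifest, with a forced class mix:
# class_ids overridden cyclically from `classes` per image.
write_phantom_dataset <- function(dir, n_images, classes_per_image,
                                  seed = 11L, size = 64L) {
  recs <- generate_phantom(phantom_config(
    image_size = size, n_images = n_images,
    nodules_per_image = c(length(classes_per_image[[1]]),
                          length(classes_per_image[[1]])),
    seed = seed))
  for (i in seq_along(recs)) {
    cls <- classes_per_image[[(i - 1L) %% length(classes_per_image) + 1L]]
    recs[[i]]$boxes$class_id <- cls[seq_len(nrow(recs[[i]]$boxes))]
  }
  write_dataset(recs, dir)
}
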