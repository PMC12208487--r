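#' Intersection over union of two boxes
#'
#' Boxes in YOLO normalized center format; overlap computed in normalized
#' coordinates. Disjoint boxes score 0.
#'
#' @param a,b single rows of a [labeled_boxes] frame (or any list with
#'   `cx`, `cy`, `w`, `h`).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- min(a$cx + a$w / 2, b$cx + b$w / 2) -
        max(a$cx - a$w / 2, b$cx - b$w / 2)
  iy <- min(a$cy + a$h / 2, b$cy + b$h / 2) -
        max(a$cy - a$h / 2, b$cy - b$h / 2)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

# All-pairs IoU matrix between two box frames (rows: a, cols: b).
iou_matrix <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(0, nrow(a), nrow(b)))
  ax1 <- a$cx - a$w / 2; ax2 <- a$cx + a$w / 2
  ay1 <- a$cy - a$h / 2; ay2 <- a$cy + a$h / 2
  bx1 <- b$cx - b$w / 2; bx2 <- b$cx + b$w / 2
  by1 <- b$cy - b$h / 2; by2 <- b$cy + b$h / 2
  ix <- pmax(outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax), 0)
  iy <- pmax(outer(ay2, by2, pmin) - outer(ay1, by1, pmax), 0)
  inter <- ix * iy
  union <- outer(a$w * a$h, b$w * b$h, `+`) - inter
  inter / union
}

#' Class-agnostic non-maximum suppression
#'
#' Greedy NMS across *all* classes (the prediction setting used for
#' pre-annotation: one anatomical structure should yield one box even if
#' the detector hedges between categories): repeatedly keep the
#' highest-confidence box and discard every remaining box, of any class,
#' whose IoU with it exceeds `iou_threshold`.
#'
#' @param boxes a [labeled_boxes] frame; every box must carry a
#'   confidence.
#' @param iou_threshold suppression threshold (default 0.7, the
#'   prediction-time setting).
#' @return kept boxes, sorted by confidence descending (ties keep input
#'   order).
#' @export
class_agnostic_nms <- function(boxes, iou_threshold = 0.7) {
  validate_boxes(boxes)
  if (nrow(boxes) == 0L) return(boxes)
  if (anyNA(boxes$confidence))
    stop("all boxes must carry a confidence for NMS", call. = FALSE)
  ord <- order(-boxes$confidence)
  boxes <- boxes[ord, , drop = FALSE]
  iou <- iou_matrix(boxes, boxes)
  n <- nrow(boxes)
  alive <- rep(TRUE, n)
  keep <- integer()
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive <- alive & iou[i, ] <= iou_threshold
  }
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confidence filtering
#'
#' Keeps boxes with `confidence >= conf_threshold` (boundary inclusive),
#' preserving input order. The pre-annotation workflow runs the detector
#' at a deliberately low threshold (0.1) to maximize nodule sensitivity.
#'
#' @param boxes a [labeled_boxes] frame with confidences.
#' @param conf_threshold minimum confidence (default 0.1).
#' @return filtered frame.
#' @export
filter_confidence <- function(boxes, conf_threshold = 0.1) {
  validate_boxes(boxes)
  if (nrow(boxes) == 0L) return(boxes)
  if (anyNA(boxes$confidence))
    stop("all boxes must carry a confidence", call. = FALSE)
  out <- boxes[boxes$confidence >= conf_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match candidate annotations to a gold standard
#'
#' Pairs one image's candidate boxes (junior-physician or model
#' annotations) with its gold boxes (senior-reviewed) greedily by
#' descending IoU, class-blind — class disagreements are exactly what the
#' confusion matrix is meant to expose, so they must not prevent a spatial
#' match. Each box is used at most once; pairs require
#' `IoU >= match_iou`. Ties are broken by candidate row order, then gold
#' row order (deterministic).
#'
#' @param candidates,gold [labeled_boxes] frames for one image.
#' @param match_iou minimum pairing IoU (default 0.5).
#' @return a `match_result`: `pairs` (data frame with `cand`, `gold` row
#'   indices, classes and `iou`), `unmatched_candidates` (indices — false
#'   detections), `unmatched_gold` (indices — missed nodules).
#' @export
match_to_gold <- function(candidates, gold, match_iou = 0.5) {
  validate_boxes(candidates)
  validate_boxes(gold)
  iou <- iou_matrix(candidates, gold)
  nc <- nrow(candidates); ng <- nrow(gold)
  pairs <- data.frame(cand = integer(), gold = integer(),
                      cand_class = integer(), gold_class = integer(),
                      iou = numeric())
  if (nc > 0L && ng > 0L) {
    cand_free <- rep(TRUE, nc); gold_free <- rep(TRUE, ng)
    ord <- order(-iou, slice.index(iou, 1), slice.index(iou, 2))
    for (k in ord) {
      if (iou[k] < match_iou) break
      i <- (k - 1L) %% nc + 1L
      j <- (k - 1L) %/% nc + 1L
      if (!cand_free[i] || !gold_free[j]) next
      cand_free[i] <- gold_free[j] <- FALSE
      pairs <- rbind(pairs, data.frame(
        cand = i, gold = j,
        cand_class = candidates$class_id[i], gold_class = gold$class_id[j],
        iou = iou[k]))
    }
  }
  structure(list(pairs = pairs,
                 unmatched_candidates = setdiff(seq_len(nc), pairs$cand),
                 unmatched_gold = setdiff(seq_len(ng), pairs$gold),
                 match_iou = match_iou),
            class = "match_result")
}

#' Confusion matrix of an annotation set against the gold standard
#'
#' Builds the `(C+1) x (C+1)` table with rows = candidate (annotator)
#' class, columns = gold class, plus a background row/column: a matched
#' pair increments `(candidate class, gold class)`; a missed gold nodule
#' increments `(background, gold class)`; an unmatched candidate (a
#' vessel, lymph node or other structure wrongly annotated as a nodule)
#' increments `(candidate class, background)`. Proportions are
#' column-normalized — each gold class's column shows where its nodules
#' went.
#'
#' @param matches list of `match_result`s (one per image) together with
#'   the box frames they came from: supply via `candidates` and `gold`
#'   lists parallel to `matches`.
#' @param candidates,gold lists of [labeled_boxes] frames, parallel to
#'   `matches`.
#' @param class_count number of real classes `C`.
#' @param class_names optional class labels for dimnames.
#' @return a `confusion_matrix`: `counts`, `proportions`, `class_names`.
#' @export
confusion <- function(matches, candidates, gold, class_count,
                      class_names = NULL) {
  stopifnot(length(matches) == length(candidates),
            length(matches) == length(gold))
  k <- class_count + 1L
  counts <- matrix(0L, k, k)
  labs <- c(class_names %||% as.character(seq_len(class_count) - 1L),
            "background")
  dimnames(counts) <- list(candidate = labs, gold = labs)
  for (m in seq_along(matches)) {
    mr <- matches[[m]]
    if (nrow(mr$pairs))
      for (p in seq_len(nrow(mr$pairs)))
        counts[mr$pairs$cand_class[p] + 1L, mr$pairs$gold_class[p] + 1L] <-
          counts[mr$pairs$cand_class[p] + 1L, mr$pairs$gold_class[p] + 1L] + 1L
    for (j in mr$unmatched_gold) {
      gc <- gold[[m]]$class_id[j] + 1L
      counts[k, gc] <- counts[k, gc] + 1L
    }
    for (i in mr$unmatched_candidates) {
      cc <- candidates[[m]]$class_id[i] + 1L
      counts[cc, k] <- counts[cc, k] + 1L
    }
  }
  if (any(counts[, seq_len(class_count)] < 0))
    stop("negative count", call. = FALSE)
  csum <- colSums(counts)
  proportions <- sweep(counts, 2, pmax(csum, 1L), "/")
  proportions[, csum == 0] <- 0
  structure(list(counts = counts, proportions = proportions,
                 class_names = labs[seq_len(class_count)]),
            class = "confusion_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix (rows: candidate, cols: gold)>\n")
  print(x$counts)
  invisible(x)
}

#' Per-class and overall annotation accuracy
#'
#' Per-class accuracy is the diagonal count over the gold column total
#' (background column excluded), so a *missed* gold nodule counts against
#' its class; overall accuracy is the summed diagonal over all gold
#' nodules. With a strongly imbalanced class mix the overall figure is
#' dominated by the common classes — the count-weighted mean of the
#' per-class accuracies, exactly.
#'
#' @param cm a `confusion_matrix`.
#' @return `list(per_class =, overall =)`; per-class is `NaN` for classes
#'   with no gold instances.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  k <- length(cm$class_names)
  counts <- cm$counts
  gold_tot <- colSums(counts)[seq_len(k)]
  if (sum(gold_tot) == 0) stop("no gold boxes", call. = FALSE)
  per_class <- diag(counts)[seq_len(k)] / gold_tot
  names(per_class) <- cm$class_names
  list(per_class = per_class,
       overall = sum(diag(counts)[seq_len(k)]) / sum(gold_tot))
}

# Average precision by all-points interpolation: area under the precision
# envelope as a function of recall.
average_precision <- function(tp, n_gold) {
  if (n_gold == 0L) return(NA_real_)
  if (length(tp) == 0L) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_gold
  precision <- cum_tp / (cum_tp + cum_fp)
  # precision envelope (non-increasing from the right)
  for (i in rev(seq_len(length(precision) - 1L)))
    precision[i] <- max(precision[i], precision[i + 1L])
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * precision)
}

#' Mean average precision (mAP50, mAP50-95)
#'
#' Standard detection metric: per class, detections across all images are
#' ranked by confidence and greedily matched to unused same-class gold
#' boxes at each IoU threshold (highest-IoU available gold wins); AP is
#' the all-points-interpolated area under the precision-recall curve; mAP
#' is the unweighted mean over classes with at least one gold instance.
#' `map50` is mAP at IoU 0.5; `map50_95` averages IoU 0.5 to 0.95 in
#' steps of 0.05.
#'
#' @param candidates list (one per image) of [labeled_boxes] with
#'   confidences.
#' @param gold list (one per image) of gold [labeled_boxes].
#' @param class_count number of classes.
#' @param iou_thresholds IoU thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @return `list(map_per_threshold =, map50 =, map50_95 =,
#'   ap_per_class =)`.
#' @export
mean_average_precision <- function(candidates, gold, class_count,
                                   iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(length(candidates) == length(gold))
  n_img <- length(candidates)
  ap <- matrix(NA_real_, length(iou_thresholds), class_count,
               dimnames = list(sprintf("%.2f", iou_thresholds), NULL))
  for (cl in seq_len(class_count) - 1L) {
    det <- list()
    gold_cl <- lapply(gold, function(g) g[g$class_id == cl, , drop = FALSE])
    n_gold <- sum(vapply(gold_cl, nrow, integer(1)))
    for (m in seq_len(n_img)) {
      d <- candidates[[m]]
      d <- d[d$class_id == cl, , drop = FALSE]
      if (nrow(d))
        det[[length(det) + 1L]] <- data.frame(img = m, conf = d$confidence,
                                              cx = d$cx, cy = d$cy,
                                              w = d$w, h = d$h)
    }
    det <- if (length(det)) do.call(rbind, det) else
      data.frame(img = integer(), conf = numeric(), cx = numeric(),
                 cy = numeric(), w = numeric(), h = numeric())
    det <- det[order(-det$conf, det$img), , drop = FALSE]
    for (ti in seq_along(iou_thresholds)) {
      if (n_gold == 0L) next
      thr <- iou_thresholds[ti]
      used <- lapply(gold_cl, function(g) rep(FALSE, nrow(g)))
      tp <- logical(nrow(det))
      for (di in seq_len(nrow(det))) {
        m <- det$img[di]
        g <- gold_cl[[m]]
        if (nrow(g) == 0L) next
        ious <- vapply(seq_len(nrow(g)), function(j)
          box_iou(det[di, ], g[j, ]), numeric(1))
        ious[used[[m]]] <- -1
        j <- which.max(ious)
        if (length(j) && ious[j] >= thr) {
          tp[di] <- TRUE
          used[[m]][j] <- TRUE
        }
      }
      ap[ti, cl + 1L] <- average_precision(tp, n_gold)
    }
  }
  map_per_threshold <- rowMeans(ap, na.rm = TRUE)
  list(map_per_threshold = map_per_threshold,
       map50 = map_per_threshold[["0.50"]],
       map50_95 = mean(map_per_threshold),
       ap_per_class = ap)
}

#' End-to-end annotation audit
#'
#' Convenience pipeline over parallel candidate/gold box lists: optional
#' confidence filtering and class-agnostic NMS (applied only when the
#' candidates carry confidences, i.e., are model output), IoU matching,
#' confusion matrix and accuracies.
#'
#' @param candidates,gold lists of [labeled_boxes], one element per image.
#' @param class_count number of classes.
#' @param class_names optional labels.
#' @param match_iou pairing threshold (default 0.5).
#' @param conf_threshold confidence filter (default 0.1); ignored for
#'   human candidates (no confidence).
#' @param nms_iou NMS threshold (default 0.7); ignored for human
#'   candidates.
#' @return `list(confusion =, accuracy =, matches =, candidates =)` where
#'   `candidates` are the boxes actually scored (post filter/NMS).
#' @export
evaluate_annotations <- function(candidates, gold, class_count,
                                 class_names = NULL, match_iou = 0.5,
                                 conf_threshold = 0.1, nms_iou = 0.7) {
  stopifnot(length(candidates) == length(gold))
  scored <- lapply(candidates, function(b) {
    if (nrow(b) && !anyNA(b$confidence)) {
      b <- filter_confidence(b, conf_threshold)
      b <- class_agnostic_nms(b, nms_iou)
    }
    b
  })
  matches <- mapply(match_to_gold, scored, gold,
                    MoreArgs = list(match_iou = match_iou),
                    SIMPLIFY = FALSE)
  cm <- confusion(matches, scored, gold, class_count, class_names)
  list(confusion = cm, accuracy = accuracy(cm), matches = matches,
       candidates = scored)
}
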