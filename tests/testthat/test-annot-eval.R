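box1 <- function(cx, cy, w, h, cls = 0L, conf = NA_real_)
  labeled_boxes(cls, cx, cy, w, h, conf)

test_that("box_iou: identity, disjointness, hand-computed overlap", {
  a <- box1(0.5, 0.5, 0.2, 0.2)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, box1(0.9, 0.9, 0.1, 0.1)), 0)
  # two half-width boxes sharing half their width: inter 0.25, union 0.75
  l <- box1(0.25, 0.5, 0.5, 1)
  r <- box1(0.5, 0.5, 0.5, 1)
  expect_equal(box_iou(l, r), 1 / 3, tolerance = 1e-12)
  # touching edges count as disjoint
  expect_equal(box_iou(box1(0.25, 0.5, 0.5, 1), box1(0.75, 0.5, 0.5, 1)), 0)
})

test_that("class-agnostic NMS basics and suppression antichain", {
  b <- box1(0.5, 0.5, 0.2, 0.2, conf = 0.7)
  expect_equal(nrow(class_agnostic_nms(b)), 1)

  two <- labeled_boxes(c(0L, 3L), c(0.5, 0.5), c(0.5, 0.5), c(0.2, 0.2),
                       c(0.2, 0.2), c(0.9, 0.8))
  kept <- class_agnostic_nms(two, 0.7)
  expect_equal(nrow(kept), 1)       # suppression crosses classes
  expect_equal(kept$confidence, 0.9)

  set.seed(50)
  for (i in 1:50) {
    boxes <- random_boxes(sample(2:8, 1), with_conf = TRUE)
    thr <- runif(1, 0.2, 0.8)
    kept <- class_agnostic_nms(boxes, thr)
    expect_false(is.unsorted(rev(kept$confidence)))
    if (nrow(kept) > 1)
      for (i2 in 1:(nrow(kept) - 1)) for (j2 in (i2 + 1):nrow(kept))
        expect_lte(box_iou(kept[i2, ], kept[j2, ]), thr)
  }
  expect_error(class_agnostic_nms(box1(0.5, 0.5, 0.2, 0.2)), "confidence")
})

test_that("NMS equals the exhaustive greedy oracle over 200 seeded trials", {
  set.seed(60)
  for (trial in 1:200) {
    boxes <- random_boxes(sample(1:8, 1), with_conf = TRUE)
    thr <- runif(1, 0.1, 0.9)
    got <- class_agnostic_nms(boxes, thr)
    want <- oracle_nms(boxes, thr)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("confidence filter: boundary inclusive, monotone in threshold", {
  mixed <- labeled_boxes(0L, c(0.3, 0.5, 0.7), 0.5, 0.1, 0.1,
                         c(0.05, 0.1, 0.5))
  expect_equal(nrow(filter_confidence(mixed, 0)), 3)
  expect_equal(nrow(filter_confidence(mixed, 0.1)), 2)
  expect_equal(nrow(filter_confidence(mixed, 0.9)), 0)
  set.seed(70)
  b <- random_boxes(20, with_conf = TRUE)
  thrs <- sort(runif(5))
  kept <- vapply(thrs, function(t) nrow(filter_confidence(b, t)), integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("greedy matching: trivial cases and the brute-force oracle", {
  g <- random_boxes(3)
  ident <- match_to_gold(g, g)
  expect_equal(nrow(ident$pairs), 3)
  expect_length(ident$unmatched_gold, 0)
  expect_length(ident$unmatched_candidates, 0)
  expect_equal(ident$pairs$iou, rep(1, 3), tolerance = 1e-12)

  none <- match_to_gold(empty <- g[0, ], g)
  expect_equal(none$unmatched_gold, 1:3)

  set.seed(80)
  for (trial in 1:200) {
    cand <- random_boxes(sample(0:5, 1))
    gold <- random_boxes(sample(0:5, 1))
    thr <- runif(1, 0.2, 0.7)
    got <- match_to_gold(cand, gold, thr)
    want <- oracle_match(cand, gold, thr)
    expect_equal(nrow(got$pairs), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      expect_equal(got$pairs$cand, want[, 1])
      expect_equal(got$pairs$gold, want[, 2])
      expect_equal(got$pairs$iou, want[, 3], tolerance = 1e-12)
    }
    expect_true(all(got$pairs$iou >= thr))
    expect_false(anyDuplicated(got$pairs$cand) > 0)
    expect_false(anyDuplicated(got$pairs$gold) > 0)
  }
})

test_that("confusion matrix: perfect diagonal, off-diagonal cell, conservation", {
  g <- random_boxes(4, class_count = 6)
  perfect <- confusion(list(match_to_gold(g, g)), list(g), list(g), 6)
  expect_equal(sum(diag(perfect$counts)[1:6]), 4)
  expect_equal(sum(perfect$counts) - sum(diag(perfect$counts)), 0)

  # one gold 4B (class 3) annotated as 4A (class 2)
  gold <- box1(0.5, 0.5, 0.2, 0.2, cls = 3L)
  cand <- box1(0.5, 0.5, 0.2, 0.2, cls = 2L)
  cm <- confusion(list(match_to_gold(cand, gold)), list(cand), list(gold),
                  6, tirads_classes())
  expect_equal(cm$counts["4A", "4B"], 1L)
  expect_equal(sum(cm$counts), 1L)
  expect_equal(cm$proportions["4A", "4B"], 1)

  # misses fall in the background row, false detections in the background
  # column; grand total = pairs + misses + false detections
  set.seed(90)
  cand <- random_boxes(5); gold <- random_boxes(6)
  mr <- match_to_gold(cand, gold, 0.5)
  cm <- confusion(list(mr), list(cand), list(gold), 6)
  expect_equal(sum(cm$counts),
               nrow(mr$pairs) + length(mr$unmatched_gold) +
                 length(mr$unmatched_candidates))
  expect_equal(unname(colSums(cm$counts)[1:6]),
               tabulate(gold$class_id + 1L, 6))  # column sums = gold totals
  csum <- colSums(cm$counts)
  psum <- colSums(cm$proportions)
  expect_true(all(abs(psum[csum > 0] - 1) < 1e-12))
})

test_that("accuracy: toy arithmetic and the count-weighted-mean identity", {
  # gold {A:8, B:2}, correct {A:7, B:0}: the B boxes called A
  gold <- labeled_boxes(c(rep(0L, 8), rep(1L, 2)),
                        cx = seq(0.05, 0.95, length.out = 10), cy = 0.5,
                        w = 0.04, h = 0.2)
  cand <- gold
  cand$class_id <- c(rep(0L, 7), 1L, 0L, 0L)
  cand$class_id[8] <- 2L    # one A miscalled as class 2
  cm <- confusion(list(match_to_gold(cand, gold)), list(cand), list(gold), 3)
  acc <- accuracy(cm)
  expect_equal(unname(acc$per_class[1:2]), c(7 / 8, 0))
  expect_equal(acc$overall, 0.7)

  # algebraic identity on random confusions
  set.seed(100)
  for (i in 1:20) {
    cand <- random_boxes(8, class_count = 4)
    gold <- cand
    gold$class_id <- sample(0:3, 8, replace = TRUE)
    cm <- confusion(list(match_to_gold(cand, gold)), list(cand), list(gold),
                    4)
    acc <- accuracy(cm)
    gt <- colSums(cm$counts)[1:4]
    pc <- acc$per_class
    pc[gt == 0] <- 0
    expect_equal(acc$overall, sum(pc * gt) / sum(gt), tolerance = 1e-12)
  }
})

test_that("mAP: perfect and empty detectors, hand-enumerated toy AP", {
  set.seed(110)
  gold <- lapply(1:3, function(i) random_boxes(2, class_count = 2))
  perfect <- lapply(gold, function(g) { g$confidence <- 0.9; g })
  mp <- mean_average_precision(perfect, gold, 2)
  expect_equal(mp$map50, 1)
  expect_equal(mp$map50_95, 1)

  nothing <- lapply(gold, function(g) g[0, ])
  mp0 <- mean_average_precision(nothing, gold, 2)
  expect_equal(mp0$map50, 0)
  expect_equal(mp0$map50_95, 0)

  # single class, 3 gold; detections ranked: TP, FP, TP, TP.
  # Raw PR points: (1/3, 1), (1/3, 1/2), (2/3, 2/3), (1, 3/4). The
  # precision envelope is 1 on (0, 1/3] and 3/4 on (1/3, 1], so the
  # all-points AP = 1/3 * 1 + 2/3 * 3/4 = 5/6.
  gold1 <- labeled_boxes(0L, c(0.2, 0.5, 0.8), 0.5, 0.1, 0.1)
  det <- labeled_boxes(0L, c(0.2, 0.35, 0.5, 0.8), c(0.5, 0.9, 0.5, 0.5),
                       0.1, 0.1, c(0.9, 0.8, 0.7, 0.6))
  ap <- mean_average_precision(list(det), list(gold1), 1,
                               iou_thresholds = 0.5)
  expect_equal(unname(ap$map50), 5 / 6, tolerance = 1e-12)

  # monotone non-increasing in the IoU threshold; invariant to image order
  set.seed(111)
  gold <- lapply(1:4, function(i) random_boxes(3))
  cand <- lapply(gold, function(g) {
    g$cx <- pmin(pmax(g$cx + runif(3, -0.02, 0.02), g$w / 2), 1 - g$w / 2)
    g$confidence <- runif(3)
    g
  })
  mp <- mean_average_precision(cand, gold, 6)
  expect_true(all(diff(mp$map_per_threshold) <= 1e-9))
  perm <- c(3, 1, 4, 2)
  mp_perm <- mean_average_precision(cand[perm], gold[perm], 6)
  expect_equal(mp_perm$map50, mp$map50, tolerance = 1e-12)
})

test_that("evaluate_annotations pipelines filter, NMS, matching, confusion", {
  set.seed(120)
  gold <- lapply(1:3, function(i) random_boxes(2, class_count = 3))
  cand <- lapply(gold, function(g) {
    g$confidence <- c(0.9, 0.05)     # second box falls to the conf filter
    g
  })
  res <- evaluate_annotations(cand, gold, 3, conf_threshold = 0.1)
  expect_equal(sum(vapply(res$candidates, nrow, integer(1))), 3)
  expect_equal(length(res$matches), 3)
  expect_s3_class(res$confusion, "confusion_matrix")
  expect_true(res$accuracy$overall <= 1)
})
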