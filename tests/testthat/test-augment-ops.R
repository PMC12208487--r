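test_that("gaussian_kernel matches the closed form and normalizes", {
  k <- gaussian_kernel(5, 1)
  # center/corner ratio: exp(-0) / exp(-(4+4)/2) = exp(4)
  expect_equal(k$weights[3, 3] / k$weights[1, 1], exp(4), tolerance = 1e-12)
  expect_equal(sum(k$weights), 1, tolerance = 1e-9)
  expect_equal(k$weights, t(k$weights))                     # x <-> y
  expect_equal(k$weights, k$weights[5:1, ])                 # y -> -y
  expect_equal(k$weights, k$weights[, 5:1])                 # x -> -x
  expect_equal(which.max(k$weights), 13L)                   # center max

  for (sigma in c(0.3, 0.9, 2.2, 5)) {
    expect_equal(sum(gaussian_kernel(5, sigma)$weights), 1, tolerance = 1e-9)
    expect_equal(sum(gaussian_kernel(7, sigma)$weights), 1, tolerance = 1e-9)
  }
  # flat limit
  expect_equal(gaussian_kernel(5, 1e6)$weights,
               matrix(1 / 25, 5, 5), tolerance = 1e-9)

  expect_error(gaussian_kernel(4, 1), "odd")
  expect_error(gaussian_kernel(5, 0), "positive")
})

test_that("defocus: constant invariance, impulse response, smoothing", {
  const <- gray_image(matrix(128L, 20, 20))
  expect_identical(unclass(apply_defocus(const, 1.3)), unclass(const))

  # impulse response equals the kernel scaled by the pixel value
  m <- matrix(0L, 15, 15); m[8, 8] <- 255L
  out <- apply_defocus(gray_image(m), 0.8)
  k <- gaussian_kernel(5, 0.8)
  expect_equal(unclass(out)[6:10, 6:10],
               matrix(as.integer(round(255 * k$weights)), 5, 5))
  expect_true(all(unclass(out)[-(6:10), ] == 0L))

  set.seed(99)
  for (i in 1:50) {
    img <- random_image(12)
    out <- apply_defocus(img, runif(1, 0.5, 2.5))
    expect_lte(var(as.vector(unclass(out))), var(as.vector(unclass(img))))
  }
})

test_that("shadow box: opacity, linear blend, oracle, darkening", {
  img <- gray_image(matrix(200L, 10, 10))
  out <- apply_shadow_box(img, c(3, 3, 6, 6), alpha = 1)
  expect_true(all(unclass(out)[3:6, 3:6] == 0L))
  expect_true(all(unclass(out)[1:2, ] == 200L))

  out <- apply_shadow_box(img, c(3, 3, 6, 6), alpha = 0.5)
  expect_true(all(unclass(out)[3:6, 3:6] == 100L))

  # per-pixel brute force on 8x8 rasters
  set.seed(5)
  for (i in 1:20) {
    img <- random_image(8)
    a <- runif(1, 0.1, 1)
    out <- apply_shadow_box(img, c(2, 3, 7, 6), a)
    ref <- unclass(img)
    ref[2:7, 3:6] <- oracle_affine(ref[2:7, 3:6, drop = FALSE], 1 - a, 0)
    expect_identical(unclass(out), ref)
    expect_lte(mean(unclass(out)), mean(unclass(img)))
  }

  expect_error(apply_shadow_box(img, c(20, 20, 30, 30), 0.5), "empty")
  expect_error(apply_shadow_box(img, c(1, 1, 5, 5), 0), "alpha")
})

test_that("sidelobe: identity at angle 0, vanishing alpha, interior of constants", {
  img <- random_image(16)
  expect_identical(unclass(apply_sidelobe(img, 0, 0.3)), unclass(img))
  expect_identical(unclass(apply_sidelobe(img, 7, 1e-9)), unclass(img))

  const <- gray_image(matrix(180L, 64, 64))
  out <- apply_sidelobe(const, 8, 0.3)
  # interior pixels see a rotated constant = unchanged; only the border
  # ring (rotated out-of-frame fill) darkens
  interior <- unclass(out)[20:45, 20:45]
  expect_true(all(interior == 180L))
  expect_true(all(unclass(out) <= 180L))

  # brute-force blend check on 8x8: out = (1-a)*img + a*rot
  set.seed(8)
  img <- random_image(8)
  a <- 0.25; ang <- 5
  rot <- usaug:::rotate_image(img, ang)
  ref <- matrix(pmin(pmax(round((1 - a) * unclass(img) + a * rot), 0), 255),
                8, 8)
  expect_equal(unclass(apply_sidelobe(img, ang, a)),
               matrix(as.integer(ref), 8, 8))

  expect_error(apply_sidelobe(img, 5, 1), "alpha")
})

test_that("brightness/contrast matches the per-pixel affine oracle", {
  img <- random_image(8)
  expect_identical(unclass(apply_brightness_contrast(img, 1, 0)),
                   unclass(img))
  expect_true(all(unclass(apply_brightness_contrast(img, 1, 300)) == 255L))

  px <- gray_image(matrix(150L, 1, 1))
  expect_equal(unclass(apply_brightness_contrast(px, 2, -100))[1, 1], 200L)

  set.seed(3)
  for (i in 1:20) {
    img <- random_image(8)
    g <- runif(1, 0.5, 2); b <- runif(1, -80, 80)
    expect_identical(unclass(apply_brightness_contrast(img, g, b)),
                     oracle_affine(unclass(img), g, b))
  }
  expect_error(apply_brightness_contrast(img, 0, 0), "positive")
})

test_that("rotation transforms boxes by the analytic corner hull", {
  img <- gray_image(matrix(100L, 50, 50))
  boxes <- labeled_boxes(0, 0.5, 0.5, 0.2, 0.1)

  r0 <- apply_rotation(img, boxes, 0)
  expect_equal(r0$boxes$cx, 0.5)
  expect_equal(r0$boxes$w, 0.2)
  expect_identical(unclass(r0$image), unclass(img))

  sq <- labeled_boxes(0, 0.5, 0.5, 0.3, 0.3)
  r90 <- apply_rotation(img, sq, 90)
  expect_equal(unlist(r90$boxes[, c("cx", "cy", "w", "h")]),
               unlist(sq[, c("cx", "cy", "w", "h")]), tolerance = 1e-9)

  # 45 degrees: hull side = (w + h) * cos(45) = 0.3 / sqrt(2)
  r45 <- apply_rotation(img, boxes, 45)
  expect_equal(r45$boxes$w, 0.3 / sqrt(2), tolerance = 1e-9)
  expect_equal(r45$boxes$h, 0.3 / sqrt(2), tolerance = 1e-9)
  expect_equal(r45$boxes$cx, 0.5, tolerance = 1e-9)

  # analytic corner rotation oracle at an arbitrary angle
  ang <- 17
  th <- ang * pi / 180
  hull_w <- 0.2 * abs(cos(th)) + 0.1 * abs(sin(th))
  hull_h <- 0.2 * abs(sin(th)) + 0.1 * abs(cos(th))
  r17 <- apply_rotation(img, boxes, ang)
  expect_equal(r17$boxes$w, hull_w, tolerance = 1e-9)
  expect_equal(r17$boxes$h, hull_h, tolerance = 1e-9)

  # a box rotated mostly out of frame is dropped
  corner <- labeled_boxes(0, 0.98, 0.02, 0.2, 0.2)
  r <- apply_rotation(img, corner, 45)
  expect_true(nrow(r$boxes) <= 1)
})

test_that("all operators preserve dimensions and intensity range; only rotation touches boxes", {
  set.seed(12)
  img <- random_image(24)
  boxes <- random_boxes(3)
  rec <- image_record("t", img, boxes)
  specs <- list(
    aug_spec("defocus", list(sigma = 1.5)),
    aug_spec("shadow_box", list(x = 0.5, y = 0.5, w = 0.3, h = 0.3,
                                alpha = 0.7)),
    aug_spec("sidelobe", list(angle = 6, alpha = 0.2)),
    aug_spec("brightness", list(bias = 30)),
    aug_spec("contrast", list(gain = 1.2)))
  for (s in specs) {
    out <- apply_spec(rec, s)
    expect_equal(dim(out$image), dim(img))
    expect_true(min(out$image) >= 0 && max(out$image) <= 255)
    expect_equal(out$boxes, boxes)   # boxes untouched by non-rotation ops
  }
  out <- apply_spec(rec, aug_spec("rotation", list(angle = 9)))
  expect_equal(dim(out$image), dim(img))
})

test_that("apply_spec is deterministic, id-suffixed, serialization-stable", {
  set.seed(2)
  rec <- image_record("img001", random_image(16), random_boxes(2))
  s <- aug_spec("sidelobe", list(angle = 4.25, alpha = 0.21))

  a <- apply_spec(rec, s)
  b <- apply_spec(rec, s)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$image_id, b$image_id)
  expect_true(startsWith(a$image_id, "img001__sidelobe"))

  ident <- apply_spec(rec, aug_spec("brightness", list(bias = 0)))
  expect_identical(unclass(ident$image), unclass(rec$image))
  expect_false(identical(ident$image_id, rec$image_id))

  # round-trip through the serialized sidecar form
  s2 <- usaug:::spec_from_list(
    jsonlite::fromJSON(jsonlite::toJSON(usaug:::spec_to_list(s),
                                        auto_unbox = TRUE, digits = NA)))
  expect_identical(unclass(apply_spec(rec, s2)$image), unclass(a$image))

  expect_error(aug_spec("defocus", list()), "sigma")
  expect_error(aug_spec("warp", list()), "arg")
})
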