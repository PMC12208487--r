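#' Discrete 2-D Gaussian blur kernel
#'
#' Builds the `size` x `size` kernel whose weights follow the bivariate
#' Gaussian `exp(-(x^2 + y^2) / (2 sigma^2))`, where `x` and `y` are the
#' horizontal and vertical offsets from the kernel center and `sigma`
#' controls the blur strength. The continuous normalization coefficient
#' `1/(2 pi sigma^2)` does not make a truncated discrete kernel sum to one,
#' so the weights are renormalized to unit sum: mean image brightness is
#' preserved by the convolution, which is what the continuous
#' normalization is for.
#'
#' @param size odd kernel side, `>= 3` (default 5, the standard defocus
#'   kernel here).
#' @param sigma positive standard deviation in pixels.
#' @return a `gaussian_kernel`: list with `size`, `sigma` and the `weights`
#'   matrix (unit sum, symmetric, center-maximal).
#' @examples
#' k <- gaussian_kernel(5, 1)
#' sum(k$weights)                      # 1
#' k$weights[3, 3] / k$weights[1, 1]   # exp(4)
#' @export
gaussian_kernel <- function(size = 5L, sigma) {
  if (size %% 2L == 0L || size < 3L)
    stop("kernel size must be odd and >= 3", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  half <- (size - 1L) / 2L
  off <- seq(-half, half)
  w <- exp(-outer(off^2, off^2, `+`) / (2 * sigma^2))
  structure(list(size = as.integer(size), sigma = sigma, weights = w / sum(w)),
            class = "gaussian_kernel")
}

# 2-D convolution with replicate (edge-clamp) padding, stride 1. Vectorized
# as a sum of shifted submatrices; fast enough in plain R for 8-bit frames.
convolve2d_replicate <- function(m, weights) {
  h <- nrow(m); w <- ncol(m)
  k <- nrow(weights); half <- (k - 1L) %/% 2L
  ridx <- pmin(pmax(seq_len(h + 2L * half) - half, 1L), h)
  cidx <- pmin(pmax(seq_len(w + 2L * half) - half, 1L), w)
  pad <- m[ridx, cidx, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(k))
    for (j in seq_len(k))
      out <- out + weights[i, j] *
        pad[i:(i + h - 1L), j:(j + w - 1L), drop = FALSE]
  out
}

#' Simulated defocus (Gaussian blur)
#'
#' Ultrasound frames acquired away from the transmit focus are blurred;
#' the effect is emulated by convolving the image with a 5x5 Gaussian
#' kernel ([gaussian_kernel]), stride 1, replicate padding at the edges
#' (zero padding would paint an artificial dark frame). Labels are
#' untouched: blur moves no anatomy.
#'
#' @param image a [gray_image].
#' @param sigma positive blur standard deviation; sampled uniformly from a
#'   configured range when driven by the planner.
#' @param size odd kernel side (default 5).
#' @return the blurred [gray_image], same dimensions.
#' @export
apply_defocus <- function(image, sigma, size = 5L) {
  stopifnot(is_gray_image(image))
  k <- gaussian_kernel(size, sigma)
  clamp_image(convolve2d_replicate(unclass(image) * 1.0, k$weights))
}

#' Acoustic-shadow occlusion box
#'
#' Fast approximation of an acoustic shadow: a rectangle of the image is
#' darkened by a factor `alpha` (`out = (1 - alpha) * in` inside, unchanged
#' outside). `alpha = 1` paints the region fully black, as behind a dense
#' calcification. Labels are retained even when a nodule is occluded — the
#' point of the artifact is to teach robustness to exactly that masking.
#'
#' @param image a [gray_image].
#' @param region integer vector `c(row1, col1, row2, col2)`, 1-based
#'   inclusive pixel bounds; clipped to the frame.
#' @param alpha opacity in `(0, 1]`.
#' @return shadowed [gray_image].
#' @export
apply_shadow_box <- function(image, region, alpha) {
  stopifnot(is_gray_image(image), length(region) == 4L)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  r1 <- max(1L, as.integer(region[1])); c1 <- max(1L, as.integer(region[2]))
  r2 <- min(nrow(image), as.integer(region[3]))
  c2 <- min(ncol(image), as.integer(region[4]))
  if (r1 > r2 || c1 > c2)
    stop("shadow region is empty after clipping to the image", call. = FALSE)
  m <- unclass(image) * 1.0
  m[r1:r2, c1:c2] <- (1 - alpha) * m[r1:r2, c1:c2]
  clamp_image(m)
}

# Bilinear rotation about the image center, zero fill outside the source
# frame (ultrasound background is black). Positive angles rotate the image
# content counterclockwise on screen. Shared by sidelobe and rotation ops.
rotate_image <- function(image, angle_deg) {
  m <- unclass(image) * 1.0
  h <- nrow(m); w <- ncol(m)
  if (angle_deg %% 360 == 0) return(m)
  th <- -angle_deg * pi / 180       # inverse mapping
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  cs <- cos(th); sn <- sin(th)
  gx <- matrix(rep(seq_len(w), each = h), h, w) - cc   # x = column offset
  gy <- matrix(rep(seq_len(h), times = w), h, w) - cr  # y = row offset
  sx <- cs * gx - sn * gy + cc
  sy <- sn * gx + cs * gy + cr
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inside <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  cl <- function(v, lim) pmin(pmax(v, 1), lim)
  at <- function(rr, cc2)
    m[cbind(as.vector(cl(rr, h)), as.vector(cl(cc2, w)))]
  v <- (1 - fx) * (1 - fy) * at(y0, x0) +
       fx * (1 - fy) * at(y0, x0 + 1) +
       (1 - fx) * fy * at(y0 + 1, x0) +
       fx * fy * at(y0 + 1, x0 + 1)
  v[!inside] <- 0
  matrix(v, h, w)
}

#' Sidelobe-artifact overlay
#'
#' Off-axis transducer lobes superimpose a faint, slightly rotated and
#' displaced copy of the anatomy on the main-lobe image. Emulated as a
#' convex blend of the image with a rotated copy of itself:
#' `out = (1 - alpha) * original + alpha * rotate(original, angle)`,
#' rotation about the center with bilinear interpolation and black fill.
#' The convex blend keeps intensities inside the input range. Labels are
#' unchanged (the true anatomy stays put; only a ghost is added).
#'
#' @param image a [gray_image].
#' @param angle_deg small rotation angle of the ghost copy, degrees.
#' @param alpha ghost opacity in `(0, 1)`.
#' @return blended [gray_image].
#' @export
apply_sidelobe <- function(image, angle_deg, alpha) {
  stopifnot(is_gray_image(image))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  m <- unclass(image) * 1.0
  clamp_image((1 - alpha) * m + alpha * rotate_image(image, angle_deg))
}

#' Brightness / contrast adjustment
#'
#' Affine intensity remap `out = clip(round(gain * in + bias))`. A pure
#' brightness change is `gain = 1, bias != 0`; a contrast change scales
#' around zero (callers wanting a mid-gray pivot pass
#' `bias = 128 * (1 - gain)`).
#'
#' @param image a [gray_image].
#' @param gain multiplicative factor, `> 0`.
#' @param bias additive offset in intensity units.
#' @return adjusted [gray_image].
#' @export
apply_brightness_contrast <- function(image, gain = 1, bias = 0) {
  stopifnot(is_gray_image(image))
  if (!is.numeric(gain) || gain <= 0) stop("gain must be positive", call. = FALSE)
  clamp_image(gain * (unclass(image) * 1.0) + bias)
}

# Forward-rotate normalized boxes about the image center and take the
# axis-aligned hull of the four corners, in pixel space so non-square
# frames are handled. Boxes whose clipped area drops below min_frac of the
# original are discarded. Exposed internally so the balancing planner can
# project post-rotation class counts without touching pixels.
rotate_boxes <- function(boxes, angle_deg, width, height, min_frac = 0.25) {
  if (nrow(boxes) == 0L) return(boxes)
  th <- angle_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  keep <- logical(nrow(boxes))
  out <- boxes
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    px <- b$cx * width; py <- b$cy * height
    hw <- b$w * width / 2; hh <- b$h * height / 2
    corn_x <- px + c(-hw, hw, hw, -hw) - width / 2
    corn_y <- py + c(-hh, -hh, hh, hh) - height / 2
    rx <- cs * corn_x - sn * corn_y + width / 2
    ry <- sn * corn_x + cs * corn_y + height / 2
    x1 <- max(0, min(rx)); x2 <- min(width, max(rx))
    y1 <- max(0, min(ry)); y2 <- min(height, max(ry))
    area0 <- (2 * hw) * (2 * hh)
    if (x2 <= x1 || y2 <= y1 || (x2 - x1) * (y2 - y1) < min_frac * area0)
      next
    keep[i] <- TRUE
    out$cx[i] <- (x1 + x2) / 2 / width
    out$cy[i] <- (y1 + y2) / 2 / height
    out$w[i] <- (x2 - x1) / width
    out$h[i] <- (y2 - y1) / height
  }
  out[keep, , drop = FALSE]
}

#' Small-angle rotation of image and labels
#'
#' Rotates the image about its center (bilinear interpolation, zero fill,
#' unchanged canvas size) and replaces each bounding box by the
#' axis-aligned hull of its four rotated corners, clipped to the frame.
#' Boxes whose clipped area falls below `min_box_frac` of the original area
#' are dropped — a nodule mostly rotated out of frame is no longer a
#' usable training instance.
#'
#' @param image a [gray_image].
#' @param boxes a [labeled_boxes] frame.
#' @param angle_deg rotation angle, degrees (small angles in practice).
#' @param min_box_frac minimum surviving area fraction (default 0.25).
#' @return `list(image =, boxes =)`.
#' @export
apply_rotation <- function(image, boxes, angle_deg, min_box_frac = 0.25) {
  stopifnot(is_gray_image(image))
  validate_boxes(boxes)
  img <- clamp_image(rotate_image(image, angle_deg))
  bx <- rotate_boxes(boxes, angle_deg, ncol(image), nrow(image), min_box_frac)
  list(image = img, boxes = bx)
}

#' Augmentation specification
#'
#' A reproducible record of one augmentation: the operator name and its
#' fully sampled parameters. Applying the same spec to the same record
#' always yields the identical output; all randomness lives in the planner
#' that *samples* specs, never inside the operators.
#'
#' Parameter conventions per op: `defocus` needs `sigma`; `shadow_box`
#' needs `x, y, w, h` (region center/size as fractions of the frame) and
#' `alpha`; `sidelobe` needs `angle, alpha`; `brightness` needs `bias`;
#' `contrast` needs `gain`; `rotation` needs `angle`.
#'
#' @param op one of `"defocus"`, `"shadow_box"`, `"sidelobe"`,
#'   `"brightness"`, `"contrast"`, `"rotation"`.
#' @param params named list of numeric parameters for `op`.
#' @return an `aug_spec`.
#' @export
aug_spec <- function(op, params) {
  op <- match.arg(op, aug_op_names())
  need <- switch(op,
    defocus = "sigma", shadow_box = c("x", "y", "w", "h", "alpha"),
    sidelobe = c("angle", "alpha"), brightness = "bias",
    contrast = "gain", rotation = "angle")
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop(sprintf("op '%s' missing parameter(s): %s", op,
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(op = op, params = params[need]), class = "aug_spec")
}

#' @rdname aug_spec
#' @export
aug_op_names <- function() {
  c("defocus", "shadow_box", "sidelobe", "brightness", "contrast", "rotation")
}

#' @export
print.aug_spec <- function(x, ...) {
  cat(sprintf("<aug_spec %s(%s)>\n", x$op,
              paste(sprintf("%s=%.4g", names(x$params),
                            unlist(x$params)), collapse = ", ")))
  invisible(x)
}

# Deterministic, filename-safe token encoding a spec; used as the output
# image-id suffix so augmented copies are traceable.
spec_token <- function(spec) {
  paste0(spec$op, "-",
         paste(sprintf("%s%s", names(spec$params),
                       formatC(unlist(spec$params), format = "fg",
                               digits = 6)), collapse = "_"))
}

spec_to_list <- function(spec) list(op = spec$op, params = spec$params)

spec_from_list <- function(x) aug_spec(x$op, lapply(x$params, as.numeric))

#' Apply one augmentation spec to an image record
#'
#' Dispatches to the operator named by `spec$op`; the output record's id is
#' the input id plus a deterministic suffix encoding the spec, so
#' augmented files are self-describing and re-running is byte-identical.
#'
#' @param record an [image_record].
#' @param spec an [aug_spec].
#' @param min_box_frac minimum box survival fraction for rotation.
#' @return the augmented [image_record].
#' @export
apply_spec <- function(record, spec, min_box_frac = 0.25) {
  stopifnot(inherits(record, "image_record"), inherits(spec, "aug_spec"))
  p <- spec$params
  img <- record$image
  boxes <- record$boxes
  if (spec$op == "defocus") {
    img <- apply_defocus(img, p$sigma)
  } else if (spec$op == "shadow_box") {
    h <- nrow(img); w <- ncol(img)
    r1 <- round((p$y - p$h / 2) * h) + 1L
    r2 <- round((p$y + p$h / 2) * h)
    c1 <- round((p$x - p$w / 2) * w) + 1L
    c2 <- round((p$x + p$w / 2) * w)
    img <- apply_shadow_box(img, c(r1, c1, r2, c2), p$alpha)
  } else if (spec$op == "sidelobe") {
    img <- apply_sidelobe(img, p$angle, p$alpha)
  } else if (spec$op == "brightness") {
    img <- apply_brightness_contrast(img, gain = 1, bias = p$bias)
  } else if (spec$op == "contrast") {
    img <- apply_brightness_contrast(img, gain = p$gain,
                                     bias = 128 * (1 - p$gain))
  } else if (spec$op == "rotation") {
    rot <- apply_rotation(img, boxes, p$angle, min_box_frac)
    img <- rot$image
    boxes <- rot$boxes
  }
  image_record(paste0(record$image_id, "__", spec_token(spec)),
               img, boxes, source = record$source)
}
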