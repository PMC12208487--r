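#' Graded acoustic-shadow field
#'
#' Physics-inspired (not physics-accurate) simulator of the shadow cast
#' behind a high-acoustic-impedance occluder. The beam is marched front by
#' front: each line perpendicular to the propagation direction inherits the
#' previous line's shadow, spread laterally by a 1-D blur (diffraction
#' refilling the shadow from the sides) and faded by a geometric decay
#' (shadow intensity falling with distance from the occluder). The result
#' is an attenuation raster in `[0, 1]` (1 = full shadow) aligned with the
#' image grid.
#'
#' @name shadow_field
NULL

new_shadow_field <- function(attenuation, direction, occluder,
                             diffusion_rate, decay_rate) {
  structure(list(attenuation = attenuation, direction = direction,
                 occluder = occluder, diffusion_rate = diffusion_rate,
                 decay_rate = decay_rate),
            class = "shadow_field")
}

#' @export
print.shadow_field <- function(x, ...) {
  cat(sprintf(
    "<shadow_field %d x %d, dir (%.2f, %.2f), diffusion %.3g, decay %.3g>\n",
    nrow(x$attenuation), ncol(x$attenuation), x$direction[1], x$direction[2],
    x$diffusion_rate, x$decay_rate))
  invisible(x)
}

# Normalized discrete Gaussian for the lateral diffraction spread; sd is in
# pixels per marched front. sd = 0 degenerates to the identity kernel.
diffusion_kernel <- function(sd) {
  if (sd <= 0) return(1)
  half <- max(1L, ceiling(3 * sd))
  off <- seq(-half, half)
  w <- exp(-off^2 / (2 * sd^2))
  w / sum(w)
}

# 1-D convolution with zero padding: mass can only leak out at the borders,
# never grow, which keeps the per-front attenuation mass non-increasing.
blur1d <- function(v, kern) {
  if (length(kern) == 1L) return(v)
  half <- (length(kern) - 1L) %/% 2L
  padded <- c(numeric(half), v, numeric(half))
  out <- numeric(length(v))
  for (j in seq_along(kern))
    out <- out + kern[j] * padded[j:(j + length(v) - 1L)]
  out
}

#' Propagate an acoustic shadow behind an occluder
#'
#' @param occluder binary (0/1 or logical) matrix marking the
#'   high-impedance object on the target grid; must be non-empty.
#' @param direction beam propagation direction as `c(dr, dc)` (row, column
#'   deltas). Axis-aligned presets — down `c(1,0)`, up `c(-1,0)`, right
#'   `c(0,1)`, left `c(0,-1)` — are propagated exactly on the grid;
#'   diagonal directions are handled by rotating the grid, marching
#'   downward, and rotating back (interpolation smooths such fields
#'   slightly).
#' @param diffusion_rate non-negative lateral spread (pixels of blur
#'   standard deviation per marched front); 0 disables diffraction and the
#'   scheme reduces to a sharp geometric projection.
#' @param decay_rate per-front fading in `[0, 1)`; behind a full-width
#'   occluder the maximum attenuation at depth `r` is exactly
#'   `(1 - decay_rate)^r`.
#' @return a `shadow_field`.
#' @export
propagate_shadow <- function(occluder, direction = c(1, 0),
                             diffusion_rate = 0.5, decay_rate = 0.05) {
  occ <- (unclass(occluder) != 0) * 1.0
  if (!is.matrix(occ)) stop("occluder must be a matrix", call. = FALSE)
  if (sum(occ) == 0) stop("occluder is empty", call. = FALSE)
  if (length(direction) != 2L || all(direction == 0))
    stop("direction must be a non-zero 2-vector", call. = FALSE)
  if (diffusion_rate < 0) stop("diffusion_rate must be >= 0", call. = FALSE)
  if (decay_rate < 0 || decay_rate >= 1)
    stop("decay_rate must lie in [0, 1)", call. = FALSE)
  dir <- direction / sqrt(sum(direction^2))

  axis <- axis_preset(dir)
  if (!is.na(axis)) {
    work <- orient_to_down(occ, axis)
    att <- march_down(work, diffusion_rate, decay_rate)
    att <- orient_from_down(att, axis)
  } else {
    # rotate so the beam points straight down, march, rotate back
    ang <- atan2(dir[2], dir[1]) * 180 / pi  # 0 = down in (dr, dc) terms
    occ_rot <- rotate_field(occ, -ang)
    att <- rotate_field(march_down((occ_rot > 0.5) * 1.0,
                                   diffusion_rate, decay_rate), ang)
    att <- pmin(pmax(att, 0), 1)
  }
  new_shadow_field(att, dir, occ != 0, diffusion_rate, decay_rate)
}

axis_preset <- function(dir) {
  eps <- 1e-9
  if (abs(dir[1] - 1) < eps && abs(dir[2]) < eps) return("down")
  if (abs(dir[1] + 1) < eps && abs(dir[2]) < eps) return("up")
  if (abs(dir[2] - 1) < eps && abs(dir[1]) < eps) return("right")
  if (abs(dir[2] + 1) < eps && abs(dir[1]) < eps) return("left")
  NA_character_
}

# Map the grid so the beam points down (rows increasing), and back.
orient_to_down <- function(m, axis) {
  switch(axis,
    down = m,
    up = m[nrow(m):1, , drop = FALSE],
    right = t(m),
    left = {tm <- t(m); tm[nrow(tm):1, , drop = FALSE]})
}

orient_from_down <- function(m, axis) {
  switch(axis,
    down = m,
    up = m[nrow(m):1, , drop = FALSE],
    right = t(m),
    left = t(m[nrow(m):1, , drop = FALSE]))
}

# Front-marching along increasing row index. Row 1 starts at the occluder
# value; every later front is the decayed, laterally blurred previous
# front, re-seeded to full shadow wherever the occluder itself extends.
march_down <- function(occ, diffusion_rate, decay_rate) {
  h <- nrow(occ)
  att <- matrix(0, h, ncol(occ))
  kern <- diffusion_kernel(diffusion_rate)
  att[1, ] <- occ[1, ]
  for (r in seq_len(h - 1L)) {
    nxt <- (1 - decay_rate) * blur1d(att[r, ], kern)
    att[r + 1L, ] <- pmin(pmax(pmax(nxt, occ[r + 1L, ]), 0), 1)
  }
  att
}

# rotate_image operates on the raw matrix; no 8-bit quantization needed.
rotate_field <- function(m, angle_deg) rotate_image(m, angle_deg)

#' Apply a shadow field to an image
#'
#' Per-pixel darkening `out = round(in * (1 - attenuation))`. With a
#' constant-alpha rectangular field this coincides exactly with
#' [apply_shadow_box].
#'
#' @param image a [gray_image].
#' @param field a `shadow_field` on the same grid.
#' @return shadowed [gray_image].
#' @export
apply_shadow_field <- function(image, field) {
  stopifnot(is_gray_image(image), inherits(field, "shadow_field"))
  if (!all(dim(field$attenuation) == dim(image)))
    stop("field grid does not match image dimensions", call. = FALSE)
  clamp_image(unclass(image) * (1 - field$attenuation))
}

#' Iso-attenuation contours of a shadow field
#'
#' Presentational: extracts iso-lines of the attenuation raster (as drawn
#' in contour-map illustrations of shadow formation) for plotting.
#'
#' @param field a `shadow_field`.
#' @param levels strictly increasing attenuation levels in `(0, 1)`.
#' @return a list of contour polylines, each with `level`, `x` (column) and
#'   `y` (row) coordinates; empty for a constant field.
#' @export
render_contours <- function(field, levels = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(field, "shadow_field"))
  if (length(levels) == 0) stop("levels must be non-empty", call. = FALSE)
  if (any(levels <= 0 | levels >= 1) || is.unsorted(levels, strictly = TRUE))
    stop("levels must be strictly increasing within (0, 1)", call. = FALSE)
  a <- field$attenuation
  if (diff(range(a)) == 0) return(list())
  cl <- grDevices::contourLines(x = seq_len(nrow(a)), y = seq_len(ncol(a)),
                                z = a, levels = levels)
  lapply(cl, function(p) list(level = p$level, x = p$y, y = p$x))
}
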