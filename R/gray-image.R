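#' Grayscale image container
#'
#' A `gray_image` is an integer matrix of 8-bit intensities (0-255),
#' row-major with a top-left origin: `pixels[r, c]` is row `r` (depth,
#' increasing downwards on a typical ultrasound display) and column `c`
#' (lateral position). It is the unit every augmentation operator
#' transforms.
#'
#' @param pixels numeric matrix; values must lie in `[0, 255]`. Non-integer
#'   values are rounded.
#' @return An object of class `gray_image`: an integer matrix with
#'   attributes preserved.
#' @examples
#' img <- gray_image(matrix(128L, 32, 32))
#' dim(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  if (anyNA(pixels)) stop("image contains NA intensities", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  m <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  class(m) <- c("gray_image", "matrix", "array")
  m
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%d, %d]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

# Clamp to [0,255], round, re-wrap. All operators funnel through this so the
# intensity-range invariant holds by construction.
clamp_image <- function(m) {
  gray_image(pmin(pmax(round(m), 0), 255))
}

#' Read a grayscale image from disk
#'
#' PNG and JPEG are supported. Color inputs are collapsed to a single
#' channel by averaging the R, G and B planes (ultrasound B-mode frames are
#' pure grayscale; the average is an adequate luminance proxy for
#' accidentally color-encoded files). Portable graymaps (`.pgm`, ASCII "P2")
#' are also read so that fixtures can be plain text.
#'
#' @param path file path ending in `.png`, `.jpg`, `.jpeg` or `.pgm`.
#' @return a [gray_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    a <- jpeg_read(path)
  } else if (ext == "pgm") {
    return(read_pgm(path))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  gray_image(round(a * 255))
}

# jpeg is only needed when a user actually feeds a JPEG; keep the namespace
# soft so png remains the single hard codec dependency.
jpeg_read <- function(path) {
  if (!requireNamespace("jpeg", quietly = TRUE))
    stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
  jpeg::readJPEG(path)
}

#' Write a grayscale image to disk
#'
#' @param image a [gray_image].
#' @param path output path; `.png` or `.pgm` (ASCII) are supported. PNG
#'   output is deterministic: identical pixels give identical bytes.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is_gray_image(image))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(unclass(image) / 255, path)
  } else if (ext == "pgm") {
    write_pgm(image, path)
  } else {
    stop("unsupported output format: .", ext, call. = FALSE)
  }
  invisible(path)
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only ASCII (P2) PGM supported", call. = FALSE)
  w <- as.integer(toks[2]); h <- as.integer(toks[3]); mx <- as.numeric(toks[4])
  v <- as.numeric(toks[-(1:4)])
  if (length(v) != w * h) stop("PGM pixel count mismatch", call. = FALSE)
  gray_image(matrix(round(v / mx * 255), nrow = h, ncol = w, byrow = TRUE))
}

write_pgm <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "255"), con)
  apply(unclass(image), 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
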