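#' Labeled bounding boxes
#'
#' Boxes are kept as a data frame in YOLO normalized center format: one row
#' per nodule with columns `class_id` (0-based integer index into the class
#' list), `cx`, `cy` (box center as a fraction of image width/height),
#' `w`, `h` (box extent as a fraction), and `confidence` (score in `[0,1]`;
#' `NA` for human annotations). Boxes may protrude past the frame after a
#' rotation; they are clipped at render/evaluation time, not here, so the
#' intersection requirement is `cx - w/2 < 1`, `cx + w/2 > 0` (same in y).
#'
#' @param class_id integer vector (0-based).
#' @param cx,cy box centers in `[0, 1]`.
#' @param w,h box extents in `(0, 1]`.
#' @param confidence optional scores in `[0, 1]`; `NA` means human label.
#' @return a `labeled_boxes` data frame.
#' @export
labeled_boxes <- function(class_id = integer(), cx = numeric(),
                          cy = numeric(), w = numeric(), h = numeric(),
                          confidence = NA_real_) {
  if (length(class_id) == 0L) confidence <- numeric(0)
  df <- data.frame(class_id = as.integer(class_id),
                   cx = as.numeric(cx), cy = as.numeric(cy),
                   w = as.numeric(w), h = as.numeric(h),
                   confidence = as.numeric(confidence))
  validate_boxes(df)
  class(df) <- c("labeled_boxes", "data.frame")
  df
}

validate_boxes <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  with(df, {
    if (any(class_id < 0L)) stop("negative class_id", call. = FALSE)
    if (any(cx < 0 | cx > 1 | cy < 0 | cy > 1))
      stop("box centers must lie in [0, 1]", call. = FALSE)
    if (any(w <= 0 | w > 1 | h <= 0 | h > 1))
      stop("box extents must lie in (0, 1]", call. = FALSE)
    if (any(cx - w / 2 >= 1 | cx + w / 2 <= 0 |
            cy - h / 2 >= 1 | cy + h / 2 <= 0))
      stop("box does not intersect the image", call. = FALSE)
    if (any(!is.na(confidence) & (confidence < 0 | confidence > 1)))
      stop("confidence must lie in [0, 1]", call. = FALSE)
  })
  invisible(df)
}

empty_boxes <- function() labeled_boxes()

as_labeled_boxes <- function(df) {
  df$confidence <- if ("confidence" %in% names(df)) as.numeric(df$confidence) else NA_real_
  labeled_boxes(df$class_id, df$cx, df$cy, df$w, df$h, df$confidence)
}

#' One annotated image
#'
#' Bundles an image, its boxes, a unique id, and the annotation provenance
#' (`source`): `junior` and `senior` mirror the two-stage human annotation
#' workflow, `model` marks machine pre-annotations, `synthetic` marks
#' phantom data.
#'
#' @param image_id unique string.
#' @param image a [gray_image].
#' @param boxes a [labeled_boxes] frame.
#' @param source one of `"junior"`, `"senior"`, `"model"`, `"synthetic"`.
#' @return an `image_record`.
#' @export
image_record <- function(image_id, image, boxes = empty_boxes(),
                         source = c("synthetic", "junior", "senior", "model")) {
  source <- match.arg(source)
  stopifnot(is.character(image_id), length(image_id) == 1L, nzchar(image_id))
  stopifnot(is_gray_image(image))
  validate_boxes(boxes)
  structure(list(image_id = image_id, image = image,
                 boxes = boxes, source = source),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record '%s' [%s]: %d x %d, %d box(es)>\n",
              x$image_id, x$source, nrow(x$image), ncol(x$image),
              nrow(x$boxes)))
  invisible(x)
}

#' Read a YOLO label file
#'
#' Each non-empty line holds `class cx cy w h` (optionally a sixth
#' `confidence` field) separated by whitespace. Malformed lines raise an
#' error with the offending line number; they are never skipped silently.
#'
#' @param path label file path.
#' @param class_count number of classes; any `class_id >= class_count`
#'   raises an error.
#' @return a [labeled_boxes] frame in file order (possibly empty).
#' @export
read_labels <- function(path, class_count) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  stopifnot(is.numeric(class_count), class_count >= 1)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) return(empty_boxes())
  rows <- lapply(which(keep), function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (!length(f) %in% c(5L, 6L))
      stop(sprintf("%s:%d: expected 5 or 6 fields, got %d", path, i,
                   length(f)), call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop(sprintf("%s:%d: non-numeric field", path, i), call. = FALSE)
    if (v[1] != floor(v[1]) || v[1] < 0 || v[1] >= class_count)
      stop(sprintf("%s:%d: class id %s out of range [0, %d)", path, i, f[1],
                   as.integer(class_count)), call. = FALSE)
    c(v, if (length(v) == 5L) NA_real_)
  })
  m <- do.call(rbind, rows)
  out <- labeled_boxes(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6])
  out
}

#' Write a YOLO label file
#'
#' Coordinates are written with six decimals; boxes carrying a confidence
#' get a sixth field. `read_labels()` of the result reproduces the input up
#' to 1e-6, and re-writing what was read is byte-identical.
#'
#' @param boxes a [labeled_boxes] frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(boxes, path) {
  validate_boxes(boxes)
  lines <- character(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    lines[i] <- if (is.na(b$confidence))
      sprintf("%d %.6f %.6f %.6f %.6f", b$class_id, b$cx, b$cy, b$w, b$h)
    else
      sprintf("%d %.6f %.6f %.6f %.6f %.6f", b$class_id, b$cx, b$cy, b$w,
              b$h, b$confidence)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Dataset manifest
#'
#' Lists the class names (default: the six TI-RADS categories annotated in
#' the source workflow) and parallel vectors of image and label paths.
#' Serialized as YAML with `names:`, `images:` and `labels:` keys.
#'
#' @param class_names ordered unique class names.
#' @param image_paths,label_paths parallel path vectors (label `i` annotates
#'   image `i`; same file stem by YOLO convention).
#' @return a `dataset_manifest`.
#' @export
dataset_manifest <- function(class_names = tirads_classes(),
                             image_paths = character(),
                             label_paths = character()) {
  stopifnot(!anyDuplicated(class_names),
            length(image_paths) == length(label_paths))
  structure(list(class_names = as.character(class_names),
                 image_paths = as.character(image_paths),
                 label_paths = as.character(label_paths)),
            class = "dataset_manifest")
}

#' Default class list: TI-RADS categories 2-5
#'
#' Category 6 is a pathology-based label and is never image-annotated, so
#' the working class list is 2, 3, 4A, 4B, 4C, 5.
#' @return character vector of length 6.
#' @export
tirads_classes <- function() c("2", "3", "4A", "4B", "4C", "5")

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest: %d image(s), classes [%s]>\n",
              length(x$image_paths), paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Read / write a dataset manifest
#'
#' @param path YAML file. Keys: `names` (class list) and either explicit
#'   `images`/`labels` path lists or `images_dir`/`labels_dir` directories
#'   (all images in `images_dir` paired with same-stem `.txt` labels).
#' @return a [dataset_manifest].
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$names)) stop("manifest missing `names:`", call. = FALSE)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  if (!is.null(y$images)) {
    imgs <- rel(unlist(y$images)); labs <- rel(unlist(y$labels))
  } else if (!is.null(y$images_dir)) {
    d <- rel(y$images_dir)
    imgs <- sort(list.files(d, pattern = "\\.(png|jpg|jpeg|pgm)$",
                            full.names = TRUE))
    labs <- file.path(rel(y$labels_dir),
                      paste0(tools::file_path_sans_ext(basename(imgs)), ".txt"))
  } else stop("manifest needs `images:` or `images_dir:`", call. = FALSE)
  dataset_manifest(unlist(y$names), imgs, labs)
}

#' @rdname read_manifest
#' @param manifest a [dataset_manifest].
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(list(names = as.list(manifest$class_names),
                        images = as.list(manifest$image_paths),
                        labels = as.list(manifest$label_paths)),
                   path)
  invisible(path)
}

#' Image ids of a manifest
#'
#' The id of an image is its file stem (basename without extension); label
#' files share the stem by YOLO convention.
#'
#' @param manifest a [dataset_manifest].
#' @return character vector of ids.
#' @export
manifest_ids <- function(manifest) {
  tools::file_path_sans_ext(basename(manifest$image_paths))
}

#' Per-class nodule counts
#'
#' Counts nodule *instances* (label lines), not images, across every label
#' file of a manifest — the bar-chart summary used to expose class
#' imbalance before and after balancing.
#'
#' @param dataset a [dataset_manifest].
#' @return named integer vector, one entry per class (zeros included);
#'   `sum()` equals the total number of boxes.
#' @export
class_counts <- function(dataset) {
  k <- length(dataset$class_names)
  counts <- integer(k)
  names(counts) <- dataset$class_names
  for (lp in dataset$label_paths) {
    b <- read_labels(lp, k)
    if (nrow(b)) {
      t <- tabulate(b$class_id + 1L, nbins = k)
      counts <- counts + t
    }
  }
  counts
}

# Counts for an in-memory list of image_records (used by the planner and
# the phantom tests; avoids round-tripping through disk).
record_class_counts <- function(records, class_count) {
  counts <- integer(class_count)
  for (r in records)
    if (nrow(r$boxes))
      counts <- counts + tabulate(r$boxes$class_id + 1L, nbins = class_count)
  counts
}

# Load record i of a manifest.
load_record <- function(manifest, i, source = "senior") {
  img <- read_image(manifest$image_paths[i])
  boxes <- read_labels(manifest$label_paths[i], length(manifest$class_names))
  image_record(manifest_ids(manifest)[i], img, boxes, source = source)
}

#' Write a list of image records as a YOLO-format dataset
#'
#' Creates `images/` and `labels/` under `out_dir`, one PNG + one label
#' file per record, and returns the manifest (also written as
#' `manifest.yaml`).
#'
#' @param records list of [image_record]s.
#' @param out_dir output directory (created if missing).
#' @param class_names class list for the manifest.
#' @return a [dataset_manifest].
#' @export
write_dataset <- function(records, out_dir, class_names = tirads_classes()) {
  img_dir <- file.path(out_dir, "images")
  lab_dir <- file.path(out_dir, "labels")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- labs <- character(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    imgs[i] <- file.path(img_dir, paste0(r$image_id, ".png"))
    labs[i] <- file.path(lab_dir, paste0(r$image_id, ".txt"))
    write_image(r$image, imgs[i])
    write_labels(r$boxes, labs[i])
  }
  ids <- tools::file_path_sans_ext(basename(imgs))
  if (anyDuplicated(ids)) stop("duplicate image ids in dataset", call. = FALSE)
  m <- dataset_manifest(class_names, imgs, labs)
  write_manifest(m, file.path(out_dir, "manifest.yaml"))
  m
}
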