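#' Cumulative batched train/validation schedule
#'
#' Reproduces the progressive data-division protocol: the image ids are
#' shuffled once, chunked into `n_portions` (default 25) near-equal
#' portions, and training proceeds in `n_batches` (default 5) cumulative
#' batches — batch `N` uses exactly the first `5 * N` portions. Within
#' every block of `n_portions / n_batches` portions the *last* portion is
#' the validation portion, so each batch has a 4:1 train/validation split
#' and earlier batches' assignments never change as `N` grows.
#'
#' @param image_ids character vector of unique image ids.
#' @param n_portions number of portions (default 25); must be divisible by
#'   `n_batches` and not exceed the number of ids.
#' @param n_batches number of cumulative batches (default 5).
#' @param seed integer seed for the single shuffle.
#' @return a `batch_schedule`: `portions` (list of id vectors, sizes
#'   differing by at most one, earlier portions take the remainder),
#'   `batches` (per batch: `train_portions`, `val_portions` indices),
#'   `n_portions`, `n_batches`, `seed`.
#' @examples
#' sch <- make_schedule(sprintf("img%05d", 1:8500), seed = 1)
#' lengths(sch$portions)[1]                          # 340
#' sch$batches[[2]]$train_portions                   # 1 2 3 4 6 7 8 9
#' @export
make_schedule <- function(image_ids, n_portions = 25L, n_batches = 5L,
                          seed) {
  image_ids <- as.character(image_ids)
  if (anyDuplicated(image_ids)) stop("image ids must be unique", call. = FALSE)
  if (length(image_ids) < n_portions)
    stop("fewer images than portions", call. = FALSE)
  if (n_portions %% n_batches != 0L)
    stop("n_portions must be divisible by n_batches", call. = FALSE)
  stopifnot(is.numeric(seed))
  set.seed(as.integer(seed))
  shuffled <- sample(image_ids)
  n <- length(shuffled)
  base <- n %/% n_portions
  extra <- n %% n_portions
  sizes <- rep(base, n_portions) + c(rep(1L, extra),
                                     rep(0L, n_portions - extra))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  portions <- lapply(seq_len(n_portions),
                     function(i) shuffled[starts[i]:ends[i]])
  block <- n_portions %/% n_batches
  batches <- lapply(seq_len(n_batches), function(N) {
    used <- seq_len(block * N)
    val <- block * seq_len(N)     # last portion of each block
    list(train_portions = setdiff(used, val), val_portions = val)
  })
  structure(list(portions = portions, batches = batches,
                 n_portions = as.integer(n_portions),
                 n_batches = as.integer(n_batches),
                 seed = as.integer(seed)),
            class = "batch_schedule")
}

#' @export
print.batch_schedule <- function(x, ...) {
  cat(sprintf("<batch_schedule: %d ids in %d portions, %d batches>\n",
              sum(lengths(x$portions)), x$n_portions, x$n_batches))
  invisible(x)
}

schedule_ids <- function(schedule, portion_idx) {
  unlist(schedule$portions[portion_idx], use.names = FALSE)
}

#' Materialize one batch as train/validation manifests
#'
#' Selects the original images of batch `batch_n` from a manifest. Only
#' originals are split; class balancing (which may add augmented copies)
#' is applied afterwards, per portion, so augmented derivatives always
#' inherit their source image's side of the split and can never leak
#' across it.
#'
#' @param schedule a `batch_schedule`.
#' @param batch_n batch index in `1..n_batches`.
#' @param dataset a [dataset_manifest] containing every scheduled id.
#' @return `list(train =, val =)` of [dataset_manifest]s with disjoint ids.
#' @export
materialize_batch <- function(schedule, batch_n, dataset) {
  stopifnot(inherits(schedule, "batch_schedule"))
  if (batch_n < 1 || batch_n > schedule$n_batches)
    stop("batch_n out of range", call. = FALSE)
  b <- schedule$batches[[batch_n]]
  ids <- manifest_ids(dataset)
  pick <- function(portion_idx) {
    want <- schedule_ids(schedule, portion_idx)
    idx <- match(want, ids)
    if (anyNA(idx))
      stop("schedule refers to ids missing from the manifest", call. = FALSE)
    dataset_manifest(dataset$class_names, dataset$image_paths[idx],
                     dataset$label_paths[idx])
  }
  list(train = pick(b$train_portions), val = pick(b$val_portions))
}

schedule_to_list <- function(schedule) {
  list(n_portions = schedule$n_portions, n_batches = schedule$n_batches,
       seed = schedule$seed, portions = schedule$portions,
       batches = lapply(schedule$batches, function(b)
         list(train_portions = b$train_portions,
              val_portions = b$val_portions)))
}
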