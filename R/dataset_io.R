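# Dataset handling: image-folder scanning, the 7:2:1 image-wise split with
# largest-remainder apportionment, image preprocessing (bilinear resize,
# channel replication, standardization), and deterministic batch iteration.

.image_exts <- c("png", "jpg", "jpeg")

#' Scan an image-folder tree into a dataset index
#'
#' Expects `root/<split>/<class>/<image files>`. Class names are the sorted
#' union of class directories across splits; labels are the 0-based position
#' in that ordering. Non-image files are skipped. A class present in one
#' split but absent in another raises a warning, not an error.
#'
#' @param root dataset root directory.
#' @return An object of class `oct_index`: a data frame with columns `path`,
#'   `label`, `split`, and the ordered class names in `attr(, "class_names")`.
#' @export
scan_imagefolder <- function(root) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  splits <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  per_split_classes <- lapply(splits, function(sp) {
    sort(list.dirs(file.path(root, sp), recursive = FALSE, full.names = FALSE))
  })
  names(per_split_classes) <- splits
  class_names <- sort(Reduce(union, per_split_classes, character()))
  if (length(splits) == 0L || length(class_names) == 0L) {
    stop("empty dataset: no split/class directories under ", root)
  }
  for (sp in splits) {
    miss <- setdiff(class_names, per_split_classes[[sp]])
    if (length(miss)) {
      warning("split '", sp, "' is missing class(es): ",
              paste(miss, collapse = ", "))
    }
  }
  rec <- list()
  for (sp in splits) {
    for (cl in per_split_classes[[sp]]) {
      files <- list.files(file.path(root, sp, cl), full.names = TRUE)
      files <- files[tolower(tools::file_ext(files)) %in% .image_exts]
      if (!length(files)) next
      rec[[length(rec) + 1L]] <- data.frame(
        path = sort(files),
        label = match(cl, class_names) - 1L,
        split = sp, stringsAsFactors = FALSE)
    }
  }
  if (!length(rec)) stop("empty dataset: no image files under ", root)
  idx <- do.call(rbind, rec)
  rownames(idx) <- NULL
  attr(idx, "class_names") <- class_names
  class(idx) <- c("oct_index", "data.frame")
  idx
}

#' Split sizes by largest-remainder apportionment
#'
#' Each split receives `floor(n * r_i)` items; the remainder goes one by one
#' to the splits with the largest fractional parts, ties resolved in favour
#' of the earlier split. The sizes always sum to `n`. With ratios 7:2:1 this
#' reproduces, for example, 3231 -> (2262, 646, 323).
#'
#' @param n_items total number of items.
#' @param ratios positive proportions (normalised to sum to 1).
#' @return Integer vector of sizes, named after `names(ratios)` if present.
#' @export
split_sizes <- function(n_items, ratios = c(train = 0.7, val = 0.2, test = 0.1)) {
  if (any(ratios < 0) || sum(ratios) <= 0) stop("ratios must be positive")
  r <- ratios / sum(ratios)
  exact <- n_items * r
  sizes <- floor(exact)
  rem <- n_items - sum(sizes)
  if (rem > 0) {
    frac <- exact - sizes
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    sizes[take] <- sizes[take] + 1
  }
  stats::setNames(as.integer(sizes), names(ratios))
}

#' Assign items to train/val/test splits
#'
#' Sizes come from [split_sizes()] (largest-remainder apportionment);
#' membership is assigned by a seeded shuffle, so the assignment is
#' image-wise, exhaustive and disjoint.
#'
#' @param n_items number of items to assign.
#' @param ratios split proportions, named (default 7:2:1 train/val/test).
#' @param seed shuffle seed.
#' @return Character vector of length `n_items` with the split name per item.
#' @export
split_indices <- function(n_items, ratios = c(train = 0.7, val = 0.2, test = 0.1),
                          seed = 1L) {
  nz <- sum(ratios > 0)
  if (n_items < nz) stop("infeasible split: ", n_items, " item(s) for ", nz,
                         " non-empty splits")
  sizes <- split_sizes(n_items, ratios)
  labels <- rep(names(sizes), times = sizes)
  ord <- with_seed(seed, sample.int(n_items))
  out <- character(n_items)
  out[ord] <- labels
  out
}

#' Read an image file into a numeric array
#'
#' PNG is read natively; JPEG requires the optional EBImage package. The
#' result is an `h x w x 3` array on the 0..255 scale (grayscale replicated).
#'
#' @param path image file path.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package")
    }
    a <- EBImage::imageData(EBImage::readImage(path))
    a <- aperm(a, c(2L, 1L, 3L)[seq_len(length(dim(a)))])
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3L] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  a * 255
}

# Separable bilinear interpolation weights (corner-aligned = FALSE): output
# pixel centres map to (i + 0.5) * n/m - 0.5 in source coordinates.
resize_weights <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- clamp(src, 0, n_in - 1)
  i0 <- pmin(floor(src), n_in - 1)
  f <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), i0 + 1)] <- W[cbind(seq_len(n_out), i0 + 1)] + (1 - f)
  W[cbind(seq_len(n_out), i1 + 1)] <- W[cbind(seq_len(n_out), i1 + 1)] + f
  W
}

bilinear_resize <- function(mat, oh, ow) {
  Wr <- resize_weights(nrow(mat), oh)
  Wc <- resize_weights(ncol(mat), ow)
  Wr %*% mat %*% t(Wc)
}

#' Preprocess an image into a normalized network input tensor
#'
#' Scales to `[0, 1]`, replicates grayscale to 3 channels, resizes with
#' separable bilinear interpolation (half-pixel-centre convention) to
#' `size x size`, and standardizes each channel with the given mean/sd
#' (default 0.5/0.5; ImageNet statistics can be supplied when loading
#' pretrained CNN weights).
#'
#' @param image a `labeled_image`, or a numeric array/matrix on the 0..255 or
#'   0..1 scale.
#' @param size output side length in pixels.
#' @param mean,sd per-channel normalization constants (scalar or length 3).
#' @return A `size x size x 3` array with the normalization recorded in
#'   `attr(, "normalization")`.
#' @export
preprocess <- function(image, size = 224L, mean = 0.5, sd = 0.5) {
  if (inherits(image, "labeled_image")) image <- image$pixels
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || any(d == 0L)) {
    stop("image must be a non-empty h x w x c array")
  }
  x <- image
  if (max(x) > 1 + 1e-9) x <- x / 255
  mean <- rep_len(mean, 3L); sd <- rep_len(sd, 3L)
  out <- array(0, c(size, size, 3L))
  for (ch in 1:3) {
    plane <- if (d[3L] >= 3L) x[, , ch] else x[, , 1L]
    out[, , ch] <- (bilinear_resize(plane, size, size) - mean[ch]) / sd[ch]
  }
  attr(out, "normalization") <- list(mean = mean, sd = sd)
  out
}

#' Deterministic batches over one split of a dataset index
#'
#' Yields every record of the split exactly once per epoch in a seeded
#' shuffled order; the last batch may be short.
#'
#' @param index an [scan_imagefolder()] index.
#' @param split split name (`"train"`, `"val"`, `"test"`).
#' @param batch_size batch size.
#' @param shuffle_seed order seed; `NULL` keeps the index order.
#' @param size preprocessing size (pixels); see [preprocess()].
#' @param tensors optional list of precomputed tensors aligned with `index`
#'   rows (used to avoid repeated decoding during training).
#' @return A list of batches: each has `x` (`size x size x 3 x n` array),
#'   `y` (0-based labels) and `rows` (index rows).
#' @export
batch_iterator <- function(index, split, batch_size, shuffle_seed = NULL,
                           size = 224L, tensors = NULL) {
  rows <- which(index$split == split)
  if (!length(rows)) stop("unknown or empty split: ", split)
  if (!is.null(shuffle_seed)) {
    rows <- rows[with_seed(shuffle_seed, sample.int(length(rows)))]
  }
  starts <- seq.int(1L, length(rows), by = batch_size)
  lapply(starts, function(s) {
    b <- rows[s:min(s + batch_size - 1L, length(rows))]
    xs <- lapply(b, function(r) {
      if (!is.null(tensors)) tensors[[r]]
      else preprocess(read_image(index$path[r]), size = size)
    })
    x <- array(unlist(xs), c(dim(xs[[1L]]), length(b)))
    list(x = x, y = index$label[b], rows = b)
  })
}

#' @export
print.oct_index <- function(x, ...) {
  cn <- attr(x, "class_names")
  cat(sprintf("oct_index: %d images, %d classes (%s)\n", nrow(x), length(cn),
              paste(cn, collapse = ", ")))
  print(table(split = x$split, label = x$label))
  invisible(x)
}
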