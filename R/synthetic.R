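# Deterministic synthetic OCT-like image generator. Images are smooth
# horizontal "retina band" intensity profiles with one class-specific lesion
# motif (bright blob, dark cavity, dome elevation of the bands, or a vertical
# band break) at a seeded random position, plus Gaussian pixel noise. Every
# image is generated from an independent RNG stream derived from the master
# seed and the (class, draw) pair, so per-image determinism survives
# reordering.

.motif_kinds <- c("none", "bright-blob", "dark-cavity", "dome-elevation",
                  "band-break")

#' Specification of a synthetic OCT-like dataset
#'
#' @param num_classes number of classes K (>= 2).
#' @param images_per_class draws per class (>= 1).
#' @param image_size square image side in pixels.
#' @param band_count number of horizontal retina-like bands.
#' @param lesion_params per-class motif descriptors: a list of K lists with
#'   fields `kind` (one of `r paste(octfusion:::.motif_kinds, collapse=", ")`),
#'   `amplitude` (grayscale units) and `radius` (pixels). Defaults cycle
#'   through the motif kinds with amplitude 80 and radius `image_size / 10`.
#' @param noise_sd Gaussian pixel noise standard deviation (grayscale units).
#' @param seed master seed; together with the spec it determines every byte
#'   of every image.
#' @return An object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(num_classes = 2, images_per_class = 5,
#'                        image_size = 64, seed = 7)
#' imgs <- generate_dataset(spec)
#' length(imgs)
#' @export
synthetic_spec <- function(num_classes = 4L, images_per_class = 10L,
                           image_size = 224L, band_count = 6L,
                           lesion_params = NULL, noise_sd = 8, seed = 1L) {
  num_classes <- as.integer(num_classes)
  images_per_class <- as.integer(images_per_class)
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (images_per_class < 1L) stop("images_per_class must be >= 1")
  if (image_size < 16L) stop("image_size must be at least 16 pixels")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(lesion_params)) {
    lesion_params <- lapply(seq_len(num_classes), function(k) {
      list(kind = .motif_kinds[((k - 1L) %% length(.motif_kinds)) + 1L],
           amplitude = 80, radius = max(5L, round(image_size / 8)))
    })
  }
  if (length(lesion_params) != num_classes) {
    stop("lesion_params must have one descriptor per class")
  }
  for (lp in lesion_params) {
    if (!lp$kind %in% .motif_kinds) {
      stop("unknown motif kind: ", lp$kind, " (expected one of ",
           paste(.motif_kinds, collapse = ", "), ")")
    }
  }
  structure(list(num_classes = num_classes,
                 images_per_class = images_per_class,
                 image_size = as.integer(image_size),
                 band_count = as.integer(band_count),
                 lesion_params = lesion_params,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

class_dirname <- function(spec, class_id) {
  sprintf("class%02d_%s", class_id,
          gsub("-", "", spec$lesion_params[[class_id + 1L]]$kind))
}

#' Render one synthetic labelled image
#'
#' Smooth horizontal intensity bands plus the class's lesion motif at a
#' seeded random position inside the central half of the image, plus Gaussian
#' noise, clamped to `[0, 255]`. Deterministic given
#' `(spec$seed, class_id, draw_index)`.
#'
#' @param class_id class index in `0 .. num_classes - 1`.
#' @param spec a [synthetic_spec()].
#' @param draw_index draw number within the class (1-based).
#' @return A `labeled_image`: list with `pixels` (`S x S x 3` integer array in
#'   `[0, 255]`), `label` (0-based class index), `identifier`, and `lesion`
#'   (the motif kind with its ground-truth centre in pixel coordinates --
#'   `x` = column, `y` = row -- and radius), which lets localization methods
#'   be scored against the generator's truth.
#' @export
render_image <- function(class_id, spec, draw_index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  class_id <- as.integer(class_id)
  if (class_id < 0L || class_id >= spec$num_classes) {
    stop("class_id out of range 0..", spec$num_classes - 1L)
  }
  S <- spec$image_size
  lp <- spec$lesion_params[[class_id + 1L]]
  lesion_pos <- NULL
  img <- with_seed(stream_seed(spec$seed, class_id, draw_index), {
    # the band profile is a fixed anatomy-like scaffold shared by all
    # images; the class signal is carried by the lesion motif alone, and
    # per-image variation comes from the lesion position and pixel noise
    nb <- spec$band_count
    centers <- clamp((seq_len(nb) - 0.5) / nb +
                       0.02 * sin(seq_len(nb)), 0.05, 0.95)
    widths <- 0.02 + 0.012 * (seq_len(nb) %% 3) / 2
    amps <- 70 + 8 * rep_len(c(1, -0.5, 0.25), nb)
    base <- 30
    profile <- function(yy) {
      out <- rep(base, length(yy))
      for (b in seq_len(nb)) {
        out <- out + amps[b] * exp(-((yy - centers[b]) / widths[b])^2)
      }
      out
    }
    cx <- stats::runif(1, 0.25, 0.75) * S
    cy <- stats::runif(1, 0.25, 0.75) * S
    lesion_pos <- c(x = cx, y = cy)
    y01 <- (seq_len(S) - 0.5) / S
    x <- seq_len(S)
    if (lp$kind == "dome-elevation") {
      disp <- (lp$radius / S) * 1.2 * exp(-((x - cx) / (1.8 * lp$radius))^2)
      img <- vapply(seq_len(S), function(j) profile(y01 + disp[j]), numeric(S))
    } else {
      img <- matrix(profile(y01), S, S)
    }
    if (lp$kind %in% c("bright-blob", "dark-cavity")) {
      d2 <- outer((seq_len(S) - cy)^2, (x - cx)^2, "+")
      blob <- lp$amplitude * exp(-d2 / lp$radius^2)
      img <- img + if (lp$kind == "bright-blob") blob else -blob
    } else if (lp$kind == "band-break") {
      strip <- exp(-((x - cx) / lp$radius)^4)
      img <- base + sweep(img - base, 2L, 1 - strip, "*")
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(S * S, 0, spec$noise_sd), S, S)
    }
    img
  })
  px <- as.integer(round(clamp(img, 0, 255)))
  pixels <- array(px, c(S, S, 3L))
  structure(list(pixels = pixels, label = class_id,
                 identifier = sprintf("c%02d_i%04d", class_id, draw_index),
                 lesion = list(kind = lp$kind, x = unname(lesion_pos["x"]),
                               y = unname(lesion_pos["y"]),
                               radius = lp$radius)),
            class = "labeled_image")
}

#' Generate the full synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @return A list of `num_classes * images_per_class` [render_image()]
#'   results (balanced per class), with the class directory names attached as
#'   `attr(, "class_names")`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- vector("list", spec$num_classes * spec$images_per_class)
  n <- 0L
  for (k in 0:(spec$num_classes - 1L)) {
    for (i in seq_len(spec$images_per_class)) {
      n <- n + 1L
      out[[n]] <- render_image(k, spec, i)
    }
  }
  attr(out, "class_names") <- vapply(0:(spec$num_classes - 1L),
                                     function(k) class_dirname(spec, k), "")
  class(out) <- "oct_dataset"
  out
}

#' Write labelled images in the image-folder layout
#'
#' Files are written as lossless PNG at
#' `root/<split>/<class_name>/<identifier>.png`; re-scanning the tree with
#' [scan_imagefolder()] recovers the same label and split assignment.
#'
#' @param images an `oct_dataset` (or list of `labeled_image` with a
#'   `class_names` attribute).
#' @param root output directory (created if needed).
#' @param split_of either a single split name applied to all images, or a
#'   named character vector mapping identifier -> split.
#' @return Invisibly, a manifest data frame (path, label, split).
#' @export
write_imagefolder <- function(images, root, split_of = "train") {
  class_names <- attr(images, "class_names")
  if (is.null(class_names)) stop("images must carry a class_names attribute")
  ids <- vapply(images, `[[`, "", "identifier")
  if (length(split_of) == 1L && is.null(names(split_of))) {
    split_of <- stats::setNames(rep(split_of, length(ids)), ids)
  }
  miss <- setdiff(ids, names(split_of))
  if (length(miss)) stop("split_of does not cover identifiers: ",
                         paste(utils::head(miss, 3L), collapse = ", "))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop("cannot create output directory: ", root)
  paths <- character(length(images))
  labels <- integer(length(images))
  splits <- character(length(images))
  for (i in seq_along(images)) {
    im <- images[[i]]
    sp <- split_of[[im$identifier]]
    d <- file.path(root, sp, class_names[im$label + 1L])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(d, paste0(im$identifier, ".png"))
    png::writePNG(im$pixels / 255, p)
    paths[i] <- p; labels[i] <- im$label; splits[i] <- sp
  }
  invisible(data.frame(path = paths, label = labels, split = splits,
                       stringsAsFactors = FALSE))
}
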