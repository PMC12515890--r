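# Grad-CAM interpretability: channel weights are the spatial means of the
# class-score gradient at a chosen spatial layer; the rectified weighted sum
# of activation channels, upsampled and min-max normalized, localises the
# image evidence for a class.

#' Grad-CAM heatmap for one image
#'
#' Computes the gradient of the (pre-softmax) class score with respect to a
#' spatial activation, averages it spatially into per-channel weights, and
#' rectifies the weighted channel sum. The map is bilinearly upsampled to the
#' input size and min-max normalized to `[0, 1]` (an all-zero raw map stays
#' all-zero).
#'
#' @param model an [oct_model()] or [oct_fit()].
#' @param x a preprocessed input tensor (`S x S x 3`).
#' @param target_class 0-based class to explain; default is the predicted
#'   class.
#' @param layer spatial layer name: one of `fused1..4` (default `fused4`,
#'   the fusion output feeding the classifier), `cnn1..4`, `swin1..4`,
#'   or `input`.
#' @return An object of class `oct_heatmap`: list with `values`
#'   (`S x S` in `[0, 1]`), `source_layer`, `target_class` and the
#'   probability vector of the forward pass.
#' @export
grad_cam <- function(model, x, target_class = NULL, layer = "fused4") {
  if (inherits(model, "oct_fit")) {
    m <- model$model
    if (!is.null(model$best$params)) m$params <- model$best$params
    model <- m
  }
  out <- oct_forward(model, x, record = TRUE)
  nodes <- out$state$nodes
  K <- model$cfg$num_classes
  if (is.null(target_class)) target_class <- which.max(out$prob) - 1L
  if (target_class < 0L || target_class >= K) stop("target_class out of range")
  node <- nodes[[layer]]
  if (is.null(node)) {
    stop("unknown layer '", layer, "'; available: ",
         paste(setdiff(names(nodes), c("logits", "prob")), collapse = ", "))
  }
  is_token_layer <- layer %in% paste0("swin", 1:4)
  if (!is_token_layer && length(dim(node$val)) != 3L) {
    stop("layer '", layer, "' does not expose a spatial activation")
  }
  seed <- matrix(0, 1L, K)
  seed[1L, target_class + 1L] <- 1
  ad_backward(nodes$logits, seed = seed)
  grad <- ad_grad(node)
  if (is.null(grad)) grad <- array(0, dim1(node$val))
  act <- node$val
  if (is_token_layer) {
    g <- stage_grids(model$cfg)[as.integer(substring(layer, 5L))]
    act <- tokens_to_map(act, g, g)
    grad <- tokens_to_map(grad, g, g)
  }
  wts <- apply(grad, 3L, mean)
  cam <- pmax(apply(sweep(act, 3L, wts, "*"), c(1L, 2L), sum), 0)
  S <- dim(x)[1L]
  cam <- bilinear_resize(cam, S, S)
  cam <- pmax(cam, 0)
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  structure(list(values = cam, source_layer = layer,
                 target_class = as.integer(target_class),
                 prob = out$prob),
            class = "oct_heatmap")
}

# Simple blue->cyan->yellow->red colormap on [0,1].
jet_colors <- function(v) {
  ramp <- grDevices::colorRamp(c("#00007F", "blue", "cyan", "yellow",
                                 "red", "#7F0000"))
  cols <- ramp(clamp(v, 0, 1)) / 255
  cols
}

#' Overlay a Grad-CAM heatmap on its source image
#'
#' Alpha-blends the colour-mapped heatmap over the grayscale image; warm
#' colours mark regions most associated with the target class.
#'
#' @param h an [grad_cam()] heatmap.
#' @param image the source `labeled_image` or an `h x w (x c)` array on the
#'   0..255 or 0..1 scale.
#' @param alpha blend weight of the heatmap layer.
#' @param file optional path; when given the overlay is also written as PNG.
#' @return An `h x w x 3` array in `[0, 1]`, invisibly when `file` is given.
#' @export
overlay <- function(h, image, alpha = 0.45, file = NULL) {
  stopifnot(inherits(h, "oct_heatmap"))
  if (inherits(image, "labeled_image")) image <- image$pixels
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  img <- image
  if (max(img) > 1 + 1e-9) img <- img / 255
  d <- dim(img)
  gray <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
  cam <- h$values
  if (!all(dim(cam) == d[1:2])) cam <- bilinear_resize(cam, d[1L], d[2L])
  cols <- jet_colors(as.vector(cam))
  out <- array(0, c(d[1L], d[2L], 3L))
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * gray + alpha * matrix(cols[, ch], d[1L], d[2L])
  }
  out <- clamp(out, 0, 1)
  if (!is.null(file)) {
    png::writePNG(out, file)
    return(invisible(out))
  }
  out
}

#' @export
print.oct_heatmap <- function(x, ...) {
  pk <- which(x$values == max(x$values), arr.ind = TRUE)[1L, ]
  cat(sprintf("oct_heatmap: layer %s, class %d, peak at (%d, %d)\n",
              x$source_layer, x$target_class, pk[1L], pk[2L]))
  invisible(x)
}
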