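#' Model configuration for the dual-branch OCT classifier
#'
#' Collects every architectural hyperparameter of the network: the shifted
#' window transformer branch (patch size, embedding width C, stage depths,
#' heads, window), the residual CNN branch (per-stage widths, blocks per
#' stage), the per-stage fusion width (the transformer stage width under
#' defaults), the classifier head and the class count.
#'
#' Both branches share the four-stage spatial ledger: with a 224-pixel input
#' and patch size 4 the token/feature grids are 56, 28, 14 and 7, the
#' transformer widths C, 2C, 4C, 8C, and the fused maps carry twice the stage
#' width (channel concatenation of the two branches).
#'
#' @param image_size input side length in pixels; must be divisible by
#'   `patch_size * 8`.
#' @param num_classes number of disease classes K (>= 2).
#' @param patch_size tokenization patch side in pixels.
#' @param embed_dim transformer base width C.
#' @param depths integer vector of 4 even block counts per stage.
#' @param heads integer vector of 4 head counts; each must divide the stage
#'   width `C * 2^(stage-1)`.
#' @param window attention window side M (clipped to the grid when a stage's
#'   grid is smaller).
#' @param cnn_widths integer vector of 4 output widths for the CNN stages.
#' @param cnn_blocks_per_stage residual bottleneck blocks per CNN stage:
#'   a scalar (the default two blocks in every stage) or a length-4 vector
#'   such as `c(3, 4, 6, 3)` for a ResNet-50-shaped branch (useful when
#'   loading pretrained weights via [set_weights()]).
#' @param classifier_hidden width of the fully connected classifier layer.
#' @param fusion_forward direction of the multi-level fusion chain:
#'   `"down"` passes stage i-1 fused features (downsampled) into stage i.
#' @param preset `"default"` (224-pixel, C = 96 scale), `"tiny"` (64-pixel,
#'   C = 16 desk-scale) or `"micro"` (32-pixel, C = 8, for fast checks);
#'   explicit arguments override preset values.
#' @return An object of class `oct_config`.
#' @examples
#' cfg <- oct_config(num_classes = 3, preset = "tiny")
#' model_shapes(cfg)
#' @export
oct_config <- function(num_classes,
                       image_size = NULL, patch_size = NULL, embed_dim = NULL,
                       depths = NULL, heads = NULL, window = NULL,
                       cnn_widths = NULL, cnn_blocks_per_stage = NULL,
                       classifier_hidden = NULL,
                       fusion_forward = c("down", "none"),
                       preset = c("default", "tiny", "micro")) {
  preset <- match.arg(preset)
  base <- switch(preset,
    default = list(image_size = 224L, patch_size = 4L, embed_dim = 96L,
                   depths = c(2L, 2L, 6L, 2L), heads = c(3L, 6L, 12L, 24L),
                   window = 7L, cnn_widths = c(256L, 512L, 1024L, 2048L),
                   cnn_blocks_per_stage = 2L, classifier_hidden = 1024L),
    tiny = list(image_size = 64L, patch_size = 4L, embed_dim = 16L,
                depths = c(2L, 2L, 6L, 2L), heads = c(2L, 4L, 8L, 16L),
                window = 4L, cnn_widths = c(32L, 64L, 128L, 256L),
                cnn_blocks_per_stage = 2L, classifier_hidden = 128L),
    micro = list(image_size = 32L, patch_size = 4L, embed_dim = 8L,
                 depths = c(2L, 2L, 2L, 2L), heads = c(2L, 2L, 4L, 4L),
                 window = 2L, cnn_widths = c(16L, 32L, 64L, 128L),
                 cnn_blocks_per_stage = 1L, classifier_hidden = 32L)
  )
  ov <- list(image_size = image_size, patch_size = patch_size,
             embed_dim = embed_dim, depths = depths, heads = heads,
             window = window, cnn_widths = cnn_widths,
             cnn_blocks_per_stage = cnn_blocks_per_stage,
             classifier_hidden = classifier_hidden)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) base[[nm]] <- ov[[nm]]
  cfg <- base
  cfg$num_classes <- as.integer(num_classes)
  cfg$fusion_forward <- match.arg(fusion_forward)
  cfg$preset <- preset
  cfg <- lapply(cfg, function(x) if (is.numeric(x)) as.integer(x) else x)
  validate_oct_config(structure(cfg, class = "oct_config"))
}

validate_oct_config <- function(cfg) {
  if (cfg$num_classes < 2L) stop("num_classes must be at least 2")
  if (cfg$image_size %% (cfg$patch_size * 8L) != 0L) {
    stop("image_size must be divisible by patch_size * 8 ",
         "(four stages of halving from the 1/", cfg$patch_size, " grid)")
  }
  if (length(cfg$depths) != 4L || any(cfg$depths %% 2L != 0L)) {
    stop("depths must be four even integers (W-MSA/SW-MSA pairs)")
  }
  if (length(cfg$heads) != 4L) stop("heads must have length 4")
  if (length(cfg$cnn_widths) != 4L) stop("cnn_widths must have length 4")
  if (!length(cfg$cnn_blocks_per_stage) %in% c(1L, 4L) ||
      any(cfg$cnn_blocks_per_stage < 1L)) {
    stop("cnn_blocks_per_stage must be a positive scalar or length-4 vector")
  }
  widths <- swin_widths(cfg)
  bad <- widths %% cfg$heads != 0L
  if (any(bad)) {
    stop("heads must divide the stage width at every stage; offending stage(s): ",
         paste(which(bad), collapse = ", "))
  }
  if (any(cfg$cnn_widths %% 4L != 0L)) {
    stop("cnn_widths must be divisible by 4 (bottleneck mid width)")
  }
  base_grid <- cfg$image_size %/% cfg$patch_size
  for (i in 1:4) stage_window(base_grid %/% 2L^(i - 1L), cfg$window)
  cfg
}

swin_widths <- function(cfg) as.integer(cfg$embed_dim * 2^(0:3))

stage_grids <- function(cfg) {
  as.integer((cfg$image_size %/% cfg$patch_size) %/% 2^(0:3))
}

#' Per-stage shape ledger of a model configuration
#'
#' @param cfg an [oct_config()].
#' @return A data frame with one row per stage: grid side, transformer width,
#'   CNN width, fused width (2x the stage fusion width) and attention window.
#' @export
model_shapes <- function(cfg) {
  grids <- stage_grids(cfg)
  widths <- swin_widths(cfg)
  win <- vapply(grids, function(g) stage_window(g, cfg$window)$M, 0L)
  data.frame(
    stage = 1:4,
    grid = grids,
    swin_width = widths,
    cnn_width = cfg$cnn_widths,
    fused_width = 2L * widths,
    window = win
  )
}

#' @export
print.oct_config <- function(x, ...) {
  cat(sprintf("Dual-branch OCT classifier configuration ('%s' preset)\n", x$preset))
  cat(sprintf("  input %dx%d, patch %d, C=%d, K=%d classes\n",
              x$image_size, x$image_size, x$patch_size, x$embed_dim,
              x$num_classes))
  cat(sprintf("  transformer depths %s, heads %s, window %d\n",
              paste(x$depths, collapse = "/"), paste(x$heads, collapse = "/"),
              x$window))
  cat(sprintf("  CNN widths %s, %d bottleneck block(s) per stage\n",
              paste(x$cnn_widths, collapse = "/"), x$cnn_blocks_per_stage))
  cat(sprintf("  classifier hidden %d; multi-level fusion: %s\n",
              x$classifier_hidden, x$fusion_forward))
  print(model_shapes(x), row.names = FALSE)
  invisible(x)
}
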