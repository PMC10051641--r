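# Preprocessing: resize to the working resolution, then contrast-limited
# adaptive histogram equalisation (CLAHE). Raw NIR wrist images lack contrast
# between vein and skin; CLAHE equalises histograms on a grid of tiles with
# the per-tile histogram clipped at a limit and the clipped mass
# redistributed, with bilinear interpolation between tile mappings.

#' Preprocessing configuration
#'
#' @param target_size output (H, W), default 256 x 256.
#' @param clahe_tile tile grid (rows, cols), default 8 x 8.
#' @param clahe_clip clip limit in the normalised convention (multiples of the
#'   uniform histogram height), default 6.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_size = c(256, 256), clahe_tile = c(8, 8),
                              clahe_clip = 6) {
  stopifnot(clahe_clip > 0, all(clahe_tile >= 1), all(target_size >= 16))
  structure(list(target_size = as.integer(target_size),
                 clahe_tile = as.integer(clahe_tile),
                 clahe_clip = clahe_clip),
            class = "preprocess_config")
}

#' Resize an intensity image
#'
#' Aspect ratio is not preserved: region-of-interest images are resized
#' directly to the working resolution. Bilinear interpolation for images;
#' use [resize_mask()] for binary masks.
#'
#' @param img `H x W` matrix in `[0, 255]`.
#' @param target (H, W) output size, both >= 16.
#' @return Resized matrix.
#' @export
resize_image <- function(img, target = c(256, 256)) {
  assert_grayscale(img)
  if (any(target < 16)) stop("target size must be at least 16 x 16")
  if (all(dim(img) == target)) return(img)
  out <- EBImage::resize(EBImage::Image(img / 255), w = target[1], h = target[2],
                         antialias = FALSE)
  pmin(pmax(EBImage::imageData(out), 0), 1) * 255
}

#' Resize a binary mask (nearest neighbour, preserves binarity)
#' @param mask `{0, 1}` matrix.
#' @param target (H, W) output size.
#' @export
resize_mask <- function(mask, target) {
  if (all(dim(mask) == target)) return(mask)
  out <- EBImage::resize(EBImage::Image(mask), w = target[1], h = target[2],
                         filter = "none")
  (EBImage::imageData(out) > 0.5) * 1
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Per-tile histogram equalisation with the histogram clipped at
#' `cfg$clahe_clip` times the uniform bin height (excess redistributed
#' uniformly) and bilinear interpolation between neighbouring tile mappings.
#'
#' @param img `H x W` matrix in `[0, 255]`.
#' @param cfg a [preprocess_config()].
#' @return Enhanced matrix in `[0, 255]`.
#' @export
clahe_enhance <- function(img, cfg = preprocess_config()) {
  assert_grayscale(img)
  out <- EBImage::clahe(EBImage::Image(img / 255),
                        nx = cfg$clahe_tile[1], ny = cfg$clahe_tile[2],
                        bins = 256, limit = cfg$clahe_clip)
  round(pmin(pmax(EBImage::imageData(out), 0), 1) * 255)
}

#' Full preprocessing pipeline: resize, then CLAHE
#'
#' @param img raw intensity matrix.
#' @param cfg a [preprocess_config()].
#' @return Preprocessed `target_size` matrix in `[0, 255]`.
#' @export
preprocess_pipeline <- function(img, cfg = preprocess_config()) {
  clahe_enhance(resize_image(img, cfg$target_size), cfg)
}
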