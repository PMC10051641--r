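# Classical pseudo-label generation. The chain - non-local means denoising,
# morphological opening, global histogram equalisation, then an iterative
# erosion/dilation refinement run to a fixed point - produces approximate
# binary vein masks used to supervise the segmenter, so no manual annotation
# is needed.
#
# Decisions the chain needs but the classical description leaves open: the
# gray-to-binary step is an absolute cut on the equalised image (after global
# equalisation intensity is a monotone function of rank, so the cut is a
# quantile cut; Otsu systematically over-segments sparse thin foregrounds);
# veins are the darker class; the structuring element is a 3 x 3 disc; the
# refinement is capped at `morph_max_iter` rounds to guarantee termination.

#' Labeling (pseudo-mask generation) configuration
#'
#' @param nlm_strength non-local-means filter strength (gray levels).
#' @param nlm_patch_r,nlm_search_r patch and search-window radii (pixels).
#' @param opening_size structuring-element diameter for the opening (pixels).
#' @param morph_max_iter cap on refinement iterations (>= 1).
#' @param binarize_threshold final cut on the equalised image, `[1, 254]`:
#'   pixels below it are vein candidates (a quantile cut, since global
#'   equalisation maps intensity onto rank).
#' @param invert set TRUE for sensors where veins are brighter than skin;
#'   default FALSE (NIR veins are dark).
#' @return A `labeling_config` list.
#' @export
labeling_config <- function(nlm_strength = 10, nlm_patch_r = 1, nlm_search_r = 3,
                            opening_size = 3, morph_max_iter = 50,
                            binarize_threshold = 15, invert = FALSE) {
  stopifnot(nlm_strength > 0, opening_size >= 1, morph_max_iter >= 1,
            binarize_threshold > 0, binarize_threshold < 255)
  structure(list(nlm_strength = nlm_strength, nlm_patch_r = as.integer(nlm_patch_r),
                 nlm_search_r = as.integer(nlm_search_r),
                 opening_size = as.integer(opening_size),
                 morph_max_iter = as.integer(morph_max_iter),
                 binarize_threshold = binarize_threshold, invert = invert),
            class = "labeling_config")
}

#' Non-local means denoising
#'
#' Patch-based weighted averaging: each pixel is replaced by an average of
#' pixels in its search window, weighted by patch similarity. Strictly
#' reduces noise variance on flat regions while preserving vein edges better
#' than a Gaussian blur.
#'
#' @param img `H x W` matrix in `[0, 255]`.
#' @param strength filter strength h (gray levels).
#' @param patch_r,search_r patch and search-window radii.
#' @return Denoised matrix.
#' @export
denoise <- function(img, strength = 10, patch_r = 1, search_r = 3) {
  assert_grayscale(img)
  nlm_denoise_cpp(img, strength, as.integer(patch_r), as.integer(search_r))
}

disc_kernel <- function(size) {
  if (size <= 1) return(matrix(1, 1, 1))
  EBImage::makeBrush(size, shape = "disc")
}

#' Morphological opening (erosion then dilation)
#'
#' Removes pixel groups smaller than the structuring element; idempotent.
#'
#' @param img grayscale or binary matrix.
#' @param kernel_size structuring-element diameter (odd, pixels).
#' @return Opened matrix.
#' @export
open_morph <- function(img, kernel_size = 3) {
  if (kernel_size > min(dim(img)))
    stop("structuring element larger than the image")
  kern <- disc_kernel(kernel_size)
  out <- EBImage::opening(EBImage::Image(img / 255), kern)
  EBImage::imageData(out) * 255
}

#' Global histogram equalisation
#'
#' Plain (non-adaptive) equalisation over the whole image; preserves the
#' monotone ordering of intensities and maps the range onto `[0, 255]`.
#'
#' @param img `H x W` matrix in `[0, 255]`.
#' @return Equalised matrix.
#' @export
equalize <- function(img) {
  assert_grayscale(img)
  v <- round(img)
  cdf <- cumsum(tabulate(v + 1, nbins = 256)) / length(v)
  matrix(round(255 * cdf[v + 1]), nrow(img), ncol(img))
}

#' Iterative erosion/dilation refinement to a binary mask
#'
#' Binarises the enhanced image at `cfg$binarize_threshold` (veins = darker
#' class unless `cfg$invert`), then alternates erosion and dilation with the
#' configured structuring element until a full round changes no pixels, or
#' until `cfg$morph_max_iter` rounds (in which case the current mask is
#' returned with a warning).
#'
#' @param img enhanced intensity matrix in `[0, 255]`.
#' @param cfg a [labeling_config()].
#' @return `{0, 1}` mask matrix.
#' @export
iterative_refine <- function(img, cfg = labeling_config()) {
  mask <- if (cfg$invert) (img > 255 - cfg$binarize_threshold) * 1
          else (img < cfg$binarize_threshold) * 1
  refine_mask(mask, cfg)
}

refine_mask <- function(mask, cfg = labeling_config()) {
  kern <- disc_kernel(cfg$opening_size)
  for (it in seq_len(cfg$morph_max_iter)) {
    nxt <- EBImage::dilate(EBImage::erode(EBImage::Image(mask), kern), kern)
    nxt <- (EBImage::imageData(nxt) > 0.5) * 1
    if (identical(nxt, mask)) return(mask)
    mask <- nxt
  }
  warning("mask refinement did not converge within ", cfg$morph_max_iter,
          " iterations; returning current mask")
  mask
}

#' Generate a pseudo-ground-truth vein mask from a preprocessed image
#'
#' Full chain: denoise -> opening -> histogram equalisation -> iterative
#' refinement. Deterministic; output is binary with the input's dimensions.
#'
#' @param img preprocessed intensity matrix in `[0, 255]`.
#' @param cfg a [labeling_config()].
#' @return `{0, 1}` mask matrix.
#' @export
generate_mask <- function(img, cfg = labeling_config()) {
  x <- denoise(img, cfg$nlm_strength, cfg$nlm_patch_r, cfg$nlm_search_r)
  # open the vein (foreground) class: for dark veins that is the opening of
  # the inverted image, which removes dark specks smaller than the kernel
  x <- if (cfg$invert) open_morph(x, cfg$opening_size)
       else 255 - open_morph(255 - x, cfg$opening_size)
  x <- equalize(x)
  iterative_refine(x, cfg)
}
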