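# Raster conventions used throughout the package:
#   * intensity images are numeric H x W matrices on the 8-bit scale [0, 255],
#     indexed [row, col] with the origin at the top-left;
#   * binary masks are numeric H x W matrices with values in {0, 1}, 1 = vein;
#   * on disk both are 8-bit grayscale PNG (masks stored as {0, 255}).

#' Read a grayscale image as an 8-bit intensity matrix
#'
#' @param path PNG file path.
#' @return Numeric `H x W` matrix in `[0, 255]`.
#' @export
read_vein_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]  # collapse grayscale-with-alpha
  round(px * 255)
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param path output path (directories are created).
#' @export
write_vein_image <- function(img, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

#' Read a binary vein mask from PNG
#'
#' Pixels above half intensity are vein (1).
#' @param path PNG file path.
#' @return `{0, 1}` numeric matrix.
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  (px > 0.5) * 1
}

#' Write a binary mask as a `{0, 255}` grayscale PNG
#' @param mask `{0, 1}` matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(all(mask %in% c(0, 1)))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

assert_grayscale <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a single-channel numeric matrix image")
  if (any(img < 0 | img > 255)) stop("intensities must lie in [0, 255]")
  invisible(img)
}

## ---- affine transforms -----------------------------------------------------

#' Build a forward affine map in row/col pixel coordinates
#'
#' The transform scales, rotates (counter-clockwise in row/col space) about the
#' image centre, then translates: `p_out = s * R * (p_in - ctr) + ctr + v`.
#'
#' @param rotation_deg rotation angle in degrees.
#' @param translate length-2 numeric, (rows, cols) shift in pixels.
#' @param scale isotropic scale factor.
#' @param center length-2 numeric, centre of rotation/scaling (0-based).
#' @return An `affine_map` object (linear part `M`, offset `v`).
#' @export
make_affine <- function(rotation_deg = 0, translate = c(0, 0), scale = 1,
                        center = c(0, 0)) {
  th <- rotation_deg * pi / 180
  M <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  v <- center + translate - M %*% center
  structure(list(M = M, v = as.numeric(v)), class = "affine_map")
}

#' Invert an affine map
#' @param af `affine_map`.
#' @return The inverse `affine_map`.
#' @export
invert_affine <- function(af) {
  Mi <- solve(af$M)
  structure(list(M = Mi, v = as.numeric(-Mi %*% af$v)), class = "affine_map")
}

#' Apply an affine map to an image or mask
#'
#' Resampling is by inverse mapping; out-of-frame regions are filled with
#' `fill`. Nearest-neighbour resampling preserves binarity of masks.
#'
#' @param img `H x W` numeric matrix.
#' @param af `affine_map` from [make_affine()].
#' @param filter `"bilinear"` (images) or `"nearest"` (masks).
#' @param fill background fill value.
#' @return Warped matrix of the same dimensions.
#' @export
apply_affine <- function(img, af, filter = c("bilinear", "nearest"), fill = 0) {
  filter <- match.arg(filter)
  inv <- invert_affine(af)
  warp_affine_cpp(img, inv$M, inv$v, as.integer(filter == "bilinear"), fill)
}

#' Draw a random session-jitter affine within stated ranges
#'
#' @param rotation_deg max absolute rotation (degrees).
#' @param translate_frac max absolute translation as a fraction of frame size.
#' @param scale_range length-2 scale factor interval.
#' @param dim image dimensions (H, W).
#' @return `affine_map` centred on the frame.
#' @export
random_jitter_affine <- function(dim, rotation_deg = 10, translate_frac = 0.05,
                                 scale_range = c(0.95, 1.05)) {
  make_affine(
    rotation_deg = stats::runif(1, -rotation_deg, rotation_deg),
    translate = stats::runif(2, -translate_frac, translate_frac) * dim,
    scale = stats::runif(1, scale_range[1], scale_range[2]),
    center = (dim - 1) / 2
  )
}
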