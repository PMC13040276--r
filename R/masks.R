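#' Hue segmentation configuration
#'
#' Thresholds for turning an RGB overlay into a binary mask. A pixel is
#' contributive when its hue falls in any of the configured ranges and its
#' saturation and value clear the minimums (which excludes the achromatic
#' gray background). The default contributive range runs from red through
#' yellow and green to cyan — the warm side of a jet scale — plus the red
#' wrap-around, and excludes the blue band that encodes non-contributive
#' relevance.
#'
#' @param contributive List of hue intervals in degrees on `[0, 360)`;
#'   an interval with `lo > hi` wraps through 0.
#' @param min_saturation,min_value HSV floors in `[0, 1]`.
#' @return A `hue_config` object.
#' @export
hue_config <- function(contributive = list(c(0, 180), c(330, 360)),
                       min_saturation = 0.20, min_value = 0.15) {
  ok <- vapply(contributive, function(r) {
    length(r) == 2L && all(r >= 0) && all(r <= 360)
  }, logical(1))
  if (!all(ok)) {
    abort("hue intervals must be pairs of degrees in [0, 360]",
          class = "embryoxai_parameter_error")
  }
  structure(list(contributive = contributive,
                 min_saturation = min_saturation,
                 min_value = min_value),
            class = "hue_config")
}

#' @rdname hue_config
#' @export
lime_yellow_config <- function() {
  hue_config(contributive = list(c(45, 75)),
             min_saturation = 0.5, min_value = 0.5)
}

image_hsv <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3L] < 3L) {
    abort("expected an RGB raster (h x w x 3 array)",
          class = "embryoxai_format_error")
  }
  rgb <- rbind(as.vector(image[, , 1L]),
               as.vector(image[, , 2L]),
               as.vector(image[, , 3L]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  list(h = hsv[1L, ] * 360, s = hsv[2L, ], v = hsv[3L, ],
       dim = dim(image)[1:2])
}

in_hue_ranges <- function(h, ranges) {
  hit <- rep(FALSE, length(h))
  for (r in ranges) {
    if (r[1L] <= r[2L]) {
      hit <- hit | (h >= r[1L] & h <= r[2L])
    } else {
      hit <- hit | (h >= r[1L] | h <= r[2L])
    }
  }
  hit
}

#' Binary mask from a Grad-CAM-style overlay
#'
#' Segments the contributive region of a heatmap overlay by hue: pixels in
#' the contributive hue range (cyan through red by default) with enough
#' saturation and value become `TRUE`; blue and desaturated (gray
#' background) pixels stay `FALSE`.
#'
#' @param image RGB image array as returned by [render_gradcam_overlay()]
#'   or [read_overlay_png()].
#' @param config A [hue_config()].
#' @return A logical matrix mask.
#' @export
gradcam_to_mask <- function(image, config = hue_config()) {
  hsv <- image_hsv(image)
  m <- in_hue_ranges(hsv$h, config$contributive) &
    hsv$s >= config$min_saturation & hsv$v >= config$min_value
  matrix(m, nrow = hsv$dim[1L], ncol = hsv$dim[2L])
}

#' Binary mask from a LIME-style boundary overlay
#'
#' Detects yellow boundary pixels, morphologically closes small gaps in
#' the contours, and fills every closed contour, merging all filled
#' superpixel regions into one mask. With no yellow pixels at all the mask
#' is all-`FALSE` and a warning is issued (an image genuinely without
#' positive regions is valid input).
#'
#' @param image RGB image array.
#' @param yellow_config A [hue_config()] selecting the boundary color
#'   (default [lime_yellow_config()]).
#' @param gap_close Largest contour gap, in pixels, repaired by
#'   morphological closing before filling (default 2; 0 disables).
#' @return A logical matrix mask (boundary plus filled interior).
#' @export
lime_to_mask <- function(image, yellow_config = lime_yellow_config(),
                         gap_close = 2L) {
  hsv <- image_hsv(image)
  yel <- in_hue_ranges(hsv$h, yellow_config$contributive) &
    hsv$s >= yellow_config$min_saturation & hsv$v >= yellow_config$min_value
  m <- matrix(as.numeric(yel), nrow = hsv$dim[1L], ncol = hsv$dim[2L])
  if (!any(yel)) {
    warn("no yellow boundary pixels found; returning an empty mask",
         class = "embryoxai_empty_mask_warning")
    return(m > 0)
  }
  if (gap_close > 0L) {
    m <- EBImage::closing(m, EBImage::makeBrush(2L * as.integer(gap_close) + 1L,
                                                "box"))
  }
  filled <- EBImage::fillHull(m)
  as.matrix(filled) > 0
}

#' Intersection-over-union of two binary masks
#'
#' @param mask_a,mask_b Logical matrices of identical dimensions.
#' @return A one-row tibble: `intersection_px`, `union_px`, `iou` in
#'   `[0, 1]`, `percent`, and `degenerate` (`TRUE` when both masks are
#'   empty, in which case `iou` is defined as 0).
#' @examples
#' a <- rect_mask(10, 10, 1, 1, 10, 5)
#' b <- rect_mask(10, 10, 1, 4, 10, 8)
#' iou(a, b)
#' @export
iou <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) {
    abort("mask dimensions differ", class = "embryoxai_shape_error")
  }
  i <- sum(mask_a & mask_b)
  u <- sum(mask_a | mask_b)
  v <- if (u > 0) i / u else 0
  tibble(intersection_px = i, union_px = u, iou = v,
         percent = 100 * v, degenerate = u == 0)
}

#' Read and write binary masks and overlays as PNG
#'
#' Masks are stored as single-channel 8-bit PNGs with values 0 and 255
#' only, so a write/read round trip is bit-identical.
#'
#' @param mask Logical matrix.
#' @param path PNG file path.
#' @return `read_mask_png()` returns a logical matrix;
#'   `read_overlay_png()` returns an RGB array with a `kind` attribute.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

#' @rdname write_mask_png
#' @param image RGB array.
#' @param kind `"gradcam"` or `"lime"`, attached as an attribute on read.
#' @export
write_overlay_png <- function(image, path) {
  png::writePNG(image[, , 1:3, drop = FALSE], path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_overlay_png <- function(path, kind = c("gradcam", "lime")) {
  kind <- match.arg(kind)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  new_overlay(img[, , 1:3, drop = FALSE], kind)
}
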