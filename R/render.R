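#' Elementary region masks
#'
#' Constructors for logical region masks used as ground-truth attention
#' regions and LIME-style superpixel regions.
#'
#' @param width,height Mask dimensions in pixels.
#' @param center Numeric length-2 `(x, y)` center in pixel coordinates.
#' @param radius Disc radius in pixels.
#' @return A logical `height` x `width` matrix.
#' @export
disc_mask <- function(width, height, center = c(width / 2, height / 2),
                      radius = min(width, height) / 4) {
  x <- matrix(rep(seq_len(width), each = height), nrow = height)
  y <- matrix(rep(seq_len(height), times = width), nrow = height)
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

#' @rdname disc_mask
#' @param x0,y0,x1,y1 Inclusive pixel bounds of the rectangle.
#' @export
rect_mask <- function(width, height, x0, y0, x1, y1) {
  m <- matrix(FALSE, nrow = height, ncol = width)
  m[max(1, y0):min(height, y1), max(1, x0):min(width, x1)] <- TRUE
  m
}

#' Ground-truth attention field
#'
#' Builds a smooth relevance field in `[0, 1]` together with the truth mask
#' it induces: the level set `field >= relevance_cutoff`. The truth mask is
#' the known-by-construction contributive region against which mask
#' extraction is scored.
#'
#' @param width,height Field dimensions in pixels (default 224, the model
#'   input size; 500 matches the source image size).
#' @param kind `"disc"` — a single radial bump — or `"blobs"` — a clipped
#'   sum of Gaussian bumps at seeded random positions.
#' @param center,radius Disc parameters (disc kind). The field is
#'   `max(0, 1 - (d / radius)^2)` at distance `d` from the center.
#' @param n_blobs Number of Gaussian bumps (blobs kind).
#' @param relevance_cutoff Level in `(0, 1)` defining the truth mask.
#'   Default 0.25, the point where a jet color scale leaves blue.
#' @param seed Integer seed for the blobs kind and center jitter.
#' @return An `attention_field` object: list of `field`, `truth_mask`,
#'   `relevance_cutoff`.
#' @examples
#' tr <- attention_field(64, 64)
#' sum(tr$truth_mask)
#' @export
attention_field <- function(width = 224, height = 224,
                            kind = c("disc", "blobs"),
                            center = NULL, radius = NULL, n_blobs = 3,
                            relevance_cutoff = 0.25, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(width > 0, height > 0,
            relevance_cutoff > 0, relevance_cutoff < 1)
  x <- matrix(rep(seq_len(width), each = height), nrow = height)
  y <- matrix(rep(seq_len(height), times = width), nrow = height)
  if (kind == "disc") {
    if (is.null(center)) {
      center <- c(width / 2, height / 2)
      if (!is.null(seed)) {
        center <- center + withr::with_seed(seed, stats::runif(2, -0.1, 0.1)) *
          c(width, height)
      }
    }
    radius <- radius %||% (min(width, height) * 0.4)
    d2 <- (x - center[1])^2 + (y - center[2])^2
    field <- pmax(1 - d2 / radius^2, 0)
  } else {
    seed <- seed %||% 1L
    pars <- withr::with_seed(seed, {
      list(cx = stats::runif(n_blobs, 0.2, 0.8) * width,
           cy = stats::runif(n_blobs, 0.2, 0.8) * height,
           sg = stats::runif(n_blobs, 0.08, 0.2) * min(width, height))
    })
    field <- matrix(0, height, width)
    for (i in seq_len(n_blobs)) {
      field <- field + exp(-((x - pars$cx[i])^2 + (y - pars$cy[i])^2) /
                             (2 * pars$sg[i]^2))
    }
    field <- pmin(field / max(field), 1)
  }
  structure(
    list(field = field, truth_mask = field >= relevance_cutoff,
         relevance_cutoff = relevance_cutoff),
    class = "attention_field"
  )
}

# jet-style color scale: relevance 0 -> blue (hue 240), 1 -> red (hue 0),
# full saturation and value. Returns h x w x 3 array for a field matrix.
jet_rgb <- function(field) {
  # hue wheel segments (h in units of 60 degrees, range [0, 4]):
  # [0,1) r=1 g=x b=0 ; [1,2) r=x g=1 b=0 ; [2,3) r=0 g=1 b=x ;
  # [3,4] r=0 g=x b=1
  h <- 240 * (1 - as.vector(field)) / 60
  x <- 1 - abs(h %% 2 - 1)
  r <- ifelse(h < 1, 1, ifelse(h < 2, x, 0))
  g <- ifelse(h < 1, x, ifelse(h < 3, 1, x))
  b <- ifelse(h < 2, 0, ifelse(h < 3, x, 1))
  array(c(r, g, b), dim = c(nrow(field), ncol(field), 3))
}

new_overlay <- function(pixels, kind) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  structure(pixels, kind = kind)
}

#' Render a Grad-CAM-style heatmap overlay
#'
#' Maps the relevance field through a jet color scale — blue (low) through
#' cyan, green and yellow to red (high) — and alpha-blends it over a
#' neutral gray background, emulating a Grad-CAM visualization. Because
#' the background is achromatic, blending preserves hue, so the
#' contributive region remains recoverable by hue segmentation.
#'
#' @param truth An [attention_field()].
#' @param background_level Gray level of the background, 0..255.
#' @param blend_alpha Heatmap opacity in `[0, 1]` (default 0.5).
#' @param seed Optional integer seed for the background noise.
#' @param noise_sd Standard deviation of achromatic background noise on
#'   the `[0, 1]` scale (default 0.02; 0 disables).
#' @return An RGB image array (`height` x `width` x 3, values in `[0, 1]`,
#'   quantized to 8 bits) with attribute `kind = "gradcam"`.
#' @export
render_gradcam_overlay <- function(truth, background_level = 128,
                                   blend_alpha = 0.5, seed = NULL,
                                   noise_sd = 0.02) {
  stopifnot(inherits(truth, "attention_field"))
  if (blend_alpha < 0 || blend_alpha > 1) {
    abort("`blend_alpha` must lie in [0, 1]",
          class = "embryoxai_parameter_error")
  }
  f <- truth$field
  bg <- matrix(background_level / 255, nrow(f), ncol(f))
  if (noise_sd > 0 && !is.null(seed)) {
    bg <- bg + withr::with_seed(seed,
            matrix(stats::rnorm(length(f), 0, noise_sd), nrow(f)))
    bg <- pmax(pmin(bg, 1), 0)
  }
  heat <- jet_rgb(f)
  out <- heat * blend_alpha + array(rep(bg, 3), dim = dim(heat)) * (1 - blend_alpha)
  out <- round(pmax(pmin(out, 1), 0) * 255) / 255
  new_overlay(out, "gradcam")
}

region_boundary <- function(region, line_width = 2L) {
  r <- matrix(as.numeric(region), nrow(region))
  er <- EBImage::erode(r, EBImage::makeBrush(2L * line_width + 1L, "box"))
  region & !(er > 0)
}

#' Render a LIME-style boundary overlay
#'
#' Draws the closed boundary of each superpixel region in pure yellow
#' (255, 255, 0) over the background, as LIME renders positively
#' contributing superpixels. Region interiors are left untouched.
#'
#' @param regions A list of logical region masks sharing one dimension.
#' @param background An RGB image array, or a gray level (scalar in
#'   `[0, 1]`, or 0..255).
#' @param line_width Boundary thickness in pixels (drawn inside the
#'   region), at least 1.
#' @return An RGB image array with attribute `kind = "lime"`.
#' @export
render_lime_overlay <- function(regions, background = 128, line_width = 2L) {
  stopifnot(line_width >= 1L)
  if (length(regions) == 0L && !is.array(background)) {
    abort("with no regions, `background` must be an image to return",
          class = "embryoxai_parameter_error")
  }
  if (is.array(background) && length(dim(background)) == 3L) {
    out <- background
  } else {
    stopifnot(length(regions) > 0L)
    g <- if (background > 1) background / 255 else background
    d <- dim(regions[[1L]])
    out <- array(g, dim = c(d[1L], d[2L], 3L))
  }
  h <- dim(out)[1L]; w <- dim(out)[2L]
  for (reg in regions) {
    if (!all(dim(reg) == c(h, w))) {
      abort("region dimensions do not match the output image",
            class = "embryoxai_shape_error")
    }
    bnd <- region_boundary(reg, as.integer(line_width))
    r <- out[, , 1L]; g2 <- out[, , 2L]; b <- out[, , 3L]
    r[bnd] <- 1; g2[bnd] <- 1; b[bnd] <- 0
    out[, , 1L] <- r; out[, , 2L] <- g2; out[, , 3L] <- b
  }
  new_overlay(out, "lime")
}
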